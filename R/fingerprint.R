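# Linear-path fingerprints and Tanimoto similarity. Every simple
# heavy-atom path of 1..max_len atoms is labelled by its element/bond-order
# sequence (direction-canonicalized) and hashed into a fixed-length bitset.
# Because paths are enumerated on the canonical structure, two SMILES
# spellings of the same molecule give identical bitsets.

# Deterministic string hash -> bit index in [0, n_bits).
hash_label <- function(label, n_bits) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  h %% n_bits
}

# All direction-canonical simple-path labels of a molecular graph, heavy
# atoms only, up to max_len atoms.
path_labels <- function(graph, max_len = 7) {
  heavy <- which(graph$atoms != "H")
  if (length(heavy) == 0) abort("empty molecule: no heavy atoms to fingerprint")
  el <- graph$atoms
  nb <- vector("list", length(el))
  ord <- vector("list", length(el))
  bonds <- graph$bonds
  if (nrow(bonds)) {
    keep <- el[bonds$from] != "H" & el[bonds$to] != "H"
    bonds <- bonds[keep, , drop = FALSE]
    for (i in seq_len(nrow(bonds))) {
      f <- bonds$from[i]; t <- bonds$to[i]; o <- bonds$order[i]
      nb[[f]] <- c(nb[[f]], t); ord[[f]] <- c(ord[[f]], o)
      nb[[t]] <- c(nb[[t]], f); ord[[t]] <- c(ord[[t]], o)
    }
  }
  labels <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(fwd, rev) {
    lab <- if (fwd <= rev) fwd else rev
    assign(lab, TRUE, envir = labels)
  }
  walk <- function(atom, visited, fwd, rev, depth) {
    add(fwd, rev)
    if (depth == max_len) return()
    nbrs <- nb[[atom]]
    for (j in seq_along(nbrs)) {
      nxt <- nbrs[j]
      if (nxt %in% visited) next
      o <- ord[[atom]][j]
      walk(nxt, c(visited, nxt),
           paste0(fwd, o, el[nxt]), paste0(el[nxt], o, rev), depth + 1)
    }
  }
  for (a in heavy) walk(a, a, el[a], el[a], 1)
  ls(labels)
}

#' Path fingerprint of parsed compounds
#'
#' Hashes all linear heavy-atom paths of up to `max_len` atoms into an
#' `n_bits`-bit set. A single-atom molecule still sets at least one bit (its
#' length-1 path). Deterministic for a fixed canonical structure.
#'
#' @param compounds A `compound_set` from [parse_compounds()].
#' @param n_bits Fingerprint length in bits (default 1024).
#' @param max_len Maximum path length in atoms (default 7).
#' @return The compound set with a `fingerprint` list-column of sorted
#'   0-based bit indices, plus `fp_bits` recording the configured length.
#' @export
fingerprint_compounds <- function(compounds, n_bits = 1024, max_len = 7) {
  stopifnot(inherits(compounds, "compound_set"))
  check_positive_int(n_bits, "n_bits")
  check_positive_int(max_len, "max_len")
  out <- compounds |>
    mutate(
      fingerprint = map(.data$graph, function(g) {
        labs <- path_labels(g, max_len)
        sort(unique(vapply(labs, hash_label, numeric(1), n_bits = n_bits)))
      }),
      fp_bits = as.integer(n_bits)
    )
  class(out) <- unique(c("compound_set", class(out)))
  out
}

#' Tanimoto similarity of two bitsets
#'
#' `|a AND b| / |a OR b|` over set bits. Accepts logical bit vectors or
#' integer vectors of set-bit indices (as stored by
#' [fingerprint_compounds()]). Two empty bitsets have undefined similarity
#' and raise an error.
#'
#' @param a,b Bitsets.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
tanimoto <- function(a, b) {
  if (is.logical(a) || is.logical(b)) {
    if (length(a) != length(b)) abort("logical bitsets must have equal length")
    a <- which(a) ; b <- which(b)
  }
  ni <- length(intersect(a, b))
  nu <- length(union(a, b))
  if (nu == 0) abort("Tanimoto undefined: both bitsets are empty")
  ni / nu
}

#' Similarity screen against a reference compound
#'
#' Fingerprints the library and the reference with identical settings and
#' retains compounds whose Tanimoto similarity to the reference is at least
#' `threshold` (inclusive). All scores are returned for audit; survivors
#' are flagged by `pass`.
#'
#' @param library A data frame with `id`/`smiles` columns, or a
#'   `compound_set` (fingerprinted or not).
#' @param reference Reference SMILES string.
#' @param threshold Inclusive retention threshold in `[0, 1]` (default 0.6).
#' @param n_bits,max_len Fingerprint settings (see [fingerprint_compounds()]).
#' @return A tibble with `id`, `smiles`, `tanimoto`, `pass`, sorted by
#'   descending similarity.
#' @export
similarity_screen <- function(library, reference, threshold = 0.6,
                              n_bits = 1024, max_len = 7) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    abort("`threshold` must lie in [0, 1]")
  }
  if (!inherits(library, "compound_set")) library <- parse_compounds(library)
  if (nrow(library) == 0) {
    return(tibble(id = character(), smiles = character(),
                  tanimoto = double(), pass = logical()))
  }
  if (!"fingerprint" %in% names(library) ||
      !identical(library$fp_bits[1], as.integer(n_bits))) {
    library <- fingerprint_compounds(library, n_bits = n_bits, max_len = max_len)
  }
  ref <- fingerprint_compounds(parse_compounds(c(reference = reference)),
                               n_bits = n_bits, max_len = max_len)
  ref_fp <- ref$fingerprint[[1]]
  library |>
    mutate(tanimoto = map_dbl(.data$fingerprint, tanimoto, b = ref_fp),
           pass = .data$tanimoto >= threshold) |>
    select("id", "smiles", "tanimoto", "pass") |>
    arrange(desc(.data$tanimoto), .data$id)
}
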