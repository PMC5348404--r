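# Synthetic compound library: a reference scaffold, analogs built by small
# enumerated decorations of it (a graded similarity ladder spanning the
# screening threshold), and decoys drawn from an unrelated aliphatic/ether
# scaffold family.

# Default stand-in for the reference inhibitor scaffold: a quinoline
# carbohydrazide, echoing the aromatic-plus-hydrazide chemistry of known
# Rho-GTPase inhibitors. Purely synthetic; not any real compound.
DEFAULT_REFERENCE_SMILES <- "O=C(NN)c1ccc2ncccc2c1"

# chain tokens extend the growing side chain; terminal tokens (halogens)
# may only close it, keeping every emitted valence ordinary
CHAIN_TOKENS <- c("C", "O", "N", "CC", "CO", "CN", "C(C)C", "OC")
TERMINAL_TOKENS <- c("Cl", "F")

DECOY_SCAFFOLDS <- c(
  "CCCCCC", "CCOCC", "CC(C)CC(C)C", "OCC(O)CO", "CCCCOCCCC",
  "CC(C)(C)CC(C)(C)C", "OCCOCCO", "CCSCC", "CCCCCCCCCC", "CC(O)CC(O)C",
  "CCC(CC)CC", "COCCOC"
)

#' Simulate a compound library around a reference scaffold
#'
#' Emits the reference itself, `n_analogs` analogs built by appending 1 to
#' `decoration_depth` small substituent tokens to the reference SMILES
#' (each token extends a side chain, giving a graded similarity ladder),
#' and `n_decoys` decoys built the same way from an unrelated
#' aliphatic/ether scaffold family. Every emitted SMILES is validated by
#' parsing; generation is deterministic under the seed.
#'
#' @param reference_smiles Reference scaffold SMILES (default: a synthetic
#'   quinoline carbohydrazide stand-in).
#' @param n_analogs,n_decoys Library composition (non-negative).
#' @param decoration_depth Maximum number of appended substituent tokens
#'   per analog (small integer, default 2).
#' @param seed Integer seed.
#' @return A tibble with `id`, `smiles`, `family`
#'   (`reference`/`analog`/`decoy`); the `family` column is the truth table
#'   for similarity-screen recovery tests.
#' @export
sim_library <- function(reference_smiles = DEFAULT_REFERENCE_SMILES,
                        n_analogs = 30, n_decoys = 60,
                        decoration_depth = 2, seed = 1) {
  smiles_syntax_check(reference_smiles)
  ob_canonical(reference_smiles) # errors if unparseable
  stopifnot(n_analogs >= 0, n_decoys >= 0)
  check_positive_int(decoration_depth, "decoration_depth")

  decorate <- function(base, n, prefix) {
    if (n == 0) return(character())
    out <- character(0)
    tries <- 0
    while (length(out) < n && tries < 50 * n + 50) {
      tries <- tries + 1
      base_i <- if (length(base) == 1) base else sample(base, 1)
      depth <- sample.int(decoration_depth, 1)
      toks <- sample(CHAIN_TOKENS, depth, replace = TRUE)
      if (runif(1) < 0.3) toks[depth] <- sample(TERMINAL_TOKENS, 1)
      cand <- paste0(base_i, paste(toks, collapse = ""))
      ok <- tryCatch({
        smiles_syntax_check(cand)
        ob_canonical(cand)
        TRUE
      }, error = function(e) FALSE)
      if (ok && !cand %in% out) out <- c(out, cand)
    }
    if (length(out) < n) abort("could not generate enough valid decorated SMILES")
    out
  }

  withr::with_seed(seed, {
    analogs <- decorate(reference_smiles, n_analogs, "ANA")
    decoys <- decorate(DECOY_SCAFFOLDS, n_decoys, "DEC")
  })

  tibble(
    id = c("REF0001",
           sprintf("ANA%04d", seq_len(n_analogs)),
           sprintf("DEC%04d", seq_len(n_decoys))),
    smiles = c(reference_smiles, analogs, decoys),
    family = c("reference", rep("analog", n_analogs), rep("decoy", n_decoys))
  )
}
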