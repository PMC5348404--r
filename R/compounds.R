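# Compound ingestion. SMILES are syntax-checked, parsed and canonicalized
# through Open Babel (ChemmineOB), then expanded to an explicit-hydrogen
# molecular graph (atoms + bonds) on which fingerprints and rule-of-five
# descriptors are computed in-package.

# Light lexical screen run before Open Babel sees the string: Open Babel
# silently "repairs" some malformed inputs (e.g. "C(" parses as methane),
# which would hide user errors. Checks bracket balance, ring-closure digit
# pairing and the SMILES alphabet; reports the offending token.
smiles_syntax_check <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    abort("SMILES must be a single non-empty string")
  }
  chars <- strsplit(smiles, "")[[1]]
  bad <- grep("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", chars, value = TRUE)
  if (length(bad)) {
    abort(paste0("SMILES parse error in '", smiles, "': invalid character '", bad[1], "'"))
  }
  depth <- 0
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") {
      depth <- depth - 1
      if (depth < 0) abort(paste0("SMILES parse error in '", smiles, "': unmatched ')'"))
    }
  }
  if (depth != 0) abort(paste0("SMILES parse error in '", smiles, "': unclosed '('"))
  if (length(gregexpr("\\[", smiles)[[1]][gregexpr("\\[", smiles)[[1]] > 0]) !=
      length(gregexpr("\\]", smiles)[[1]][gregexpr("\\]", smiles)[[1]] > 0])) {
    abort(paste0("SMILES parse error in '", smiles, "': unbalanced brackets"))
  }
  # ring-closure digits outside brackets must pair up
  outside <- gsub("\\[[^]]*\\]", "", smiles)
  digits <- strsplit(gsub("[^0-9]", "", gsub("%[0-9]{2}", "", outside)), "")[[1]]
  if (length(digits)) {
    counts <- table(digits)
    if (any(counts %% 2 != 0)) {
      abort(paste0("SMILES parse error in '", smiles, "': unpaired ring-closure digit '",
                   names(counts)[counts %% 2 != 0][1], "'"))
    }
  }
  invisible(smiles)
}

# Canonical SMILES via Open Babel; errors if the string does not yield a
# non-empty molecule.
ob_canonical <- function(smiles) {
  res <- tryCatch(
    ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL
  )
  if (is.null(res) || nrow(res) == 0 || !nzchar(res$cansmi[1])) {
    abort(paste0("SMILES parse error: '", smiles, "' is not a valid molecule"))
  }
  res$cansmi[1]
}

# Explicit-hydrogen molecular graph from one canonical SMILES: list with
# `atoms` (character vector of element symbols) and `bonds` (tibble
# from/to/order). Built from an Open Babel V2000 molblock read by ChemmineR.
mol_graph <- function(cansmi) {
  txt <- ChemmineOB::convertFormat(
    "SMILES", "SDF", paste0(cansmi, " mol"),
    options = data.frame(names = c("gen2D", "h"), args = c("", ""))
  )
  sdf <- suppressWarnings(ChemmineR::read.SDFset(strsplit(txt, "\n")[[1]]))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- gsub("_.*$", "", rownames(ab))
  if (length(atoms) == 0) abort(paste0("empty molecule from '", cansmi, "'"))
  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- tibble(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- tibble(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
  }
  list(atoms = atoms, bonds = bonds)
}

#' Parse a compound library from SMILES
#'
#' Validates, parses and canonicalizes each SMILES through Open Babel and
#' attaches an explicit-hydrogen molecular graph per compound. Malformed or
#' valence-impossible SMILES raise an error naming the compound and the
#' offending token.
#'
#' @param x A data frame with id and SMILES columns, or a character vector
#'   of SMILES (ids are generated).
#' @param smiles_col,id_col Column names when `x` is a data frame.
#' @return A `compound_set` tibble with columns `id`, `smiles`, `cansmi`,
#'   `n_atoms`, and a `graph` list-column.
#' @examples
#' \donttest{
#' parse_compounds(c(methanol = "CO", benzene = "c1ccccc1"))
#' }
#' @export
parse_compounds <- function(x, smiles_col = "smiles", id_col = "id") {
  if (is.character(x)) {
    ids <- names(x) %||% sprintf("cmpd%04d", seq_along(x))
    ids[ids == ""] <- sprintf("cmpd%04d", which(ids == ""))
    x <- tibble(id = ids, smiles = unname(x))
  } else {
    x <- as_tibble(x)
    x <- rename(x, id = dplyr::all_of(id_col), smiles = dplyr::all_of(smiles_col))
  }
  if (anyDuplicated(x$id)) abort("compound ids must be unique")
  out <- x |>
    mutate(
      cansmi = map_chr(.data$smiles, function(s) {
        smiles_syntax_check(s)
        ob_canonical(s)
      }),
      graph = map(.data$cansmi, mol_graph),
      n_atoms = map_int(.data$graph, ~ length(.x$atoms))
    )
  class(out) <- c("compound_set", class(out))
  out
}

#' Read / write a SMILES (.smi) library file
#'
#' One compound per line, `SMILES<whitespace>id`.
#'
#' @param path File path.
#' @return `read_smi()` returns a tibble with `id` and `smiles`;
#'   `write_smi()` returns its input invisibly.
#' @export
read_smi <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  tibble(
    id = map_chr(parts, ~ if (length(.x) > 1) .x[2] else NA_character_),
    smiles = map_chr(parts, 1)
  ) |>
    mutate(id = dplyr::coalesce(.data$id, sprintf("cmpd%04d", row_number())))
}

#' @rdname read_smi
#' @param library Data frame with `id` and `smiles` columns.
#' @export
write_smi <- function(library, path) {
  readr::write_lines(paste(library$smiles, library$id), path)
  invisible(library)
}

#' Read compounds from an SDF file
#'
#' Structures are converted back to SMILES through Open Babel and re-parsed,
#' so downstream behavior is identical for .smi and .sdf inputs.
#'
#' @param path SDF file path.
#' @return A tibble with `id` and `smiles`.
#' @export
read_sdf_smiles <- function(path) {
  txt <- paste(readr::read_lines(path), collapse = "\n")
  smi <- ChemmineOB::convertFormat("SDF", "SMILES", txt)
  lines <- strsplit(smi, "\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\t")
  tibble(
    id = map_chr(parts, ~ if (length(.x) > 1) .x[2] else NA_character_),
    smiles = map_chr(parts, 1)
  ) |>
    mutate(id = dplyr::coalesce(.data$id, sprintf("cmpd%04d", row_number())))
}
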