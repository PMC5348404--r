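# Docking-pose ingestion: the canonical pose TSV, multi-model Vina-style
# PDBQT output, and mass-weighted center-of-mass computation.

POSE_COLUMNS <- c("compound_id", "pose_id", "x", "y", "z", "energy_kcal_mol")

#' Mass-weighted center of mass of atom records
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (Angstrom).
#' @param weighted If FALSE, return the unweighted geometric center instead.
#' @return A named numeric vector `c(x, y, z)`.
#' @examples
#' center_of_mass(data.frame(element = c("O", "H", "H"),
#'                           x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0))
#' @export
center_of_mass <- function(atoms, weighted = TRUE) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) abort("need at least one atom")
  if (!all(c("element", "x", "y", "z") %in% names(atoms))) {
    abort("atom records need columns element, x, y, z")
  }
  w <- if (weighted) atomic_mass(atoms$element) else rep(1, nrow(atoms))
  c(x = sum(w * atoms$x) / sum(w),
    y = sum(w * atoms$y) / sum(w),
    z = sum(w * atoms$z) / sum(w))
}

#' Read / write the canonical pose table
#'
#' A TSV whose header is exactly `compound_id, pose_id, x, y, z,
#' energy_kcal_mol`. Coordinates in Angstrom, energies in kcal/mol (more
#' negative = more favorable). Duplicate (compound_id, pose_id) keys are
#' rejected.
#'
#' @param path File path.
#' @return A pose tibble.
#' @export
read_pose_table <- function(path) {
  poses <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             compound_id = readr::col_character(),
                             pose_id = readr::col_character(),
                             .default = readr::col_double()
                           ))
  missing_cols <- setdiff(POSE_COLUMNS, names(poses))
  if (length(missing_cols)) {
    abort(paste0("pose table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  poses <- poses[POSE_COLUMNS]
  num <- c("x", "y", "z", "energy_kcal_mol")
  if (anyNA(as.matrix(poses[num])) || !all(is.finite(as.matrix(poses[num])))) {
    abort("non-numeric or non-finite coordinate/energy in pose table")
  }
  if (anyDuplicated(poses[c("compound_id", "pose_id")])) {
    abort("duplicate (compound_id, pose_id) key in pose table")
  }
  poses
}

#' @rdname read_pose_table
#' @param poses A pose tibble.
#' @export
write_pose_table <- function(poses, path) {
  stopifnot(all(POSE_COLUMNS %in% names(poses)))
  readr::write_tsv(poses[POSE_COLUMNS], path)
  invisible(poses)
}

# Map AutoDock atom types (last field of a PDBQT atom record) to elements.
ADTYPE_TO_ELEMENT <- c(
  A = "C", C = "C", N = "N", NA. = "N", NS = "N", OA = "O", OS = "O",
  SA = "S", S = "S", HD = "H", HS = "H", H = "H", F = "F", Cl = "Cl",
  CL = "Cl", Br = "Br", BR = "Br", I = "I", P = "P", ZN = "Zn", FE = "Fe",
  MG = "Mg", CA = "Ca", MN = "Fe", NAmetal = "Na"
)

adtype_element <- function(adtype) {
  key <- ifelse(adtype == "NA", "NA.", adtype)
  el <- ADTYPE_TO_ELEMENT[key]
  if (anyNA(el)) {
    abort(paste0("unparseable atom type(s) in PDBQT: ",
                 paste(unique(adtype[is.na(el)]), collapse = ", ")))
  }
  unname(el)
}

#' Read docked poses from a multi-model Vina-style PDBQT file
#'
#' Each `MODEL ... ENDMDL` block becomes one pose: the binding energy is the
#' first numeric field of its `REMARK VINA RESULT:` line and the center of
#' mass is computed from the block's atom records via [center_of_mass()].
#'
#' @param path PDBQT file path.
#' @param compound_id Compound id to assign (default: file name without
#'   extension).
#' @param weighted Mass-weighted COM (default) or geometric center.
#' @return A pose tibble in the canonical format.
#' @export
read_vina_poses <- function(path, compound_id = NULL, weighted = TRUE) {
  compound_id <- compound_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readr::read_lines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) abort("no MODEL records found in PDBQT file")
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) abort("unbalanced MODEL/ENDMDL records")
  rows <- map(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    remark <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    if (length(remark) == 0) {
      abort(paste0("model ", i, " has no 'REMARK VINA RESULT:' line"))
    }
    energy <- suppressWarnings(
      as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "", remark[1])), "\\s+")[[1]][1])
    )
    if (is.na(energy)) abort(paste0("model ", i, ": unparseable energy in VINA RESULT"))
    at <- grep("^(ATOM|HETATM)", block, value = TRUE)
    if (length(at) == 0) abort(paste0("model ", i, " has no atom records"))
    coords <- map(at, function(l) {
      x <- suppressWarnings(as.numeric(substr(l, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(l, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(l, 47, 54)))
      fields <- strsplit(trimws(l), "\\s+")[[1]]
      adtype <- fields[length(fields)]
      if (anyNA(c(x, y, z))) abort(paste0("model ", i, ": unparseable atom line: ", l))
      tibble(element = adtype_element(adtype), x = x, y = y, z = z)
    }) |> bind_rows()
    com <- center_of_mass(coords, weighted = weighted)
    tibble(compound_id = compound_id, pose_id = as.character(i),
           x = com[["x"]], y = com[["y"]], z = com[["z"]],
           energy_kcal_mol = energy)
  })
  bind_rows(rows)
}
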