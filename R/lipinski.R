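# Rule-of-five descriptors and filter. MW, HBD and HBA are computed from
# the package's explicit-hydrogen molecular graph with a shipped atomic-mass
# table; logP uses a coarse per-element atom-contribution scheme whose
# contribution table is shipped in-package (see logp_contributions()).

# Per-element logP contributions (log units per atom). A deliberately
# coarse additive scheme: carbon and halogens are hydrophobic, N/O polar.
LOGP_CONTRIB <- c(
  H = 0.11, C = 0.36, N = -0.80, O = -1.00, S = 0.25, P = -0.50,
  F = 0.22, Cl = 0.65, Br = 0.85, I = 1.10, B = 0.10, Si = 0.30
)

#' The shipped logP atom-contribution table
#'
#' @return A tibble with `element` and `contribution` (additive log units
#'   per atom of that element, hydrogens included).
#' @export
logp_contributions <- function() {
  tibble(element = names(LOGP_CONTRIB), contribution = unname(LOGP_CONTRIB))
}

descriptor_row <- function(graph) {
  el <- graph$atoms
  unknown_mass <- setdiff(unique(el), names(ATOMIC_MASSES))
  if (length(unknown_mass)) {
    abort(paste0("unsupported element(s) in mass table: ",
                 paste(unknown_mass, collapse = ", ")))
  }
  unknown_lp <- setdiff(unique(el), names(LOGP_CONTRIB))
  if (length(unknown_lp)) {
    abort(paste0("unsupported element(s) in logP contribution table: ",
                 paste(unknown_lp, collapse = ", ")))
  }
  bonds <- graph$bonds
  # hydrogen-bond donors: hydrogens attached to N or O
  hbd <- 0L
  if (nrow(bonds)) {
    h_no <- (el[bonds$from] == "H" & el[bonds$to] %in% c("N", "O")) |
      (el[bonds$to] == "H" & el[bonds$from] %in% c("N", "O"))
    hbd <- sum(h_no)
  }
  tibble(
    mw = sum(atomic_mass(el)),
    logp = sum(LOGP_CONTRIB[el]),
    hbd = as.integer(hbd),
    hba = sum(el %in% c("N", "O"))
  )
}

#' Rule-of-five descriptors
#'
#' Computes, per compound: molecular weight (sum of standard atomic masses
#' including hydrogens, Da), logP (additive per-element contribution
#' scheme, see [logp_contributions()]), hydrogen-bond donors (count of O-H
#' and N-H hydrogens) and acceptors (count of N and O atoms — the classic
#' rule-of-five convention).
#'
#' @param compounds A `compound_set` from [parse_compounds()].
#' @return A tibble with `id`, `mw`, `logp`, `hbd`, `hba`.
#' @export
lipinski_descriptors <- function(compounds) {
  stopifnot(inherits(compounds, "compound_set"))
  bind_cols(select(as_tibble(compounds), "id"),
            bind_rows(map(compounds$graph, descriptor_row)))
}

#' Rule-of-five drug-likeness filter
#'
#' Counts violations over MW > 500 Da, logP > 5, HBD > 5, HBA > 10 and
#' retains compounds with at most `max_violations` of them. The original
#' heuristic flags compounds with two or more out-of-range properties, so
#' the default allowance is 1; strict mode is `max_violations = 0`.
#'
#' @param compounds A `compound_set`, or a descriptor table with columns
#'   `id`, `mw`, `logp`, `hbd`, `hba` (as from [lipinski_descriptors()]).
#' @param max_violations Maximum allowed violations (default 1).
#' @return A tibble with the descriptors, per-rule violation flags
#'   (`viol_mw`, `viol_logp`, `viol_hbd`, `viol_hba`), total `violations`,
#'   and `pass`.
#' @export
lipinski_filter <- function(compounds, max_violations = 1) {
  if (inherits(compounds, "compound_set")) {
    desc <- lipinski_descriptors(compounds)
  } else {
    desc <- as_tibble(compounds)
    needed <- c("id", "mw", "logp", "hbd", "hba")
    if (!all(needed %in% names(desc))) {
      abort("descriptor table needs columns id, mw, logp, hbd, hba")
    }
  }
  if (!is.numeric(max_violations) || max_violations < 0) {
    abort("`max_violations` must be a non-negative number")
  }
  desc |>
    mutate(
      viol_mw = .data$mw > 500,
      viol_logp = .data$logp > 5,
      viol_hbd = .data$hbd > 5,
      viol_hba = .data$hba > 10,
      violations = as.integer(.data$viol_mw) + as.integer(.data$viol_logp) +
        as.integer(.data$viol_hbd) + as.integer(.data$viol_hba),
      pass = .data$violations <= max_violations
    )
}
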