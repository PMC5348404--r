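# The screening cascade: similarity -> dockability -> binding-region
# specificity -> rule-of-five, with a per-stage survivor ledger.

#' Configure a screening cascade run
#'
#' @param library Compound library: a data frame with `id`/`smiles` (and
#'   optionally `family`), or a path to a .smi file.
#' @param reference Reference inhibitor SMILES.
#' @param poses Pose source: a pose tibble, a path to a pose TSV, or
#'   `"simulate"` to generate poses for the dockability stage's input
#'   compounds with [sim_poses()].
#' @param pose_sim Named list of overrides for [sim_poses()] when
#'   `poses = "simulate"`.
#' @param similarity_threshold Inclusive Tanimoto retention threshold.
#' @param fingerprint_bits,fingerprint_maxlen Fingerprint settings.
#' @param dockability_ceiling A compound is dockable iff it has at least
#'   one pose with energy <= this ceiling (kcal/mol, default -5).
#' @param cluster_cutoff Binding-region leader-clustering cutoff (Angstrom).
#' @param alpha FDR threshold on the specificity q-value.
#' @param max_violations Rule-of-five violation allowance.
#' @param min_batch Minimum specificity batch size.
#' @param seed Master seed; per-stage seeds are derived with [derive_seed()].
#' @return A `screen_config` list.
#' @export
screen_config <- function(library, reference,
                          poses = "simulate",
                          pose_sim = list(),
                          similarity_threshold = 0.6,
                          fingerprint_bits = 1024,
                          fingerprint_maxlen = 7,
                          dockability_ceiling = -5,
                          cluster_cutoff = 4,
                          alpha = 0.05,
                          max_violations = 1,
                          min_batch = 20,
                          seed = 1) {
  structure(
    list(
      library = library, reference = reference, poses = poses,
      pose_sim = pose_sim, similarity_threshold = similarity_threshold,
      fingerprint_bits = fingerprint_bits, fingerprint_maxlen = fingerprint_maxlen,
      dockability_ceiling = dockability_ceiling, cluster_cutoff = cluster_cutoff,
      alpha = alpha, max_violations = max_violations, min_batch = min_batch,
      seed = seed
    ),
    class = "screen_config"
  )
}

#' Packaged demonstration screen configuration
#'
#' A self-contained synthetic screen: a simulated library (reference +
#' analogs + decoys), simulated poses with a planted specificity gap for a
#' subset of compounds, and the default filter settings. The planted truth
#' tables travel with the report so recovery can be checked.
#'
#' @param seed Master seed.
#' @return A `screen_config`.
#' @export
demo_screen_config <- function(seed = 1) {
  lib <- sim_library(n_analogs = 60, n_decoys = 60, seed = derive_seed(seed, 101))
  screen_config(
    library = lib,
    reference = DEFAULT_REFERENCE_SMILES,
    poses = "simulate",
    pose_sim = list(specific_fraction = 0.15, planted_gap = 3,
                    background_energy_sd = 0.2),
    seed = seed
  )
}

#' Run the virtual screening cascade
#'
#' Stages, in order: (1) Tanimoto similarity to the reference (inclusive
#' threshold); (2) dockability — at least one pose at or below the energy
#' ceiling; (3) binding-region clustering of the dockable survivors' poses
#' and the specificity-gap significance test at `alpha`; (4) rule-of-five
#' filtering. The per-stage survivor ledger, full audit tables and the
#' final ranked candidates are returned. Fully deterministic given the
#' config (and its seed).
#'
#' @param config A `screen_config`.
#' @return A `cascade_report`: list with `ledger`, `candidates`,
#'   `similarity`, `specificity`, `lipinski`, `clustering`, `truth` (when
#'   poses were simulated), `config` and `status`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  library_tbl <- config$library
  if (is.character(library_tbl) && length(library_tbl) == 1) {
    library_tbl <- read_smi(library_tbl)
  }
  library_tbl <- as_tibble(library_tbl)
  ledger <- tibble(stage = character(), n_in = integer(), n_out = integer())
  note <- function(stage, n_in, n_out) {
    bind_rows(ledger, tibble(stage = stage, n_in = as.integer(n_in),
                             n_out = as.integer(n_out)))
  }
  empty_report <- function(status, candidates = NULL) {
    structure(
      list(ledger = ledger, candidates = candidates %||% tibble(),
           similarity = similarity, specificity = NULL, lipinski = NULL,
           clustering = NULL, truth = truth, config = config, status = status),
      class = "cascade_report"
    )
  }

  # stage 1: similarity
  compounds <- fingerprint_compounds(parse_compounds(library_tbl),
                                     n_bits = config$fingerprint_bits,
                                     max_len = config$fingerprint_maxlen)
  similarity <- similarity_screen(compounds, config$reference,
                                  threshold = config$similarity_threshold,
                                  n_bits = config$fingerprint_bits,
                                  max_len = config$fingerprint_maxlen)
  similar_ids <- similarity$id[similarity$pass]
  ledger <- note("similarity", nrow(library_tbl), length(similar_ids))
  truth <- NULL
  if (length(similar_ids) == 0) {
    warn("empty cascade: no compounds pass the similarity stage")
    return(empty_report("empty_after_similarity"))
  }

  # pose source for the dockability stage
  poses <- config$poses
  if (is.character(poses) && length(poses) == 1 && poses == "simulate") {
    sim_args <- utils::modifyList(
      list(compound_ids = sort(similar_ids), seed = derive_seed(config$seed, 202)),
      config$pose_sim
    )
    sim <- do.call(sim_poses, sim_args)
    poses <- sim$poses
    truth <- sim$truth
  } else if (is.character(poses)) {
    poses <- read_pose_table(poses)
  }
  poses <- as_tibble(poses)

  # stage 2: dockability
  dockable_ids <- poses |>
    filter(.data$compound_id %in% similar_ids,
           .data$energy_kcal_mol <= config$dockability_ceiling) |>
    pull(.data$compound_id) |>
    unique()
  ledger <- note("dockability", length(similar_ids), length(dockable_ids))
  if (length(dockable_ids) == 0) {
    warn("empty cascade: no compounds pass the dockability stage")
    return(empty_report("empty_after_dockability"))
  }

  # stage 3: binding-region clustering + specificity significance
  dock_poses <- filter(poses, .data$compound_id %in% dockable_ids)
  clustering <- cluster_poses(dock_poses, cutoff = config$cluster_cutoff)
  spec <- specificity_table(clustering) |>
    specificity_significance(min_batch = config$min_batch)
  specific_ids <- spec$compound_id[!spec$single_cluster & spec$q <= config$alpha]
  ledger <- note("specificity", length(dockable_ids), length(specific_ids))
  if (length(specific_ids) == 0) {
    warn("empty cascade: no compounds pass the specificity stage")
    rep <- empty_report("empty_after_specificity")
    rep$specificity <- spec
    rep$clustering <- clustering
    return(rep)
  }

  # stage 4: rule of five
  lip <- lipinski_filter(compounds[compounds$id %in% specific_ids, ],
                         max_violations = config$max_violations)
  final_ids <- lip$id[lip$pass]
  ledger <- note("lipinski", length(specific_ids), length(final_ids))

  candidates <- rank_candidates(spec, alpha = config$alpha) |>
    filter(.data$compound_id %in% final_ids)

  structure(
    list(ledger = ledger, candidates = candidates, similarity = similarity,
         specificity = spec, lipinski = lip, clustering = clustering,
         truth = truth, config = config, status = "ok"),
    class = "cascade_report"
  )
}

#' @method print cascade_report
#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report> status:", x$status, "\n")
  print(x$ledger)
  cat(nrow(x$candidates), "final candidate(s)\n")
  if (nrow(x$candidates)) print(x$candidates, n = 10)
  invisible(x)
}

#' @method tidy cascade_report
#' @export
tidy.cascade_report <- function(x, ...) x$candidates

#' @method glance cascade_report
#' @export
glance.cascade_report <- function(x, ...) {
  lg <- x$ledger
  tibble(
    n_library = if (nrow(lg)) lg$n_in[1] else 0L,
    n_similar = stage_count(lg, "similarity"),
    n_dockable = stage_count(lg, "dockability"),
    n_specific = stage_count(lg, "specificity"),
    n_candidates = nrow(x$candidates),
    status = x$status
  )
}

stage_count <- function(ledger, stage) {
  i <- match(stage, ledger$stage)
  if (is.na(i)) NA_integer_ else ledger$n_out[i]
}

#' Run the stage-stratified expression analysis
#'
#' Thin orchestration over [run_group_analysis()]: runs the per-(gene,
#' group) ANOVA, Stage-I-vs-normal contrast and permutation test, and adds
#' a human-readable `direction` column for the contrast (which way the
#' contrasted stages moved). With `n_perm = 0` the report is
#' parametric-only and the empirical columns are absent.
#'
#' @inheritParams run_group_analysis
#' @param out_path Optional TSV path for the report table.
#' @return The `stage_test` tibble with a `direction` column.
#' @export
run_expression <- function(dataset, genes = NULL, groups = NULL,
                           contrast = c(normal = -1, I = 1),
                           n_perm = 1000, seed = 1, out_path = NULL) {
  res <- run_group_analysis(dataset, genes = genes, groups = groups,
                            contrast = contrast, n_perm = n_perm, seed = seed)
  if (!is.null(contrast)) {
    res <- mutate(res, direction = dplyr::case_when(
      .data$contrast_estimate > 0 ~ "up",
      .data$contrast_estimate < 0 ~ "down",
      TRUE ~ "flat"
    ))
  }
  if (!is.null(out_path)) readr::write_tsv(res, out_path)
  res
}
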