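# Binding-specificity statistic and its significance. Per compound: the
# representative (minimum) energy within each binding region it reaches,
# the gap delta_E = E2 - E1 between the two lowest representative energies,
# and a z/p/q from an empirical conditional null — the location and spread
# of the gap are estimated locally along the energy-level axis
# A = (E1 + E2) / 2 across the screened batch (median / scaled MAD), in the
# spirit of MA-plot conditional testing.

#' Per-cluster representative energies of one compound
#'
#' For each binding region holding at least one pose of the compound, the
#' minimum member energy, sorted ascending (ties broken by cluster id).
#'
#' @param clustering A `binding_clusters` object.
#' @param compound_id Compound id.
#' @return A tibble with `cluster_id` and `energy`, sorted ascending.
#' @export
representative_energies <- function(clustering, compound_id) {
  stopifnot(inherits(clustering, "binding_clusters"))
  rows <- clustering$assignments[clustering$assignments$compound_id == compound_id, ]
  if (nrow(rows) == 0) {
    abort(paste0("compound `", compound_id, "` is absent from the cluster set"))
  }
  rows |>
    group_by(.data$cluster_id) |>
    summarise(energy = min(.data$energy_kcal_mol), .groups = "drop") |>
    arrange(.data$energy, .data$cluster_id)
}

#' Specificity gap from ordered representative energies
#'
#' `E1` is the lowest representative energy, `E2` the second lowest, and
#' `delta_e = E2 - E1 >= 0`. A compound reaching a single binding region
#' has no second energy; it is flagged (`single_cluster = TRUE`) and must
#' be excluded from the statistical batch.
#'
#' @param energies Numeric vector of representative energies sorted
#'   ascending (as from [representative_energies()]).
#' @return A one-row tibble with `e1`, `e2`, `delta_e`, `single_cluster`.
#' @export
specificity_gap <- function(energies) {
  if (is.data.frame(energies)) energies <- energies$energy
  if (length(energies) == 0) abort("empty energy collection")
  if (is.unsorted(energies)) abort("energies must be sorted ascending")
  if (length(energies) == 1) {
    return(tibble(e1 = energies[1], e2 = NA_real_, delta_e = NA_real_,
                  single_cluster = TRUE))
  }
  tibble(e1 = energies[1], e2 = energies[2],
         delta_e = energies[2] - energies[1], single_cluster = FALSE)
}

#' Specificity records for every compound in a clustering
#'
#' @param clustering A `binding_clusters` object.
#' @return A tibble with one row per compound: `compound_id`,
#'   `top_cluster_id` (region of E1), `n_clusters`, `e1`, `e2`, `delta_e`,
#'   `a` (= (E1+E2)/2, the conditioning axis), `single_cluster`.
#' @export
specificity_table <- function(clustering) {
  stopifnot(inherits(clustering, "binding_clusters"))
  clustering$assignments |>
    group_by(.data$compound_id, .data$cluster_id) |>
    summarise(energy = min(.data$energy_kcal_mol), .groups = "drop") |>
    arrange(.data$compound_id, .data$energy, .data$cluster_id) |>
    group_by(.data$compound_id) |>
    summarise(
      top_cluster_id = .data$cluster_id[1],
      n_clusters = n(),
      e1 = .data$energy[1],
      e2 = if (n() > 1) .data$energy[2] else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      delta_e = .data$e2 - .data$e1,
      a = (.data$e1 + .data$e2) / 2,
      single_cluster = is.na(.data$e2)
    )
}

#' Significance of specificity gaps under an empirical conditional null
#'
#' For each multi-region compound the gap `M = delta_e` is tested against
#' the other gaps at a comparable energy level `A = (E1+E2)/2`: the local
#' null is estimated over the window of the nearest `window_frac` of the
#' batch by `A` (at least `min_window` records, or the whole batch if
#' smaller), robustly — center = median, spread = `1.4826 * MAD`, both
#' floored at `epsilon`. The reported `z` is `(M - center) / spread`.
#'
#' The one-sided p-value (specificity is directional — only large positive
#' gaps count) comes from the configured null tail:
#' * `"exponential"` (default): `p = 2^(-M / median)`. A null gap is the
#'   spacing between the two smallest per-region minima, and spacings of
#'   order statistics are exponential-tailed, not normal-tailed; the
#'   exponential law with the window median as its median is the matching
#'   null family. A gap equal to the local median gets p = 0.5 exactly.
#' * `"normal"`: upper-tail normal p of `z`. Anti-conservative for this
#'   statistic (the gap null is right-skewed), kept for comparison.
#'
#' Benjamini-Hochberg q across the batch. Single-region compounds keep
#' `NA` statistics.
#'
#' @param records A specificity table from [specificity_table()].
#' @param window_frac Fraction of the batch in the local window (default 0.1).
#' @param min_window Minimum window size (default 50).
#' @param min_batch Minimum number of multi-region records required
#'   (default 20).
#' @param epsilon Center/spread floor in kcal/mol (default 1e-8).
#' @param tail Null tail model, `"exponential"` (default) or `"normal"`.
#' @return The records with `z`, `p`, `q` columns added.
#' @export
specificity_significance <- function(records, window_frac = 0.1,
                                     min_window = 50, min_batch = 20,
                                     epsilon = 1e-8,
                                     tail = c("exponential", "normal")) {
  tail <- match.arg(tail)
  records <- as_tibble(records)
  stopifnot(all(c("compound_id", "delta_e", "a", "single_cluster") %in% names(records)))
  batch <- records[!records$single_cluster, ]
  nb <- nrow(batch)
  if (nb < min_batch) {
    abort(sprintf("batch too small for null estimation: %d multi-region records < min_batch = %d",
                  nb, min_batch))
  }
  w <- min(nb, max(min_window, ceiling(window_frac * nb)))
  z <- numeric(nb)
  p <- numeric(nb)
  for (i in seq_len(nb)) {
    nn <- order(abs(batch$a - batch$a[i]))[seq_len(w)]
    m <- batch$delta_e[nn]
    center <- max(median(m), epsilon)
    spread <- max(1.4826 * median(abs(m - center)), epsilon)
    if (spread <= 0) abort("zero spread after flooring")
    z[i] <- (batch$delta_e[i] - center) / spread
    p[i] <- if (tail == "exponential") {
      2^(-batch$delta_e[i] / center)
    } else {
      pnorm(z[i], lower.tail = FALSE)
    }
  }
  batch$z <- z
  batch$p <- p
  batch$q <- p.adjust(batch$p, method = "BH")
  records |>
    left_join(batch[c("compound_id", "z", "p", "q")], by = "compound_id")
}

#' Rank screened candidates
#'
#' Sorts by (q, then larger gap first) and keeps records with `q <= alpha`,
#' or the `top_k` best. One of `alpha`/`top_k` must be given.
#'
#' @param records Output of [specificity_significance()].
#' @param alpha FDR threshold on q.
#' @param top_k Alternatively, number of top records to keep.
#' @return The ranked candidate tibble with columns `compound_id`,
#'   `top_cluster_id`, `e1`, `e2`, `delta_e`, `p`, `q`.
#' @export
rank_candidates <- function(records, alpha = NULL, top_k = NULL) {
  if (is.null(alpha) && is.null(top_k)) abort("give `alpha` or `top_k`")
  ranked <- records |>
    filter(!.data$single_cluster) |>
    arrange(.data$q, desc(.data$delta_e), .data$compound_id) |>
    select("compound_id", "top_cluster_id", "e1", "e2", "delta_e", "p", "q")
  if (!is.null(alpha)) ranked <- filter(ranked, .data$q <= alpha)
  if (!is.null(top_k)) ranked <- head(ranked, top_k)
  ranked
}
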