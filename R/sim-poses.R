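# Synthetic docking poses: K binding sites with isotropic Gaussian
# positional scatter, Gaussian background energies, and a planted
# specificity gap (extra energy depth at one designated site) for a
# configurable fraction of compounds. The designated site and specificity
# flag of every compound are returned as a truth table.

# Deterministically place K site centers on a jittered cubic grid with
# pairwise separation >= 5 * scatter_sd (and at least `min_sep`).
place_site_centers <- function(n_sites, scatter_sd, min_sep = 10) {
  d <- max(5 * scatter_sd, min_sep)
  side <- ceiling(n_sites^(1 / 3))
  grid <- tidyr::expand_grid(i = seq_len(side), j = seq_len(side), k = seq_len(side))
  grid <- grid[seq_len(n_sites), ]
  cbind(x = grid$i * d * 1.2, y = grid$j * d * 1.2, z = grid$k * d * 1.2)
}

#' Simulate docked poses over planted binding sites
#'
#' Each pose's center of mass is its site center plus isotropic Gaussian
#' scatter; energies are Gaussian background draws. For compounds flagged
#' specific, every pose at the compound's designated site is deepened by
#' `planted_gap` kcal/mol, so the per-site minimum at that site sits about
#' `planted_gap` below the best other site.
#'
#' @param n_compounds Number of compounds (ignored when `compound_ids` given).
#' @param compound_ids Optional explicit compound ids.
#' @param n_sites Number of binding sites K.
#' @param site_centers Optional K x 3 matrix of centers (Angstrom);
#'   auto-placed on a well-separated grid when NULL. Centers closer than
#'   `5 * site_scatter_sd` are rejected.
#' @param site_scatter_sd Isotropic positional scatter per site (Angstrom).
#' @param poses_per_compound Poses per compound; spread round-robin over
#'   sites so every compound visits several sites.
#' @param background_energy_mean,background_energy_sd Energy law (kcal/mol;
#'   negative = favorable).
#' @param specific_fraction Fraction of compounds with a planted gap.
#' @param planted_gap Extra depth (kcal/mol, >= 0) at the designated site.
#' @param seed Integer seed.
#' @return A list with `poses` (canonical pose tibble), `truth` (tibble
#'   `compound_id`, `designated_site`, `specific`) and `site_centers`.
#' @export
sim_poses <- function(n_compounds = 100,
                      compound_ids = NULL,
                      n_sites = 4,
                      site_centers = NULL,
                      site_scatter_sd = 1.0,
                      poses_per_compound = 8,
                      background_energy_mean = -7,
                      background_energy_sd = 0.2,
                      specific_fraction = 0.05,
                      planted_gap = 3,
                      seed = 1) {
  if (is.null(compound_ids)) {
    check_positive_int(n_compounds, "n_compounds")
    compound_ids <- sprintf("CMPD%04d", seq_len(n_compounds))
  }
  n_compounds <- length(compound_ids)
  check_positive_int(n_sites, "n_sites")
  check_positive_int(poses_per_compound, "poses_per_compound")
  if (specific_fraction < 0 || specific_fraction > 1) {
    abort("`specific_fraction` must lie in [0, 1]")
  }
  if (planted_gap < 0) abort("`planted_gap` must be >= 0")
  if (is.null(site_centers)) {
    site_centers <- place_site_centers(n_sites, site_scatter_sd)
  } else {
    site_centers <- as.matrix(site_centers)
    if (nrow(site_centers) != n_sites || ncol(site_centers) != 3) {
      abort("`site_centers` must be an n_sites x 3 matrix")
    }
  }
  if (n_sites > 1) {
    dmin <- min(dist(site_centers))
    if (dmin < 5 * site_scatter_sd) {
      abort(sprintf(
        "site centers too close: min separation %.2f < 5 * scatter_sd = %.2f",
        dmin, 5 * site_scatter_sd
      ))
    }
  }

  withr::with_seed(seed, {
    n_specific <- round(specific_fraction * n_compounds)
    specific <- rep(FALSE, n_compounds)
    if (n_specific > 0) specific[sample.int(n_compounds, n_specific)] <- TRUE
    designated <- sample.int(n_sites, n_compounds, replace = TRUE)

    rows <- map(seq_len(n_compounds), function(ci) {
      # round-robin site assignment from a random starting rotation, so a
      # compound with >= n_sites poses visits every site
      rot <- sample.int(n_sites, 1)
      site <- ((rot + seq_len(poses_per_compound) - 2) %% n_sites) + 1
      com <- site_centers[site, , drop = FALSE] +
        matrix(rnorm(3 * poses_per_compound, 0, site_scatter_sd),
               poses_per_compound, 3)
      energy <- rnorm(poses_per_compound, background_energy_mean, background_energy_sd)
      if (specific[ci]) {
        hit <- site == designated[ci]
        if (!any(hit)) { # ensure the designated site is represented
          hit <- seq_len(poses_per_compound) == 1
          site[1] <- designated[ci]
          com[1, ] <- site_centers[designated[ci], ] + rnorm(3, 0, site_scatter_sd)
        }
        energy[hit] <- energy[hit] - planted_gap
      }
      tibble(
        compound_id = compound_ids[ci],
        pose_id = as.character(seq_len(poses_per_compound)),
        x = com[, 1], y = com[, 2], z = com[, 3],
        energy_kcal_mol = energy,
        true_site = site
      )
    })
  })
  poses <- bind_rows(rows)
  list(
    poses = poses[POSE_COLUMNS],
    pose_truth = poses[c("compound_id", "pose_id", "true_site")],
    truth = tibble(compound_id = compound_ids,
                   designated_site = designated,
                   specific = specific),
    site_centers = site_centers
  )
}
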