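# Binding-region clustering: deterministic energy-ordered leader clustering
# of pose centers of mass. A pose joins the first existing cluster whose
# representative (lowest-energy, i.e. founding) pose lies within the cutoff,
# otherwise it founds a new cluster. Because poses are processed in
# ascending energy order, each cluster's founder is its minimum-energy
# member; cluster ids 1..K follow ascending representative energy, so
# cluster 1 is the deepest binding region.

#' Cluster docked poses into binding regions
#'
#' @param poses A pose tibble (columns `compound_id`, `pose_id`, `x`, `y`,
#'   `z`, `energy_kcal_mol`).
#' @param cutoff Leader distance cutoff in Angstrom (default 4.0). A pose
#'   within `cutoff` of an existing cluster representative joins it.
#' @return A `binding_clusters` object: list with `cutoff`, `assignments`
#'   (pose tibble plus `cluster_id`) and `clusters` (per-cluster summary:
#'   centroid, member count, representative pose and energy).
#' @export
cluster_poses <- function(poses, cutoff = 4.0) {
  poses <- as_tibble(poses)
  stopifnot(all(POSE_COLUMNS %in% names(poses)))
  if (nrow(poses) == 0) abort("need at least one pose")
  if (!is.numeric(cutoff) || cutoff < 0) abort("`cutoff` must be >= 0")

  # processing order: energy ascending, ties by compound_id then pose_id
  ord <- order(poses$energy_kcal_mol, poses$compound_id, poses$pose_id)
  P <- as.matrix(poses[ord, c("x", "y", "z")])
  n <- nrow(P)
  cluster_of <- integer(n)
  rep_xyz <- matrix(NA_real_, n, 3) # representative COM per cluster
  k <- 0
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (k > 0) {
      d2 <- (rep_xyz[seq_len(k), 1] - P[i, 1])^2 +
        (rep_xyz[seq_len(k), 2] - P[i, 2])^2 +
        (rep_xyz[seq_len(k), 3] - P[i, 3])^2
      hit <- which(d2 <= cutoff^2)
      if (length(hit)) {
        cluster_of[i] <- hit[1]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      k <- k + 1
      rep_xyz[k, ] <- P[i, ]
      cluster_of[i] <- k
    }
  }

  assignments <- poses[ord, ]
  assignments$cluster_id <- cluster_of
  assignments <- arrange(assignments, .data$compound_id, .data$pose_id)

  clusters <- assignments |>
    group_by(.data$cluster_id) |>
    summarise(
      n_members = n(),
      centroid_x = mean(.data$x), centroid_y = mean(.data$y),
      centroid_z = mean(.data$z),
      representative_energy = min(.data$energy_kcal_mol),
      representative_compound = .data$compound_id[which.min(.data$energy_kcal_mol)],
      representative_pose = .data$pose_id[which.min(.data$energy_kcal_mol)],
      .groups = "drop"
    ) |>
    arrange(.data$representative_energy, .data$cluster_id)
  # renumber 1..K by ascending representative energy
  remap <- setNames(seq_len(nrow(clusters)), clusters$cluster_id)
  clusters$cluster_id <- as.integer(remap[as.character(clusters$cluster_id)])
  assignments$cluster_id <- as.integer(remap[as.character(assignments$cluster_id)])
  clusters <- arrange(clusters, .data$cluster_id)

  structure(
    list(cutoff = cutoff, assignments = assignments, clusters = clusters),
    class = "binding_clusters"
  )
}

#' @method print binding_clusters
#' @export
print.binding_clusters <- function(x, ...) {
  cat(sprintf("<binding_clusters> %d poses in %d clusters (cutoff %.1f A)\n",
              nrow(x$assignments), nrow(x$clusters), x$cutoff))
  print(x$clusters, n = 10)
  invisible(x)
}

#' @method tidy binding_clusters
#' @export
tidy.binding_clusters <- function(x, ...) x$assignments

#' @method glance binding_clusters
#' @export
glance.binding_clusters <- function(x, ...) {
  tibble(
    n_poses = nrow(x$assignments),
    n_clusters = nrow(x$clusters),
    cutoff = x$cutoff,
    deepest_energy = min(x$clusters$representative_energy)
  )
}

#' Write cluster membership and summary TSVs
#'
#' @param clustering A `binding_clusters` object.
#' @param membership_path,summary_path Output file paths (either may be
#'   NULL to skip).
#' @export
write_clusters <- function(clustering, membership_path = NULL, summary_path = NULL) {
  stopifnot(inherits(clustering, "binding_clusters"))
  if (!is.null(membership_path)) {
    readr::write_tsv(clustering$assignments[c("compound_id", "pose_id", "cluster_id")],
                     membership_path)
  }
  if (!is.null(summary_path)) {
    readr::write_tsv(clustering$clusters, summary_path)
  }
  invisible(clustering)
}
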