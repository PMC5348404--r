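# Shared fixtures, all built in code.

# Tiny three-level toy with hand-checkable sums of squares:
# groups {1,2}, {3,4}, {5,6}: SSB = 16, SSW = 1.5, F = 16, df (2, 3).
toy_anova <- function() {
  list(x = c(1, 2, 3, 4, 5, 6), g = factor(rep(c("a", "b", "c"), each = 2)))
}

# Small two-level vector for exhaustive-permutation comparisons (20 distinct
# label assignments).
toy_two_level <- function() {
  list(x = c(1.3, 2.1, 0.7, 3.5, 4.2, 3.9), g = factor(rep(1:2, each = 3)))
}

# Exact permutation p-value by full enumeration of the distinct two-level
# assignments (choose(6, 3) = 20), the brute-force oracle for the sampled
# permutation test.
exact_perm_p <- function(x, g) {
  n <- length(x)
  k <- sum(g == levels(g)[1])
  f_obs <- f_oneway(x, g)$f
  combos <- utils::combn(n, k)
  fs <- apply(combos, 2, function(idx) {
    gg <- factor(ifelse(seq_len(n) %in% idx, "a", "b"))
    f_oneway(x, gg)$f
  })
  mean(fs > f_obs)
}

# A two-model Vina-style PDBQT text fixture (energies -7.1 and -6.3).
vina_fixture_text <- function() {
  c(
    "MODEL 1",
    "REMARK VINA RESULT:      -7.1      0.000      0.000",
    "ATOM      1  C   LIG A   1       1.000   2.000   3.000  0.00  0.00    +0.000 C ",
    "ATOM      2  O   LIG A   1       2.000   2.000   3.000  0.00  0.00    +0.000 OA",
    "ENDMDL",
    "MODEL 2",
    "REMARK VINA RESULT:      -6.3      0.000      0.000",
    "ATOM      1  C   LIG A   1      10.000  10.000  10.000  0.00  0.00    +0.000 C ",
    "ENDMDL"
  )
}

# Pose table with two tight planted sites for clustering checks.
two_site_poses <- function(seed = 1, n_compounds = 12, scatter = 0.5,
                           separation = 20) {
  sim_poses(
    n_compounds = n_compounds, n_sites = 2,
    site_centers = rbind(c(0, 0, 0), c(separation, 0, 0)),
    site_scatter_sd = scatter, poses_per_compound = 4,
    specific_fraction = 0, seed = seed
  )
}

# Partition labels from single-linkage connected components at a cutoff,
# the independent oracle for leader clustering in the well-separated regime.
single_linkage_labels <- function(poses, cutoff) {
  d <- dist(as.matrix(poses[, c("x", "y", "z")]))
  cutree(hclust(d, method = "single"), h = cutoff)
}

# TRUE iff two integer label vectors induce the same partition.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
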