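# Helper building a minimal records batch by hand.
records_batch <- function(delta, a = rep(-7, length(delta)),
                          ids = sprintf("c%03d", seq_along(delta))) {
  tibble::tibble(
    compound_id = ids, top_cluster_id = 1L, n_clusters = 2L,
    e1 = a - delta / 2, e2 = a + delta / 2,
    delta_e = delta, a = a, single_cluster = FALSE
  )
}

test_that("representative energies: per-cluster minima, order, tie rule", {
  poses <- tibble::tibble(
    compound_id = "c1", pose_id = as.character(1:6),
    x = c(0, 0, 20, 20, 40, 40), y = 0, z = 0,
    energy_kcal_mol = c(-9.1, -6.0, -6.0, -5.8, -5.5, -5.0)
  )
  cl <- cluster_poses(poses, cutoff = 4)
  re <- representative_energies(cl, "c1")
  expect_equal(re$energy, c(-9.1, -6.0, -5.5))
  expect_false(is.unsorted(re$energy))
  expect_error(representative_energies(cl, "ghost"), "absent")

  # equal minima in two clusters: deterministic order by cluster_id
  tied <- tibble::tibble(
    compound_id = "c1", pose_id = as.character(1:3),
    x = c(0, 20, 40), y = 0, z = 0,
    energy_kcal_mol = c(-7, -6, -6)
  )
  cl2 <- cluster_poses(tied, cutoff = 4)
  re2 <- representative_energies(cl2, "c1")
  expect_equal(re2$energy, c(-7, -6, -6))
  expect_equal(re2$cluster_id[2:3], sort(re2$cluster_id[2:3]))
})

test_that("specificity gap: hand values, degeneracies, translation invariance", {
  gap <- specificity_gap(c(-9.1, -6.0, -5.5))
  expect_equal(gap$e1, -9.1)
  expect_equal(gap$e2, -6.0)
  expect_equal(gap$delta_e, 3.1)
  expect_false(gap$single_cluster)

  expect_equal(specificity_gap(c(-5, -5))$delta_e, 0)
  expect_true(specificity_gap(-7.2)$single_cluster)
  expect_error(specificity_gap(numeric()), "empty")
  expect_error(specificity_gap(c(-5, -9)), "ascending")

  # uniform energy shift leaves the gap unchanged
  shifted <- specificity_gap(c(-9.1, -6.0, -5.5) + 2.5)
  expect_equal(shifted$delta_e, 3.1, tolerance = 1e-12)
})

test_that("significance: degenerate batch, monotonicity, batch guards", {
  # identical gaps and levels: z = 0 and p = 0.5 for everyone
  rec <- records_batch(rep(0.3, 25))
  out <- specificity_significance(rec, min_window = 10)
  expect_true(all(out$z == 0))
  expect_true(all(out$p == 0.5))

  # at fixed A, p strictly decreases as the gap grows
  rec2 <- records_batch(seq(0.05, 2.5, length.out = 40))
  out2 <- specificity_significance(rec2, min_window = 40)
  expect_true(all(diff(out2$p) < 0))
  expect_true(all(diff(order(out2$z)) > 0) || all(diff(out2$z) > 0))

  # BH: q in [p, 1], monotone in p
  expect_true(all(out2$q >= out2$p - 1e-12))
  expect_true(all(out2$q <= 1))
  expect_true(all(diff(out2$q[order(out2$p)]) >= -1e-12))

  expect_error(specificity_significance(records_batch(rep(0.1, 5))),
               "batch too small")
})

test_that("batch translation invariance of z and p", {
  withr::with_seed(6, delta <- rexp(30, 5))
  a <- seq(-8, -6, length.out = 30)
  base <- specificity_significance(records_batch(delta, a), min_window = 15)
  shifted <- specificity_significance(records_batch(delta, a - 3), min_window = 15)
  expect_equal(base$z, shifted$z, tolerance = 1e-12)
  expect_equal(base$p, shifted$p, tolerance = 1e-12)
})

test_that("planted screen: the specific compounds attain the smallest q values", {
  sim <- sim_poses(n_compounds = 100, specific_fraction = 0.05,
                   planted_gap = 3, background_energy_sd = 0.2, seed = 11)
  cl <- cluster_poses(sim$poses, cutoff = 4)
  sp <- specificity_significance(specificity_table(cl))
  planted <- sim$truth$compound_id[sim$truth$specific]
  ranked <- sp[!sp$single_cluster, ]
  ranked <- ranked[order(ranked$q, -ranked$delta_e), ]
  expect_setequal(ranked$compound_id[1:5], planted)
  expect_true(all(ranked$q[1:5] < 0.05))

  # single-cluster compounds are excluded from the batch, not scored
  one_region <- tibble::tibble(
    compound_id = "solo", pose_id = "1", x = 0, y = 0, z = 0,
    energy_kcal_mol = -8
  )
  tab <- specificity_table(cluster_poses(one_region, cutoff = 4))
  expect_true(tab$single_cluster)
})

test_that("candidate ranking: sorting, ties, survivor rules", {
  rec <- records_batch(c(0.1, 0.2, 2.0, 2.5), ids = c("a", "b", "c", "d"))
  out <- specificity_significance(rec, min_window = 4, min_batch = 4)
  ranked <- rank_candidates(out, alpha = 1)
  expect_equal(nrow(ranked), 4)
  expect_false(is.unsorted(ranked$q))

  # equal q: larger gap first
  tied <- out
  tied$q <- 0.01
  ranked2 <- rank_candidates(tied, alpha = 0.05)
  expect_equal(ranked2$compound_id[1], "d")
  expect_equal(ranked2$delta_e, sort(ranked2$delta_e, decreasing = TRUE))

  top2 <- rank_candidates(out, top_k = 2)
  expect_equal(nrow(top2), 2)
  expect_error(rank_candidates(out), "alpha.*top_k|top_k.*alpha")
})
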