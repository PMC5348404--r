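test_that("one-way ANOVA matches hand sums of squares and stats::lm", {
  toy <- toy_anova()
  res <- f_oneway(toy$x, toy$g)
  expect_equal(res$f, 16)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 3L)

  # cross-check against the reference linear-model ANOVA on random data
  withr::with_seed(7, {
    for (i in 1:5) {
      x <- rnorm(30)
      g <- factor(sample(letters[1:4], 30, replace = TRUE))
      if (nlevels(droplevels(g)) < 2) next
      mine <- f_oneway(x, g)
      ref <- anova(lm(x ~ g))
      expect_equal(mine$f, ref$`F value`[1], tolerance = 1e-10)
      expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    }
  })
})

test_that("ANOVA edge semantics: zero F, location invariance, degeneracy", {
  res <- f_oneway(c(1, 2, 3, 1, 2, 3), factor(rep(1:2, each = 3)))
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)

  toy <- toy_anova()
  shifted <- f_oneway(toy$x + 100, toy$g)
  expect_equal(shifted$f, 16, tolerance = 1e-8)

  expect_error(f_oneway(rep(2, 6), factor(rep(1:2, each = 3))), "degenerate")
  expect_error(f_oneway(1:6, factor(rep(1, 6))), "2 factor levels")
})

test_that("planned contrast: hand value, zero case, two-sample equivalence", {
  toy <- toy_anova()
  ct <- contrast_oneway(toy$x, toy$g, c(a = -1, c = 1))
  expect_equal(ct$estimate, 4)
  expect_equal(ct$t, 4 / sqrt(0.5), tolerance = 1e-6) # 5.657 with MSE 0.5
  expect_equal(ct$df, 3L)

  # identical level values -> estimate 0, p = 1
  x0 <- c(5, 6, 5, 6, 9, 9.5)
  ct0 <- contrast_oneway(x0, factor(rep(c("n", "I", "x"), each = 2)),
                         c(n = -1, I = 1))
  expect_equal(ct0$estimate, 0)
  expect_equal(ct0$p, 1)

  # two levels only: identical to the pooled-variance two-sample t test
  withr::with_seed(3, {
    x <- rnorm(14)
    g <- factor(rep(c("a", "b"), each = 7))
    ct2 <- contrast_oneway(x, g, c(a = -1, b = 1))
    tt <- t.test(x ~ g, var.equal = TRUE)
    expect_equal(abs(ct2$t), abs(tt$statistic[[1]]), tolerance = 1e-10)
    expect_equal(ct2$p, tt$p.value, tolerance = 1e-10)
  })

  expect_error(contrast_oneway(toy$x, toy$g, c(a = 1, c = 1)), "sum to 0")
  expect_error(contrast_oneway(toy$x, toy$g, c(zz = -1, a = 1)), "absent level")
})

test_that("permutation p-value is deterministic and matches exhaustive enumeration", {
  toy <- toy_two_level()
  p1 <- perm_f_pvalue(toy$x, toy$g, n_perm = 300, seed = 11)
  p2 <- perm_f_pvalue(toy$x, toy$g, n_perm = 300, seed = 11)
  expect_identical(p1, p2)
  expect_equal(p1$p_empirical * p1$n_perm, round(p1$p_empirical * p1$n_perm))

  exact <- exact_perm_p(toy$x, toy$g)
  sampled <- perm_f_pvalue(toy$x, toy$g, n_perm = 4000, seed = 5)$p_empirical
  expect_lt(abs(sampled - exact), 0.03)
})

test_that("permutation p-value: overwhelming effect, smoothing, relabeling", {
  withr::with_seed(9, {
    x <- c(rnorm(10, 0), rnorm(10, 100))
    g <- factor(rep(1:2, each = 10))
  })
  strict <- perm_f_pvalue(x, g, n_perm = 1000, seed = 2)
  expect_equal(strict$p_empirical, 0)
  smooth <- perm_f_pvalue(x, g, n_perm = 1000, seed = 2, smooth = TRUE)
  expect_equal(smooth$p_empirical, 1 / 1001)

  # renaming stage levels must not change the p-value
  toy <- toy_two_level()
  pa <- perm_f_pvalue(toy$x, toy$g, n_perm = 500, seed = 4)$p_empirical
  relabeled <- factor(c("IV", "normal")[as.integer(toy$g)])
  pb <- perm_f_pvalue(toy$x, relabeled, n_perm = 500, seed = 4)$p_empirical
  expect_equal(pa, pb)
})

test_that("dataset wrappers and run_group_analysis wire genes and groups correctly", {
  effects <- tibble::tibble(
    gene_id = "RHOA_like", group = "g1", stage = "I", log2_shift = 3
  )
  ds <- sim_expression(
    n_genes = 5, samples_per_stage = 8, groups = c("g1", "g2"),
    effects = effects, seed = 21
  ) |> log2_transform()

  res <- run_group_analysis(ds, genes = "RHOA_like", groups = c("g1", "g2"),
                            n_perm = 400, seed = 13)
  expect_s3_class(res, "stage_test")
  expect_equal(nrow(res), 2)
  r1 <- res[res$group == "g1", ]
  r2 <- res[res$group == "g2", ]
  # planted Stage-I effect in g1 only
  expect_lte(r1$p_empirical, 0.05)
  expect_gt(r2$p_empirical, 0.05)
  expect_gt(r1$contrast_estimate, 1)

  # singleton wrapper agrees with the underlying per-gene operations
  single <- permutation_f_test(ds, "RHOA_like", group = "g1",
                               n_perm = 400, seed = r1$seed)
  expect_equal(single$p_empirical, r1$p_empirical)
  an <- anova_stage(ds, "RHOA_like", group = "g1")
  expect_equal(an$f, r1$f_obs)

  expect_error(run_group_analysis(ds, genes = "nope"), "unknown gene")
  expect_error(run_group_analysis(ds, groups = "nope"), "unknown group")
  expect_error(anova_stage(ds, "missing_gene"), "available genes")

  # parametric-only mode drops the empirical columns
  res0 <- run_expression(ds, genes = "RHOA_like", n_perm = 0, seed = 1)
  expect_false("p_empirical" %in% names(res0))
  expect_true("direction" %in% names(res0))
  expect_equal(res0$direction[res0$group == "g1"], "up")
})

test_that("log2 transform: values, monotonicity, re-transform guard", {
  ds <- expr_dataset(
    tibble::tibble(gene_id = c("g1", "g2"), s1 = c(0, 7), s2 = c(3, 1)),
    tibble::tibble(sample_id = c("s1", "s2"), stage = c("normal", "I"),
                   group = "g")
  )
  tr <- log2_transform(ds, pseudocount = 1)
  expect_equal(tr$values$s1, c(0, 3)) # log2(0+1)=0, log2(7+1)=3
  expect_equal(tr$values$s2, log2(c(4, 2)))
  expect_true(all(order(ds$values$s1) == order(tr$values$s1)))
  expect_error(log2_transform(tr), "already")
  expect_error(expr_dataset(
    tibble::tibble(gene_id = "g", s1 = -1),
    tibble::tibble(sample_id = "s1", stage = "I", group = "g")
  ), "non-negative")
})
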