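test_that("expression generator: determinism, annotations, planted shifts", {
  ds1 <- sim_expression(n_genes = 20, samples_per_stage = 3, seed = 5)
  ds2 <- sim_expression(n_genes = 20, samples_per_stage = 3, seed = 5)
  expect_identical(ds1$values, ds2$values)
  expect_identical(ds1$meta, ds2$meta)
  ds3 <- sim_expression(n_genes = 20, samples_per_stage = 3, seed = 6)
  expect_false(identical(ds1$values, ds3$values))

  # non-negative raw values, complete annotations
  mat <- as.matrix(ds1$values[-1])
  expect_true(all(mat >= 0))
  expect_equal(nrow(ds1$meta), 2 * 5 * 3) # 2 groups x 5 stages x 3 samples
  expect_setequal(unique(ds1$meta$stage), c("normal", "I", "II", "III", "IV"))

  # a planted +4 shift moves the group/stage mean by about that much (log2)
  effects <- tibble::tibble(gene_id = "hit", group = "asian",
                            stage = "I", log2_shift = 4)
  ds <- sim_expression(n_genes = 10, samples_per_stage = 30,
                       effects = effects, noise_sd = 1, seed = 8) |>
    log2_transform(pseudocount = 1e-9)
  td <- tidy(ds)
  hit <- td[td$gene_id == "hit", ]
  m_planted <- mean(hit$value[hit$stage == "I" & hit$group == "asian"])
  m_rest <- mean(hit$value[hit$stage == "normal" & hit$group == "asian"])
  expect_equal(m_planted - m_rest, 4, tolerance = 1)
  # other group untouched
  m_other <- mean(hit$value[hit$stage == "I" & hit$group == "caucasian"]) -
    mean(hit$value[hit$stage == "normal" & hit$group == "caucasian"])
  expect_lt(abs(m_other), 1)

  expect_error(sim_expression(effects = tibble::tibble(
    gene_id = "g", group = "asian", stage = "nope", log2_shift = 1
  )), "invalid stage")
  expect_error(sim_expression(anticorr_pairs = tibble::tibble(
    gene1 = "g0001", gene2 = "g0002", rho = -1.5
  )), "rho")
})

test_that("anti-correlated pair attains its target correlation", {
  pairs <- tibble::tibble(gene1 = "g0001", gene2 = "g0002", rho = -0.8)
  ds <- sim_expression(
    n_genes = 2, samples_per_stage = 50, anticorr_pairs = pairs, seed = 12
  ) |> log2_transform(pseudocount = 1e-9)
  v <- ds$values
  r <- cor(as.numeric(v[1, -1]), as.numeric(v[2, -1]))
  expect_equal(r, -0.8, tolerance = 0.1) # 500 samples
})

test_that("expression TSV round trip preserves the dataset", {
  ds <- sim_expression(n_genes = 6, samples_per_stage = 2, seed = 3)
  m <- withr::local_tempfile(fileext = ".tsv")
  s <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ds, m, s)
  back <- read_expression(m, s)
  expect_equal(as.data.frame(back$values), as.data.frame(ds$values),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$meta), as.data.frame(ds$meta))
})

test_that("pose generator: determinism, truth flags, separation guard", {
  a <- sim_poses(n_compounds = 8, seed = 3)
  b <- sim_poses(n_compounds = 8, seed = 3)
  expect_identical(a$poses, b$poses)
  expect_identical(a$truth, b$truth)

  none <- sim_poses(n_compounds = 10, specific_fraction = 0, seed = 2)
  expect_false(any(none$truth$specific))

  # planted_gap = 0: specific flag exists but energies follow the same law
  flat <- sim_poses(n_compounds = 40, specific_fraction = 0.5,
                    planted_gap = 0, poses_per_compound = 4, seed = 7)
  merged <- dplyr::left_join(flat$poses, flat$truth, by = "compound_id")
  ks <- suppressWarnings(stats::ks.test(
    merged$energy_kcal_mol[merged$specific],
    merged$energy_kcal_mol[!merged$specific]
  ))
  expect_gt(ks$p.value, 0.01)

  expect_error(
    sim_poses(n_sites = 2, site_centers = rbind(c(0, 0, 0), c(1, 0, 0)),
              site_scatter_sd = 1),
    "too close"
  )
  expect_error(sim_poses(specific_fraction = 1.5), "specific_fraction")
  expect_error(sim_poses(planted_gap = -1), "planted_gap")
})

test_that("library generator: composition, validity, determinism, edge cases", {
  lib <- sim_library(n_analogs = 8, n_decoys = 8, seed = 4)
  expect_equal(nrow(lib), 17)
  expect_equal(sum(lib$family == "reference"), 1)
  # every emitted SMILES parses
  expect_silent(parsed <- parse_compounds(lib))
  expect_equal(nrow(parsed), 17)

  expect_identical(sim_library(n_analogs = 5, n_decoys = 5, seed = 9),
                   sim_library(n_analogs = 5, n_decoys = 5, seed = 9))

  only_ref <- sim_library(n_analogs = 0, n_decoys = 0, seed = 1)
  expect_equal(nrow(only_ref), 1)
  expect_equal(only_ref$family, "reference")

  expect_error(sim_library(reference_smiles = "C("), "unclosed")

  # analogs resemble the reference far more than decoys do
  scr <- similarity_screen(lib, lib$smiles[1], threshold = 0)
  res <- dplyr::left_join(scr, lib[c("id", "family")], by = "id")
  expect_gt(median(res$tanimoto[res$family == "analog"]),
            median(res$tanimoto[res$family == "decoy"]))
})
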