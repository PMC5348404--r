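test_that("SMILES parsing: structures, canonical equivalence, malformed input", {
  cmp <- parse_compounds(c(methane = "C", benzene = "c1ccccc1", methanol = "CO"))
  expect_s3_class(cmp, "compound_set")
  # methane: one carbon plus 4 implicit hydrogens made explicit
  g <- cmp$graph[[1]]
  expect_equal(sort(table(g$atoms)), sort(table(c("C", rep("H", 4)))))
  # benzene: 6 aromatic carbons, 6 hydrogens
  expect_equal(sum(cmp$graph[[2]]$atoms == "C"), 6)

  # malformed inputs error and name the offending token
  expect_error(parse_compounds(c(bad = "C(")), "unclosed")
  expect_error(parse_compounds(c(bad = "C)C")), "unmatched")
  expect_error(parse_compounds(c(bad = "C1CC")), "ring-closure")
  expect_error(parse_compounds(c(bad = "xyz")), "valid molecule")
  expect_error(parse_compounds(c(a = "C", a = "C")), "unique")
})

test_that("fingerprints: canonical invariance, single atoms, path enumeration", {
  fp_of <- function(smi) {
    fingerprint_compounds(parse_compounds(c(m = smi)))$fingerprint[[1]]
  }
  # equivalent SMILES spellings give identical bitsets
  expect_identical(fp_of("c1ccccc1"), fp_of("C1=CC=CC=C1"))
  expect_identical(fp_of("OCC"), fp_of("CCO"))

  # single heavy atom still sets a bit
  expect_gte(length(fp_of("C")), 1)

  # hand path enumeration: ethane has labels {C, C-C} (2), ethanol
  # {C, O, C-C, C-O, C-C-O} (5); distinct molecules, distinct bitsets
  fp_ethane <- fp_of("CC")
  fp_ethanol <- fp_of("CCO")
  expect_equal(length(fp_ethane), 2)
  expect_equal(length(fp_ethanol), 5)
  expect_false(identical(fp_ethane, fp_ethanol))
})

test_that("Tanimoto: hand value, bounds, symmetry, identity", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(c(5, 9), c(5, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto(c(1, 2), c(2, 3)), tanimoto(c(2, 3), c(1, 2)))
  # logical-vector form
  expect_equal(tanimoto(c(TRUE, TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE, TRUE)), 0.5)
  expect_error(tanimoto(integer(), integer()), "empty")

  withr::with_seed(8, {
    for (i in 1:20) {
      a <- sample(100, sample(10, 1))
      b <- sample(100, sample(10, 1))
      tv <- tanimoto(a, b)
      expect_gte(tv, 0); expect_lte(tv, 1)
      expect_equal(tv, tanimoto(b, a))
      if (tv == 1) expect_setequal(a, b)
    }
  })
})

test_that("similarity screen: survivors match brute force, boundaries inclusive", {
  lib <- sim_library(n_analogs = 10, n_decoys = 10, seed = 3)
  ref <- lib$smiles[lib$family == "reference"]
  scr <- similarity_screen(lib, ref, threshold = 0.6)

  # reference itself survives with score exactly 1
  expect_equal(scr$tanimoto[scr$id == "REF0001"], 1)
  expect_true(scr$pass[scr$id == "REF0001"])

  # brute-force recomputation compound-by-compound
  fps <- fingerprint_compounds(parse_compounds(lib))
  ref_fp <- fingerprint_compounds(parse_compounds(c(r = ref)))$fingerprint[[1]]
  brute <- vapply(fps$fingerprint, tanimoto, numeric(1), b = ref_fp)
  names(brute) <- fps$id
  expect_equal(scr$tanimoto, unname(brute[scr$id]))
  expect_setequal(scr$id[scr$pass], names(brute)[brute >= 0.6])

  # inclusive boundary: a threshold equal to an attained score keeps it,
  # anything just above drops it
  s <- scr$tanimoto[scr$tanimoto < 1][1]
  at <- similarity_screen(lib, ref, threshold = s)
  above <- similarity_screen(lib, ref, threshold = min(s + 1e-9, 1))
  expect_true(at$pass[at$tanimoto == s][1])
  expect_false(any(above$pass[above$tanimoto == s]))

  # empty library is an empty result, not an error
  empty <- similarity_screen(tibble::tibble(id = character(), smiles = character()),
                             ref)
  expect_equal(nrow(empty), 0)
})

test_that("smi round trip preserves the library", {
  lib <- sim_library(n_analogs = 4, n_decoys = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".smi")
  write_smi(lib, path)
  back <- read_smi(path)
  expect_equal(back$id, lib$id)
  expect_equal(back$smiles, lib$smiles)
})
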