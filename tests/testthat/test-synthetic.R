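test_that("fixture tables carry the expected record counts and formulas", {
  fx <- ref_fixture_set()
  expect_equal(nrow(fx$acids), 4)
  expect_equal(nrow(fx$aldehydes), 9)
  expect_equal(nrow(fx$hydrazides), 4)
  expect_equal(nrow(fx$products), 13)
  expect_equal(fx$products$formula[fx$products$id == "12"], "C19H17N5O")
  # hydrazide 31 is the rule-1 product of acid 29
  made <- apply_reaction(reaction_rules()$hydrazide_formation,
                         list(fixture_mol("29"), mol_parse("NN")))
  expect_true(mol_identical(made[[1]], fixture_mol("31")))
})

test_that("fixture loading fails when a formula contradicts the structure", {
  path <- system.file("extdata", "building_blocks.csv", package = "nahdesign")
  tmp <- withr::local_tempfile(fileext = ".csv")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$formula[tab$id == "12"] <- "C19H18N5O"
  write.csv(tab, tmp, row.names = FALSE)
  expect_error(reference_fixtures(path = tmp), "formula mismatch.*12")
})

test_that("the generator is deterministic for a fixed spec and seed", {
  spec <- reagent_library_spec(n_acids = 8, n_aldehydes = 3, n_decoys = 2,
                               duplicate_fraction = 0.5, salt_fraction = 0.25,
                               seed = 7)
  a <- generate_library(spec)
  b <- generate_library(spec)
  expect_identical(a, b)
})

test_that("combinatorial counts hold for clean single-site specs", {
  gl <- generate_library(reagent_library_spec(n_acids = 20, n_aldehydes = 5,
                                              seed = 7))
  expect_equal(gl$ground_truth$expected_product_count, 100)
  bl <- curate_blocks(gl$records$smiles, gl$records$id)
  lib <- enumerate_library(bl)
  expect_length(lib, 100)
  expect_length(apply_filters(lib), 100)
})

test_that("infeasible specs are rejected", {
  expect_error(generate_library(
    reagent_library_spec(n_acids = 1, duplicate_fraction = 1, seed = 1)),
    "infeasible")
  expect_error(generate_library(
    reagent_library_spec(n_acids = 10, stereo_fraction = 0.6,
                         low_fsp3_fraction = 0.6, seed = 1)),
    "infeasible")
  expect_error(reagent_library_spec(salt_fraction = 1.5))
})

test_that("planted stereocenter acids are exactly the stereo filter failures", {
  gl <- generate_library(reagent_library_spec(
    n_acids = 30, n_aldehydes = 3, stereo_fraction = 0.3, seed = 13))
  gt <- gl$ground_truth
  bl <- curate_blocks(gl$records$smiles, gl$records$id)
  lib <- enumerate_library(bl)
  stereo_failed <- sum(vapply(lib, function(x)
    x$descriptors$n_stereocenters > 0, logical(1)))
  expect_equal(stereo_failed, gt$expected_stereo_fail_count)
  expect_length(apply_filters(lib), gt$expected_pass_filter_count)
})

test_that("generated poses agree with their planted labels at any fraction", {
  for (f in c(0, 0.4, 1)) {
    gp <- generate_poses(20, satisfied_fraction = f, seed = 3)
    verdicts <- vapply(gp$poses, function(p) check_pharmacophore(p)$overall,
                       logical(1))
    expect_identical(verdicts, gp$labels)
    expect_equal(mean(verdicts), f)
  }
})

test_that("generator calls do not disturb the global random stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_library(reagent_library_spec(n_acids = 4,
                                                  n_aldehydes = 2, seed = 9)))
  after <- runif(1)
  expect_identical(before, after)
})
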