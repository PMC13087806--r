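test_that("Fsp3 matches hand counts on the synthesized compounds", {
  # compound 12: two methylene carbons of 19 total
  expect_equal(fsp3(fixture_mol("12")), 2 / 19, tolerance = 1e-12)
  # compound 21: three methoxy carbons of 18 total
  expect_equal(fsp3(fixture_mol("21")), 3 / 18, tolerance = 1e-12)
  benzene <- mol_parse("c1ccccc1")
  expect_equal(fsp3(benzene), 0)
  expect_equal(count_stereocenters(benzene), 0L)
})

test_that("Fsp3 is invariant under atom renumbering", {
  m <- fixture_mol("23")
  for (seed in 1:10) {
    expect_equal(fsp3(renumber_mol(m, seed)), fsp3(m))
  }
})

test_that("carbon-free molecules report Fsp3 0 with a flag", {
  expect_warning(v <- fsp3(mol_parse("[Na+].[Cl-]")), "carbon-free")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "carbon_free"))
})

test_that("stereocenter perception counts potential tetrahedral centers", {
  expect_equal(count_stereocenters(mol_parse("CC(O)C(=O)O")), 1L)  # lactic
  expect_equal(count_stereocenters(mol_parse("CC(C)C(=O)O")), 0L)  # isobutyric
  expect_equal(count_stereocenters(mol_parse("CCC(C)CC")), 0L)     # symmetric
  expect_equal(count_stereocenters(mol_parse("CCC(C)(N)CC(=O)O")), 1L)
  # planar aromatics have none
  for (id in c("6", "7", "8", "9", "10", "11")) {
    expect_equal(count_stereocenters(fixture_mol(id)), 0L, info = id)
  }
  # all thirteen synthesized products are achiral
  fx <- ref_fixture_set()
  for (i in seq_len(nrow(fx$products))) {
    expect_equal(count_stereocenters(mol_parse(fx$products$smiles[i])), 0L,
                 info = fx$products$id[i])
  }
})

test_that("monoisotopic mass equals a brute-force per-atom sum", {
  iso <- isotope_masses()
  set.seed(11)
  elems <- c("C", "H", "N", "O", "S", "Cl", "F", "Br", "P")
  for (k in 1:50) {
    n <- sample(1:6, 1)
    pick <- sample(elems, n)
    counts <- setNames(sample(1:30, n, replace = TRUE), pick)
    brute <- sum(vapply(seq_along(counts), function(i) {
      sum(rep(iso[[names(counts)[i]]], counts[i]))
    }, numeric(1)))
    expect_equal(monoisotopic_mass(counts), brute, tolerance = 1e-12)
  }
})

test_that("masses agree with the toolkit's exact-mass oracle", {
  fx <- ref_fixture_set()
  for (i in seq_len(nrow(fx$products))) {
    smi <- fx$products$smiles[i]
    ob <- ChemmineOB::exactMass_OB(ChemmineOB::forEachMol("SMILES", smi,
                                                          identity))
    expect_equal(monoisotopic_mass(mol_parse(smi)), ob, tolerance = 1e-3,
                 info = fx$products$id[i])
  }
})

test_that("descriptor sets are assembled consistently", {
  d <- compute_descriptors(fixture_mol("12"))
  expect_s3_class(d, "nah_descriptors")
  expect_equal(d$formula_string, "C19H17N5O")
  expect_equal(d$formula[["C"]], 19L)
  expect_equal(d$n_stereocenters, 0L)
  expect_gt(d$monoisotopic_mass, 0)
})
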