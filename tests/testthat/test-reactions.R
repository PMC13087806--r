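test_that("reaction rules validate their SMARTS structure", {
  rules <- reaction_rules()
  expect_named(rules, c("hydrazide_formation", "hydrazone_formation"))
  for (r in rules) {
    expect_equal(r$arity, 2L)
    expect_match(r$smarts, ">>")
  }
  bad <- structure(list(name = "x", smarts = "[C:1].[N:2]>>[C:1].[N:2]",
                        arity = 2L), class = "nah_reaction_rule")
  expect_error(nahdesign:::.validate_rule(bad), "one product")
})

test_that("hydrazide formation reproduces the printed intermediates", {
  rules <- reaction_rules()
  hydrazine <- mol_parse("NN")
  pairs <- list(c("25", "27"), c("26", "28"), c("29", "31"), c("30", "32"))
  for (p in pairs) {
    made <- apply_reaction(rules$hydrazide_formation,
                           list(fixture_mol(p[1]), hydrazine))
    expect_length(made, 1)
    expect_true(mol_identical(made[[1]], fixture_mol(p[2])), info = p[2])
  }
})

test_that("hydrazone formation reproduces compound 12 with E geometry", {
  rules <- reaction_rules()
  made <- apply_reaction(rules$hydrazone_formation,
                         list(fixture_mol("28"), fixture_mol("11")))
  expect_length(made, 1)
  expect_equal(mol_formula_string(made[[1]]), "C19H17N5O")
  expect_true(mol_identical(made[[1]], fixture_mol("12")))
  expect_equal(made[[1]]$geometry, "E")
  expect_true(has_nah_core(made[[1]]))
})

test_that("symmetric multi-site reactants collapse to unique products", {
  rules <- reaction_rules()
  succinic <- mol_parse("OC(=O)CCC(=O)O")
  made <- apply_reaction(rules$hydrazide_formation,
                         list(succinic, mol_parse("NN")))
  expect_length(made, 1)  # two symmetric sites, one unique monohydrazide
  # asymmetric diacid keeps both monohydrazides
  methylsuccinic <- mol_parse("OC(=O)C(C)CC(=O)O")
  made2 <- apply_reaction(rules$hydrazide_formation,
                          list(methylsuccinic, mol_parse("NN")))
  expect_length(made2, 2)
})

test_that("non-matching reactants give an empty set, not an error", {
  rules <- reaction_rules()
  expect_length(apply_reaction(rules$hydrazide_formation,
                               list(mol_parse("c1ccccc1"), mol_parse("NN"))), 0)
  expect_length(apply_reaction(rules$hydrazone_formation,
                               list(fixture_mol("28"), mol_parse("c1ccccc1"))),
                0)
})

test_that("rule 1 only accepts hydrazine as its second component", {
  rules <- reaction_rules()
  expect_error(apply_reaction(rules$hydrazide_formation,
                              list(fixture_mol("25"), mol_parse("NCC"))),
               "hydrazine")
})

test_that("acid perception excludes carbamic and carbonic variants", {
  expect_length(find_acid_sites(mol_parse("OC(=O)Nc1ccccc1")), 0)  # carbamic
  expect_length(find_acid_sites(mol_parse("OC(=O)Oc1ccccc1")), 0)  # carbonic
  expect_length(find_acid_sites(mol_parse("COC(=O)c1ccccc1")), 0)  # ester
  expect_length(find_acid_sites(mol_parse("OC(=O)c1ccccc1")), 1)
})

test_that("reacted products carry the NAH core and no residual acid site", {
  lib <- ref_library()
  for (cmp in lib[seq(1, length(lib), by = 7)]) {
    expect_true(has_nah_core(cmp$mol))
    # fixture acids are mono-acids, so the reacted product has no COOH left
    expect_length(find_acid_sites(cmp$mol), 0)
  }
})
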