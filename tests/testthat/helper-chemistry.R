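# Shared fixtures, memoized so expensive enumerations run once per session.

.helper_env <- new.env(parent = emptyenv())

ref_fixture_set <- function() {
  if (is.null(.helper_env$fx)) .helper_env$fx <- reference_fixtures()
  .helper_env$fx
}

ref_library <- function() {
  if (is.null(.helper_env$lib)) {
    .helper_env$lib <- enumerate_library(fixture_blocks(ref_fixture_set()))
  }
  .helper_env$lib
}

fixture_mol <- function(id) {
  fx <- ref_fixture_set()
  mol_parse(fx$all$smiles[fx$all$id == id])
}

# Random atom renumbering of a molecule's connection table; the result must
# be the same molecule under canonical comparison.
renumber_mol <- function(mol, seed) {
  set.seed(seed)
  n <- nrow(mol$atoms)
  perm <- sample.int(n)
  atoms <- mol$atoms[order(perm), c("elem", "charge"), drop = FALSE]
  bonds <- mol$bonds
  bonds$from <- perm[bonds$from]
  bonds$to <- perm[bonds$to]
  nahdesign:::.mol_finalize(atoms, bonds, geometry = mol$geometry)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
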