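# 1024-bit circular (ECFP-like, diameter 4) fingerprints.
#
# The fingerprint follows the extended-connectivity construction: each atom
# starts from a local invariant (element, heavy degree, hydrogen count,
# formal charge, ring membership); two rounds of neighbourhood hashing grow
# the environment to diameter 4; every environment identifier from rounds
# 0..2 sets one bit of a 1024-long vector (identifier mod 1024). Bit
# positions are specific to this implementation's hash - determinism within
# the package is guaranteed, bit-compatibility with other toolkits is not.

.HASH_MOD <- 2147483647

.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% .HASH_MOD)) %% .HASH_MOD
  h
}

#' Circular fingerprint of diameter 4 folded to 1024 bits
#'
#' @param mol An `nah_mol`.
#' @param n_bits Fingerprint length (default 1024).
#' @param radius Number of neighbourhood-growth rounds (default 2, i.e.
#'   diameter 4).
#' @return Integer vector of 0/1 of length `n_bits`, class `nah_fp`.
#' @examples
#' fp <- ecfp4(mol_parse("c1ccccc1O"))
#' sum(fp)
#' @export
ecfp4 <- function(mol, n_bits = 1024L, radius = 2L) {
  atoms <- mol$atoms
  n <- nrow(atoms)
  deg <- integer(n)
  if (nrow(mol$bonds) > 0) {
    tab <- table(factor(c(mol$bonds$from, mol$bonds$to), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  ring <- .ring_atoms(mol)
  elem_num <- match(atoms$elem, names(isotope_masses()))
  elem_num[is.na(elem_num)] <- 0L
  ids <- vapply(seq_len(n), function(i) {
    .hash_ints(c(elem_num[i], deg[i], atoms$nH[i], atoms$charge[i] + 8,
                 as.integer(ring[i])))
  }, numeric(1))
  all_ids <- ids
  nbrs <- lapply(seq_len(n), function(i) .neighbors(mol, i))
  ordmat <- lapply(seq_len(n), function(i) {
    vapply(nbrs[[i]], function(j) .bond_order(mol, i, j), integer(1))
  })
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(i) {
      nb <- nbrs[[i]]
      if (length(nb) == 0) return(.hash_ints(c(r, ids[i])))
      pairs <- cbind(ordmat[[i]], ids[nb])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      .hash_ints(c(r, ids[i], t(pairs)))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- integer(n_bits)
  bits[(all_ids %% n_bits) + 1] <- 1L
  structure(bits, class = "nah_fp")
}

#' @export
print.nah_fp <- function(x, ...) {
  cat(sprintf("<nah_fp> %d bits, %d set\n", length(x), sum(x)))
  invisible(x)
}

#' Tanimoto similarity between two bit fingerprints
#'
#' @param a,b Fingerprints (0/1 vectors of equal length).
#' @return Similarity in \[0, 1\]; 1 for two empty fingerprints.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' Stack fingerprints into a bit matrix
#'
#' @param fps List of fingerprints.
#' @return Integer matrix, one row per fingerprint.
#' @export
fp_matrix <- function(fps) {
  do.call(rbind, lapply(fps, as.integer))
}
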