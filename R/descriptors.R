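# Molecular formula, monoisotopic mass, Fsp3 and stereocenter perception.

#' Molecular formula as an element-count map
#'
#' @param mol An `nah_mol`.
#' @return Named integer vector of element counts (implicit and explicit
#'   hydrogens combined under `"H"`).
#' @export
mol_formula <- function(mol) {
  elems <- mol$atoms$elem
  counts <- table(elems)
  h <- sum(mol$atoms$nH) + sum(elems == "H")
  out <- as.integer(counts[names(counts) != "H"])
  names(out) <- names(counts)[names(counts) != "H"]
  if (h > 0) out <- c(out, H = as.integer(h))
  out[order(names(out))]
}

#' Molecular formula in Hill notation
#'
#' @param mol An `nah_mol`.
#' @return A single string, e.g. `"C19H17N5O"`.
#' @export
mol_formula_string <- function(mol) {
  f <- mol_formula(mol)
  hill <- c(intersect(c("C", "H"), names(f)),
            sort(setdiff(names(f), c("C", "H"))))
  paste(vapply(hill, function(e) {
    if (f[[e]] == 1L) e else paste0(e, f[[e]])
  }, character(1)), collapse = "")
}

#' Monoisotopic mass of a molecule or formula
#'
#' Sums the monoisotopic mass of the most abundant isotope of every atom in
#' the formula, using the bundled isotope table ([isotope_masses()]).
#'
#' @param x An `nah_mol`, or a named integer vector of element counts.
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(x) {
  f <- if (inherits(x, "nah_mol")) mol_formula(x) else x
  iso <- isotope_masses()
  unknown <- setdiff(names(f), names(iso))
  if (length(unknown) > 0) {
    stop("no monoisotopic mass for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(iso[names(f)] * as.numeric(f))
}

# sp3 carbons: carbon atoms whose incident bonds are all single order
# (the connection table is kekulized, so aromatic carbons carry a double bond).
.sp3_carbon_flags <- function(mol) {
  n <- nrow(mol$atoms)
  is_c <- mol$atoms$elem == "C"
  maxord <- rep(0L, n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      i <- mol$bonds$from[k]; j <- mol$bonds$to[k]
      if (o > maxord[i]) maxord[i] <- o
      if (o > maxord[j]) maxord[j] <- o
    }
  }
  is_c & maxord <= 1L
}

#' Fraction of sp3-hybridized carbons (Fsp3)
#'
#' Fsp3 is the number of sp3 carbons divided by the total number of carbons.
#' A carbon-free molecule has no defined carbon fraction; it is reported as 0
#' with attribute `carbon_free = TRUE`.
#'
#' @param mol An `nah_mol`.
#' @return Numeric in \[0, 1\].
#' @export
fsp3 <- function(mol) {
  nc <- sum(mol$atoms$elem == "C")
  if (nc == 0) {
    warning("carbon-free molecule: Fsp3 undefined, reported as 0")
    return(structure(0, carbon_free = TRUE))
  }
  sum(.sp3_carbon_flags(mol)) / nc
}

# Graph-refinement symmetry classes (Morgan-style): atoms start from a local
# invariant and are iteratively re-ranked by their neighbourhood until the
# partition stabilizes. Used for stereocenter perception and as the seed
# invariant of the circular fingerprint.
.symmetry_classes <- function(mol) {
  atoms <- mol$atoms
  n <- nrow(atoms)
  deg <- integer(n)
  if (nrow(mol$bonds) > 0) {
    tab <- table(factor(c(mol$bonds$from, mol$bonds$to), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  key <- paste(atoms$elem, atoms$charge, atoms$nH, deg, sep = "|")
  cls <- as.integer(factor(key))
  for (iter in seq_len(n)) {
    nbkeys <- vapply(seq_len(n), function(i) {
      nb <- .neighbors(mol, i)
      if (length(nb) == 0) return("")
      ords <- vapply(nb, function(j) .bond_order(mol, i, j), integer(1))
      paste(sort(paste0(ords, ":", cls[nb])), collapse = ",")
    }, character(1))
    newcls <- as.integer(factor(paste(cls, nbkeys, sep = "#")))
    if (length(unique(newcls)) == length(unique(cls))) break
    cls <- newcls
  }
  cls
}

#' Count tetrahedral stereocenters
#'
#' Counts carbon atoms that are potential or assigned tetrahedral
#' stereocenters: sp3 carbons bearing four constitutionally distinct
#' substituents (implicit hydrogen counted as one substituent).
#' Distinctness is decided by graph-refinement symmetry classes, so the count
#' covers unassigned centers of a 2D structure. Double-bond (E/Z) axes -
#' including the acylhydrazone C=N - are not counted.
#'
#' @param mol An `nah_mol`.
#' @return Non-negative integer.
#' @export
count_stereocenters <- function(mol) {
  sp3 <- .sp3_carbon_flags(mol)
  cand <- which(sp3 & mol$atoms$nH <= 1L)
  if (length(cand) == 0) return(0L)
  cls <- .symmetry_classes(mol)
  n_st <- 0L
  for (i in cand) {
    nb <- .neighbors(mol, i)
    if (length(nb) + mol$atoms$nH[i] != 4L) next
    # Explicit neighbour classes plus one pseudo-class per implicit H.
    classes <- cls[nb]
    if (mol$atoms$nH[i] == 1L) classes <- c(classes, -1L)
    if (anyDuplicated(classes) == 0L) n_st <- n_st + 1L
  }
  n_st
}

#' Compute the descriptor set of a molecule
#'
#' @param mol An `nah_mol`.
#' @return A list of class `nah_descriptors`: `fsp3`, `n_stereocenters`,
#'   `formula` (named counts), `formula_string`, `monoisotopic_mass` (Da).
#' @examples
#' d <- compute_descriptors(mol_parse("CCO"))
#' d$fsp3
#' @export
compute_descriptors <- function(mol) {
  f <- mol_formula(mol)
  structure(list(
    fsp3 = as.numeric(fsp3(mol)),
    n_stereocenters = count_stereocenters(mol),
    formula = f,
    formula_string = mol_formula_string(mol),
    monoisotopic_mass = monoisotopic_mass(f)
  ), class = "nah_descriptors")
}

#' @export
print.nah_descriptors <- function(x, ...) {
  cat(sprintf("%s  M = %.5f Da  Fsp3 = %.4f  stereocenters = %d\n",
              x$formula_string, x$monoisotopic_mass, x$fsp3,
              x$n_stereocenters))
  invisible(x)
}
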