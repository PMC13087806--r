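#' @importFrom utils read.csv write.csv
#' @importFrom stats prcomp sd setNames runif rnorm
NULL

.nah_cache <- new.env(parent = emptyenv())

#' Monoisotopic isotope mass table
#'
#' Returns the bundled table of monoisotopic atomic masses (most abundant
#' isotope, Da) used for all formula and adduct m/z arithmetic. The table is
#' shipped as a plain-text data file under `extdata` so that the exact values
#' behind every reported mass are versioned with the package.
#'
#' @return Named numeric vector of monoisotopic masses keyed by element symbol.
#' @export
isotope_masses <- function() {
  if (is.null(.nah_cache$iso)) {
    path <- system.file("extdata", "isotope_masses.csv", package = "nahdesign")
    tab <- read.csv(path, stringsAsFactors = FALSE)
    .nah_cache$iso <- setNames(tab$monoisotopic_mass, tab$element)
  }
  .nah_cache$iso
}

# Electron mass, Da, at the 5-decimal precision of the high-resolution m/z
# surface this package reports (calculated adduct masses are printed to 5
# decimals; see adduct_table()).
.ELECTRON_MASS <- 0.00055

# Effective valence used to assign implicit hydrogens on a kekulized
# connection table. Metals and anything absent from the table get no
# implicit hydrogens.
.DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

.effective_valence <- function(elem, charge) {
  base <- .DEFAULT_VALENCE[elem]
  v <- ifelse(is.na(base), 0, base)
  # Charge adjustment: N+/O+/S+ gain a bond, N-/O-/S- lose one; carbanion C-
  # has three bonds. Hypervalent neutral P/S (P=5, S=4/6) are promoted to the
  # smallest standard valence that accommodates the explicit bond order sum
  # (handled by the caller via pmax below).
  adj <- ifelse(elem %in% c("N", "O", "S", "P"), charge,
         ifelse(elem == "C", -abs(charge), 0))
  pmax(v + adj, 0)
}

.implicit_h <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    ords <- bonds$order
    bsum <- vapply(seq_len(n), function(i) {
      sum(ords[bonds$from == i]) + sum(ords[bonds$to == i])
    }, numeric(1))
  }
  # Explicit hydrogens occupy a bond; they never carry implicit H themselves.
  val <- .effective_valence(atoms$elem, atoms$charge)
  # Hypervalent S/P: allow S(4), S(6), P(5) when explicit bonds exceed the
  # default valence.
  hyper <- atoms$elem == "S" & atoms$charge == 0 & bsum > 2
  val[hyper] <- ifelse(bsum[hyper] > 4, 6, 4)
  hyperp <- atoms$elem == "P" & atoms$charge == 0 & bsum > 3
  val[hyperp] <- 5
  nh <- pmax(val - bsum, 0)
  nh[atoms$elem == "H"] <- 0
  as.integer(nh)
}

# ---------------------------------------------------------------------------
# Construction

.check_smiles_tokens <- function(smiles) {
  # Cheap lexical screen so parse failures can point at the offending
  # position; full chemistry validation is delegated to the toolkit parse.
  chars <- strsplit(smiles, "")[[1]]
  ok <- grepl("^[]A-Za-z0-9@+()=#$:/%*.\\\\[-]$", chars)
  if (any(!ok)) {
    pos <- which(!ok)[1]
    stop(sprintf("SMILES parse error: invalid token '%s' at position %d in '%s'",
                 chars[pos], pos, smiles), call. = FALSE)
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    pos <- if (any(depth < 0)) which(depth < 0)[1] else length(chars)
    stop(sprintf("SMILES parse error: unbalanced parenthesis at position %d in '%s'",
                 pos, smiles), call. = FALSE)
  }
  invisible(TRUE)
}

.molblock_from_smiles <- function(smiles) {
  .check_smiles_tokens(smiles)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", source = smiles)),
    error = function(e) "")
  if (!nzchar(out) || !grepl("V2000", out)) {
    stop(sprintf("SMILES parse error: could not interpret '%s' (position 1)",
                 smiles), call. = FALSE)
  }
  out
}

# Fixed-width V2000 reader for toolkit-generated molblocks.
.molblock_to_graph <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  cl <- grep(" V2000", lines, fixed = TRUE)[1]
  counts <- lines[cl]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atoms <- data.frame(elem = character(na), charge = integer(na),
                      x = numeric(na), y = numeric(na), z = numeric(na),
                      stringsAsFactors = FALSE)
  chg_code <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                `5` = -1L, `6` = -2L, `7` = -3L)
  for (i in seq_len(na)) {
    ln <- lines[cl + i]
    atoms$x[i] <- as.numeric(substr(ln, 1, 10))
    atoms$y[i] <- as.numeric(substr(ln, 11, 20))
    atoms$z[i] <- as.numeric(substr(ln, 21, 30))
    atoms$elem[i] <- trimws(substr(ln, 32, 34))
    atoms$charge[i] <- chg_code[[trimws(substr(ln, 37, 39))]]
  }
  if (nb > 0) {
    bonds <- data.frame(from = integer(nb), to = integer(nb), order = integer(nb))
    for (j in seq_len(nb)) {
      ln <- lines[cl + na + j]
      bonds$from[j] <- as.integer(substr(ln, 1, 3))
      bonds$to[j] <- as.integer(substr(ln, 4, 6))
      o <- as.integer(substr(ln, 7, 9))
      if (o == 4) o <- 1L  # aromatic order never expected from kekulized input
      bonds$order[j] <- o
    }
  } else {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  }
  # M CHG lines override the legacy atom-line charge column.
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "[ ]+")[[1]])
    k <- fields[1]
    for (p in seq_len(k)) {
      atoms$charge[fields[2 * p]] <- fields[2 * p + 1]
    }
  }
  list(atoms = atoms, bonds = bonds)
}

.mol_to_molblock <- function(mol, title = "", tags = NULL) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  na <- nrow(atoms)
  nb <- nrow(bonds)
  x <- if (!is.null(atoms$x)) atoms$x else numeric(na)
  y <- if (!is.null(atoms$y)) atoms$y else numeric(na)
  z <- if (!is.null(atoms$z)) atoms$z else numeric(na)
  header <- c(title, " nahdesign", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        x, y, z, atoms$elem)
  bond_lines <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$from, bonds$to, bonds$order)
  } else character(0)
  chg <- which(atoms$charge != 0)
  chg_lines <- if (length(chg) > 0) {
    vapply(chg, function(i) sprintf("M  CHG  1 %3d %3d", i, atoms$charge[i]),
           character(1))
  } else character(0)
  tag_lines <- if (length(tags) > 0) {
    unlist(lapply(names(tags), function(nm) {
      c(sprintf(">  <%s>", nm), as.character(tags[[nm]]), "")
    }))
  } else character(0)
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END", tag_lines,
          "$$$$"), collapse = "\n")
}

.canonical_from_molblock <- function(molblock) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", source = molblock)),
    error = function(e) "")
  key <- sub("[\t\n].*$", "", out)
  key <- trimws(key)
  if (!nzchar(key)) stop("canonicalization failed", call. = FALSE)
  key
}

.mol_finalize <- function(atoms, bonds, geometry = NA_character_,
                          source_smiles = NA_character_) {
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  atoms$nH <- .implicit_h(atoms, bonds)
  mol <- structure(
    list(atoms = atoms, bonds = bonds, geometry = geometry,
         source_smiles = source_smiles, canonical_key = NA_character_),
    class = "nah_mol")
  # The key is computed from a coordinate-free connection table so that it
  # reflects constitution only: depicted (2D) double-bond geometry must not
  # leak into equality comparisons.
  flat <- mol
  flat$atoms$x <- flat$atoms$y <- flat$atoms$z <- NULL
  mol$canonical_key <- .canonical_from_molblock(.mol_to_molblock(flat))
  mol
}

#' Parse a SMILES string into a molecule
#'
#' Builds a kekulized connection-table molecule from a SMILES string. Formal
#' charges are preserved; implicit hydrogens are assigned from a standard
#' valence model. The canonical key (a canonical SMILES of the constitution)
#' is attached so that two parses of equivalent spellings compare equal.
#'
#' @param smiles A single SMILES string (Daylight dialect).
#' @return An object of class `nah_mol` with elements `atoms` (element,
#'   formal charge, implicit H count), `bonds` (from, to, order) and
#'   `canonical_key`.
#' @examples
#' m <- mol_parse("OC(=O)Cc1c[nH]c2ccccc12")
#' mol_formula(m)
#' @export
mol_parse <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  g <- .molblock_to_graph(.molblock_from_smiles(smiles))
  .mol_finalize(g$atoms, g$bonds, source_smiles = smiles)
}

#' @export
print.nah_mol <- function(x, ...) {
  cat(sprintf("<nah_mol> %s  (%d atoms, %d bonds%s)\n",
              mol_formula_string(x), nrow(x$atoms), nrow(x$bonds),
              if (!is.na(x$geometry)) paste0(", C=N geometry ", x$geometry) else ""))
  cat("  canonical key:", x$canonical_key, "\n")
  invisible(x)
}

#' Test molecules for canonical equality
#'
#' @param a,b Molecules of class `nah_mol`.
#' @return Logical; `TRUE` when both share the same canonical key.
#' @export
mol_identical <- function(a, b) {
  identical(a$canonical_key, b$canonical_key)
}

# Heavy-atom neighbours of atom i (indices).
.neighbors <- function(mol, i) {
  c(mol$bonds$to[mol$bonds$from == i], mol$bonds$from[mol$bonds$to == i])
}

.bond_order <- function(mol, i, j) {
  hit <- (mol$bonds$from == i & mol$bonds$to == j) |
    (mol$bonds$from == j & mol$bonds$to == i)
  if (!any(hit)) return(0L)
  mol$bonds$order[which(hit)[1]]
}

# Ring membership flags via bridge detection on the molecular graph.
.ring_atoms <- function(mol) {
  n <- nrow(mol$atoms)
  flags <- logical(n)
  if (nrow(mol$bonds) == 0) return(flags)
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("from", "to")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  cyclic_edges <- setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
  idx <- unique(c(mol$bonds$from[cyclic_edges], mol$bonds$to[cyclic_edges]))
  flags[idx] <- TRUE
  flags
}

# Connected components (fragments) of a molecule; returns list of atom-index
# vectors.
.fragments <- function(mol) {
  n <- nrow(mol$atoms)
  if (nrow(mol$bonds) == 0) return(as.list(seq_len(n)))
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("from", "to")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  split(seq_len(n), comp$membership)
}

# Extract the sub-molecule induced by a set of atom indices.
.submol <- function(mol, idx) {
  idx <- sort(idx)
  remap <- match(seq_len(nrow(mol$atoms)), idx)
  keep <- mol$bonds$from %in% idx & mol$bonds$to %in% idx
  bonds <- mol$bonds[keep, , drop = FALSE]
  bonds$from <- remap[bonds$from]
  bonds$to <- remap[bonds$to]
  .mol_finalize(mol$atoms[idx, , drop = FALSE], bonds,
                geometry = mol$geometry)
}
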