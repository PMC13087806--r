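# Two-component virtual synthesis:
#   rule 1: carboxylic acid + hydrazine        -> acylhydrazide
#   rule 2: acylhydrazide + (aryl)aldehyde     -> E-configured N-acylhydrazone
#
# The transforms are applied as connection-table edits at every combination
# of matching sites, after which products are sanitized, canonicalized and
# deduplicated - the semantics of a two-component reaction node driven by
# the reaction SMARTS kept in reaction_rules().

#' Reaction rules of the virtual synthesis
#'
#' Returns the named reaction-SMARTS transforms implemented by
#' [apply_reaction()]. Both are two-component transforms with a single
#' product template; the hydrazone rule emits the E geometry on the newly
#' formed C=N bond.
#'
#' @return List of `nah_reaction_rule` objects (fields `name`, `smarts`,
#'   `arity`).
#' @export
reaction_rules <- function() {
  rules <- list(
    hydrazide_formation = paste0(
      "[#6:1](=[#8:2])[O:3].[#7:4][#7:5]>>",
      "[#6:1](=[#8:2])[#7:4][#7:5]"),
    hydrazone_formation = paste0(
      "[#6:1](=O)[N:2][N:3].[#6:4][C:5]=O>>",
      "[#6:1](=O)[N:2]/N=[C:5]/[#6:4]")
  )
  lapply(names(rules), function(nm) {
    r <- structure(list(name = nm, smarts = rules[[nm]], arity = 2L),
                   class = "nah_reaction_rule")
    .validate_rule(r)
    r
  }) |> setNames(names(rules))
}

.validate_rule <- function(rule) {
  parts <- strsplit(rule$smarts, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("reaction SMARTS must contain one '>>'")
  n_react <- length(strsplit(parts[1], ".", fixed = TRUE)[[1]])
  n_prod <- length(strsplit(parts[2], ".", fixed = TRUE)[[1]])
  if (n_react != rule$arity) stop("reactant template count != arity")
  if (n_prod != 1) stop("rule must have exactly one product template")
  invisible(TRUE)
}

#' @export
print.nah_reaction_rule <- function(x, ...) {
  cat(sprintf("<reaction rule> %s (%d components)\n  %s\n",
              x$name, x$arity, x$smarts))
  invisible(x)
}

# --- site perception -------------------------------------------------------

# Carboxylic acid: carbonyl carbon bearing =O (terminal) and -OH (terminal,
# neutral, one H). Carbamic/carbonic variants - an additional O or N single
# bonded to the same carbon - are excluded.
find_acid_sites <- function(mol) {
  sites <- list()
  for (i in which(mol$atoms$elem == "C")) {
    nb <- .neighbors(mol, i)
    o_dbl <- nb[mol$atoms$elem[nb] == "O" &
                vapply(nb, function(j) .bond_order(mol, i, j) == 2L &&
                         length(.neighbors(mol, j)) == 1, logical(1))]
    o_hyd <- nb[mol$atoms$elem[nb] == "O" &
                vapply(nb, function(j) .bond_order(mol, i, j) == 1L &&
                         length(.neighbors(mol, j)) == 1 &&
                         mol$atoms$charge[j] == 0 &&
                         mol$atoms$nH[j] == 1L, logical(1))]
    if (length(o_dbl) != 1 || length(o_hyd) != 1) next
    others <- setdiff(nb, c(o_dbl, o_hyd))
    if (any(mol$atoms$elem[others] %in% c("O", "N", "S"))) next
    sites[[length(sites) + 1]] <- c(c = i, o_carbonyl = o_dbl, o_hydroxyl = o_hyd)
  }
  sites
}

# Acylhydrazide head: C(=O)-N(H)-NH2 with a free terminal nitrogen.
find_hydrazide_sites <- function(mol) {
  sites <- list()
  for (i in which(mol$atoms$elem == "C")) {
    nb <- .neighbors(mol, i)
    o_dbl <- nb[mol$atoms$elem[nb] == "O" &
                vapply(nb, function(j) .bond_order(mol, i, j) == 2L &&
                         length(.neighbors(mol, j)) == 1, logical(1))]
    if (length(o_dbl) != 1) next
    for (na in nb[mol$atoms$elem[nb] == "N"]) {
      if (.bond_order(mol, i, na) != 1L) next
      nnb <- setdiff(.neighbors(mol, na), i)
      for (nb2 in nnb[mol$atoms$elem[nnb] == "N"]) {
        if (.bond_order(mol, na, nb2) != 1L) next
        if (length(.neighbors(mol, nb2)) == 1 && mol$atoms$nH[nb2] == 2L &&
            mol$atoms$charge[nb2] == 0) {
          sites[[length(sites) + 1]] <- c(c = i, n_amide = na, n_terminal = nb2)
        }
      }
    }
  }
  sites
}

# Aldehyde: H-C(=O)-C (the carbonyl carbon must carry exactly one hydrogen
# and one carbon substituent, matching the [#6][C]=O reactant template).
find_aldehyde_sites <- function(mol) {
  sites <- list()
  for (i in which(mol$atoms$elem == "C")) {
    if (mol$atoms$nH[i] != 1L) next
    nb <- .neighbors(mol, i)
    if (length(nb) != 2) next
    o_dbl <- nb[mol$atoms$elem[nb] == "O" &
                vapply(nb, function(j) .bond_order(mol, i, j) == 2L &&
                         length(.neighbors(mol, j)) == 1, logical(1))]
    cc <- setdiff(nb, o_dbl)
    if (length(o_dbl) == 1 && length(cc) == 1 && mol$atoms$elem[cc] == "C") {
      sites[[length(sites) + 1]] <- c(c = i, o = o_dbl)
    }
  }
  sites
}

# Does the N-acylhydrazone substructure C(=O)-N-N=C occur in the molecule?
has_nah_core <- function(mol) {
  for (i in which(mol$atoms$elem == "C")) {
    nb <- .neighbors(mol, i)
    has_o <- any(mol$atoms$elem[nb] == "O" &
                 vapply(nb, function(j) .bond_order(mol, i, j) == 2L, logical(1)))
    if (!has_o) next
    for (na in nb[mol$atoms$elem[nb] == "N"]) {
      if (.bond_order(mol, i, na) != 1L) next
      nnb <- setdiff(.neighbors(mol, na), i)
      for (n2 in nnb[mol$atoms$elem[nnb] == "N"]) {
        n2nb <- setdiff(.neighbors(mol, n2), na)
        if (any(mol$atoms$elem[n2nb] == "C" &
                vapply(n2nb, function(j) .bond_order(mol, n2, j) == 2L,
                       logical(1)))) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# --- graph surgery ---------------------------------------------------------

.drop_atoms <- function(atoms, bonds, drop) {
  keep <- setdiff(seq_len(nrow(atoms)), drop)
  remap <- match(seq_len(nrow(atoms)), keep)
  bkeep <- !(bonds$from %in% drop | bonds$to %in% drop)
  bonds <- bonds[bkeep, , drop = FALSE]
  bonds$from <- remap[bonds$from]
  bonds$to <- remap[bonds$to]
  list(atoms = atoms[keep, , drop = FALSE], bonds = bonds, remap = remap)
}

.react_hydrazide <- function(acid, site) {
  g <- .drop_atoms(acid$atoms[, c("elem", "charge")], acid$bonds,
                   site[["o_hydroxyl"]])
  c_idx <- g$remap[site[["c"]]]
  n1 <- nrow(g$atoms) + 1L
  n2 <- nrow(g$atoms) + 2L
  atoms <- rbind(g$atoms,
                 data.frame(elem = c("N", "N"), charge = c(0L, 0L)))
  bonds <- rbind(g$bonds,
                 data.frame(from = c(c_idx, n1), to = c(n1, n2),
                            order = c(1L, 1L)))
  .mol_finalize(atoms, bonds)
}

.react_hydrazone <- function(hydrazide, hsite, aldehyde, asite) {
  offs <- nrow(hydrazide$atoms)
  atoms <- rbind(hydrazide$atoms[, c("elem", "charge")],
                 aldehyde$atoms[, c("elem", "charge")])
  abonds <- aldehyde$bonds
  abonds$from <- abonds$from + offs
  abonds$to <- abonds$to + offs
  bonds <- rbind(hydrazide$bonds, abonds)
  g <- .drop_atoms(atoms, bonds, asite[["o"]] + offs)
  n_term <- g$remap[hsite[["n_terminal"]]]
  c_ald <- g$remap[asite[["c"]] + offs]
  g$bonds <- rbind(g$bonds,
                   data.frame(from = n_term, to = c_ald, order = 2L))
  # the condensation is run under thermodynamic control: the product C=N is
  # emitted E-configured, carried as molecule-level metadata
  .mol_finalize(g$atoms, g$bonds, geometry = "E")
}

.is_hydrazine <- function(mol) {
  nrow(mol$atoms) == 2 && all(mol$atoms$elem == "N") &&
    nrow(mol$bonds) == 1 && mol$bonds$order[1] == 1L &&
    all(mol$atoms$nH == 2L)
}

#' Apply a two-component reaction rule at every matching site
#'
#' The transform is applied independently at each combination of matching
#' sites of the two reactants (no double condensations); products are
#' sanitized, canonicalized and returned as a set (duplicates collapse).
#' A reactant with no matching site yields an empty set, not an error.
#'
#' @param rule A rule from [reaction_rules()].
#' @param reactants List of two `nah_mol` objects, in template order
#'   (acid then hydrazine for rule 1; hydrazide then aldehyde for rule 2).
#' @return List of product `nah_mol` objects, unique by canonical key.
#' @examples
#' r <- reaction_rules()
#' acid <- mol_parse("OC(=O)c1cc(OC)c(OC)c(OC)c1")
#' apply_reaction(r$hydrazide_formation, list(acid, mol_parse("NN")))
#' @export
apply_reaction <- function(rule, reactants) {
  stopifnot(inherits(rule, "nah_reaction_rule"), length(reactants) == rule$arity)
  if (rule$name == "hydrazide_formation") {
    if (!.is_hydrazine(reactants[[2]])) {
      stop("the second component of hydrazide formation must be hydrazine (NN)",
           call. = FALSE)
    }
    sites <- find_acid_sites(reactants[[1]])
    prods <- lapply(sites, function(s) .react_hydrazide(reactants[[1]], s))
  } else if (rule$name == "hydrazone_formation") {
    hsites <- find_hydrazide_sites(reactants[[1]])
    asites <- find_aldehyde_sites(reactants[[2]])
    prods <- list()
    for (h in hsites) {
      for (a in asites) {
        prods[[length(prods) + 1]] <-
          .react_hydrazone(reactants[[1]], h, reactants[[2]], a)
      }
    }
  } else {
    stop("unknown reaction rule: ", rule$name, call. = FALSE)
  }
  keys <- vapply(prods, function(p) p$canonical_key, character(1))
  prods[!duplicated(keys)]
}
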