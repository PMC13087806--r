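# Building-block curation: salt stripping, neutralization, role assignment,
# deduplication.

#' Construct a building block
#'
#' @param id Identifier string.
#' @param mol An `nah_mol`.
#' @param role One of `"acid"`, `"aldehyde"`, `"other"`.
#' @param source Free-text provenance.
#' @return `nah_block` object.
#' @export
building_block <- function(id, mol, role = c("acid", "aldehyde", "other"),
                           source = "") {
  role <- match.arg(role)
  structure(list(id = id, mol = mol, role = role, source = source),
            class = "nah_block")
}

#' @export
print.nah_block <- function(x, ...) {
  cat(sprintf("<building block> %s [%s] %s\n", x$id, x$role,
              x$mol$canonical_key))
  invisible(x)
}

# Keep the largest fragment by heavy-atom count; ties broken by larger
# monoisotopic mass. Returns NULL when no carbon-containing fragment exists.
.strip_salt <- function(mol) {
  frags <- .fragments(mol)
  if (length(frags) == 1) {
    if (!any(mol$atoms$elem == "C")) return(NULL)
    return(mol)
  }
  organic <- Filter(function(idx) any(mol$atoms$elem[idx] == "C"), frags)
  if (length(organic) == 0) return(NULL)
  subs <- lapply(organic, function(idx) .submol(mol, idx))
  heavy <- vapply(subs, function(s) sum(s$atoms$elem != "H"), numeric(1))
  mass <- vapply(subs, monoisotopic_mass, numeric(1))
  subs[[order(-heavy, -mass)[1]]]
}

# Neutralize isolated +/-1 charges on N/O/S (e.g. carboxylates from sodium
# salts). Atoms adjacent to an oppositely charged atom (ylides, nitro
# groups) are left untouched. Implicit hydrogens readjust via the valence
# model on refinalization.
.neutralize <- function(mol) {
  chg <- mol$atoms$charge
  if (all(chg == 0)) return(mol)
  fix <- logical(nrow(mol$atoms))
  for (i in which(abs(chg) == 1 & mol$atoms$elem %in% c("N", "O", "S"))) {
    nb <- .neighbors(mol, i)
    if (!any(chg[nb] * chg[i] < 0)) fix[i] <- TRUE
  }
  if (!any(fix)) return(mol)
  atoms <- mol$atoms[, c("elem", "charge")]
  atoms$charge[fix] <- 0L
  .mol_finalize(atoms, mol$bonds, geometry = mol$geometry)
}

.assign_role <- function(mol) {
  if (length(find_acid_sites(mol)) > 0) return("acid")
  if (length(find_aldehyde_sites(mol)) > 0) return("aldehyde")
  "other"
}

#' Curate a raw reagent collection into building blocks
#'
#' Each record is salt-stripped to its largest organic fragment, neutralized,
#' assigned a role by functional-group perception (carboxylic acid takes
#' precedence over aldehyde), and deduplicated by canonical key. Records with
#' no carbon-containing fragment are dropped with a warning; unparseable
#' records are dropped with a warning in permissive mode and abort in strict
#' mode. The output is sorted by canonical key, so it is independent of the
#' input order.
#'
#' @param smiles Character vector of structure strings.
#' @param ids Optional identifiers (defaults to `BB0001`, ...).
#' @param strict Abort on the first unparseable record instead of skipping it.
#' @return List of `nah_block` objects, unique by canonical key.
#' @examples
#' blocks <- curate_blocks(c("OC(=O)Cc1c[nH]c2ccccc12", "O=Cc1ccccc1"))
#' vapply(blocks, function(b) b$role, character(1))
#' @export
curate_blocks <- function(smiles, ids = NULL, strict = FALSE) {
  if (length(smiles) == 0) return(list())
  if (is.null(ids)) ids <- sprintf("BB%04d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  blocks <- list()
  seen <- character(0)
  for (k in seq_along(smiles)) {
    mol <- tryCatch(mol_parse(smiles[k]), error = function(e) e)
    if (inherits(mol, "error")) {
      if (strict) stop(sprintf("record %d (%s): %s", k, ids[k],
                               conditionMessage(mol)), call. = FALSE)
      warning(sprintf("record %d (%s) skipped: %s", k, ids[k],
                      conditionMessage(mol)), call. = FALSE)
      next
    }
    mol <- .strip_salt(mol)
    if (is.null(mol)) {
      warning(sprintf("record %d (%s) dropped: no carbon-containing fragment",
                      k, ids[k]), call. = FALSE)
      next
    }
    mol <- .neutralize(mol)
    if (mol$canonical_key %in% seen) next
    seen <- c(seen, mol$canonical_key)
    blocks[[length(blocks) + 1]] <-
      building_block(ids[k], mol, .assign_role(mol), source = smiles[k])
  }
  blocks[order(vapply(blocks, function(b) b$mol$canonical_key, character(1)))]
}
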