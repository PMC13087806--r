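# Two-stage library enumeration: acids -> hydrazides -> E-acylhydrazones.

#' Enumerate the virtual N-acylhydrazone library
#'
#' Stage 1 condenses every curated acid with hydrazine into its acylhydrazide
#' (at every carboxylic-acid site); stage 2 condenses every hydrazide with
#' every aldehyde (at every aldehyde site) into E-configured
#' N-acylhydrazones. Products are unique by canonical key across the whole
#' run; each carries provenance (acid id, aldehyde id, taken from the first
#' route that produced it) and its descriptor set.
#'
#' @param blocks List of `nah_block` objects; entries with `role == "acid"`
#'   drive stage 1.
#' @param aldehydes List of `nah_block` objects with `role == "aldehyde"`.
#'   Defaults to the aldehyde entries of `blocks`.
#' @param compute_fingerprints Attach a 1024-bit circular fingerprint to each
#'   product (needed for the chemical-space embedding).
#' @return List of `nah_compound` objects (fields `id`, `mol`, `provenance`,
#'   `descriptors`, `fingerprint`).
#' @examples
#' blocks <- curate_blocks(c("OC(=O)Cc1ccccc1", "O=Cc1ccncc1"))
#' lib <- enumerate_library(blocks)
#' length(lib)
#' @export
enumerate_library <- function(blocks, aldehydes = NULL,
                              compute_fingerprints = FALSE) {
  acids <- Filter(function(b) b$role == "acid", blocks)
  if (is.null(aldehydes)) {
    aldehydes <- Filter(function(b) b$role == "aldehyde", blocks)
  } else {
    aldehydes <- Filter(function(b) b$role == "aldehyde", aldehydes)
  }
  if (length(acids) == 0 || length(aldehydes) == 0) return(list())
  rules <- reaction_rules()
  hydrazine <- mol_parse("NN")

  # stage 1: hydrazides, unique by canonical key, provenance = first acid
  hyds <- list()
  hkeys <- character(0)
  for (a in acids) {
    prods <- apply_reaction(rules$hydrazide_formation, list(a$mol, hydrazine))
    for (p in prods) {
      if (p$canonical_key %in% hkeys) next
      hkeys <- c(hkeys, p$canonical_key)
      hyds[[length(hyds) + 1]] <- list(mol = p, acid_id = a$id)
    }
  }

  # stage 2: hydrazones
  out <- list()
  okeys <- character(0)
  for (h in hyds) {
    for (al in aldehydes) {
      prods <- apply_reaction(rules$hydrazone_formation, list(h$mol, al$mol))
      for (p in prods) {
        if (p$canonical_key %in% okeys) next
        okeys <- c(okeys, p$canonical_key)
        out[[length(out) + 1]] <- structure(list(
          id = sprintf("NAH%05d", length(out) + 1L),
          mol = p,
          provenance = c(acid_id = h$acid_id, aldehyde_id = al$id),
          descriptors = compute_descriptors(p),
          fingerprint = if (compute_fingerprints) ecfp4(p) else NULL,
          embedding = NULL
        ), class = "nah_compound")
      }
    }
  }
  out
}

#' @export
print.nah_compound <- function(x, ...) {
  cat(sprintf("<nah compound> %s (%s; acid %s + aldehyde %s)\n  %s\n",
              x$id, x$descriptors$formula_string,
              x$provenance[["acid_id"]], x$provenance[["aldehyde_id"]],
              x$mol$canonical_key))
  invisible(x)
}

#' Canonical keys of a compound list
#'
#' @param lib List of `nah_compound` objects.
#' @return Character vector of canonical keys.
#' @export
library_keys <- function(lib) {
  vapply(lib, function(x) x$mol$canonical_key, character(1))
}

#' Check that a library contains given target structures
#'
#' Membership is decided by canonical-key equality, so any equivalent SMILES
#' spelling of a target matches.
#'
#' @param lib List of `nah_compound` objects.
#' @param targets Character vector of SMILES, or list of `nah_mol`.
#' @return Logical vector, one entry per target, named when `targets` is named.
#' @export
library_contains <- function(lib, targets) {
  keys <- library_keys(lib)
  tk <- if (is.character(targets)) {
    vapply(targets, function(s) mol_parse(s)$canonical_key, character(1))
  } else {
    vapply(targets, function(m) m$canonical_key, character(1))
  }
  setNames(tk %in% keys, names(targets))
}
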