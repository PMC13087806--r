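# Bundled reference structures: the published building blocks (4 carboxylic
# acids, 9 aromatic aldehydes), the 4 intermediate hydrazides, and the 13
# synthesized N-acylhydrazone products, with their high-resolution mass
# anchors. Structures are derived from the published IUPAC names (no SMILES
# are printed in the source); each record carries the molecular formula
# implied by its HRMS characterization, and loading fails if the
# name-derived structure contradicts it.

#' Reference building blocks and synthesized compounds
#'
#' Loads the bundled table of name-derived structures: carboxylic acids
#' (ids 25, 26, 29, 30), aldehydes (6-11 plus the indazole-5-, pyrrolo-
#' pyrimidine-5- and pyrazole-4-carbaldehydes), hydrazide intermediates
#' (27, 28, 31, 32) and final products (12-24). Every structure is parsed
#' and validated against its recorded molecular formula.
#'
#' @param validate Check each parsed structure against the recorded formula
#'   (default TRUE).
#' @param path Fixture table to load (defaults to the bundled one).
#' @return List with data.frames `acids`, `aldehydes`, `hydrazides`,
#'   `products` (columns include `id`, `name`, `smiles`, `formula`,
#'   `canonical_key`; products add provenance ids, HRMS adduct and printed
#'   calculated m/z) and `all` (the full table).
#' @examples
#' fx <- reference_fixtures()
#' nrow(fx$products)
#' @export
reference_fixtures <- function(validate = TRUE,
                           path = system.file("extdata",
                                              "building_blocks.csv",
                                              package = "nahdesign")) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character", acid_id = "character",
                                 aldehyde_id = "character"))
  mols <- lapply(tab$smiles, mol_parse)
  tab$canonical_key <- vapply(mols, function(m) m$canonical_key, character(1))
  if (validate) {
    got <- vapply(mols, mol_formula_string, character(1))
    bad <- got != tab$formula
    if (any(bad)) {
      stop("fixture formula mismatch for id(s) ",
           paste(tab$id[bad], collapse = ", "), ": name-derived ",
           paste(got[bad], collapse = ", "), " vs recorded ",
           paste(tab$formula[bad], collapse = ", "), call. = FALSE)
    }
  }
  split_by <- function(cls) {
    out <- tab[tab$class == cls, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(acids = split_by("acid"), aldehydes = split_by("aldehyde"),
       hydrazides = split_by("hydrazide"), products = split_by("product"),
       all = tab)
}

#' Building blocks of the reference fixtures
#'
#' @param fixtures Output of [reference_fixtures()].
#' @return List of `nah_block` objects (acids and aldehydes, ready for
#'   [enumerate_library()]).
#' @export
fixture_blocks <- function(fixtures = reference_fixtures()) {
  blocks <- list()
  for (i in seq_len(nrow(fixtures$acids))) {
    r <- fixtures$acids[i, ]
    blocks[[length(blocks) + 1]] <-
      building_block(r$id, mol_parse(r$smiles), "acid", source = r$name)
  }
  for (i in seq_len(nrow(fixtures$aldehydes))) {
    r <- fixtures$aldehydes[i, ]
    blocks[[length(blocks) + 1]] <-
      building_block(r$id, mol_parse(r$smiles), "aldehyde", source = r$name)
  }
  blocks
}
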