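# Format plumbing: SMILES lists, SDF V2000 with SD tags, manifest CSVs.

#' Read a SMILES list file
#'
#' One structure per line, optionally followed by a tab (or whitespace) and
#' an identifier. Empty lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return data.frame with columns `smiles`, `id` and `line` (source line
#'   number, for error reporting).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0) {
    return(data.frame(smiles = character(0), id = character(0),
                      line = integer(0)))
  }
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1),
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("L%04d", keep[i])
    }, character(1)),
    line = keep, stringsAsFactors = FALSE)
}

#' Read structures from a SMILES list or an SDF file
#'
#' File type is decided by extension (`.sdf` / `.sd` versus anything else).
#' SDF records are converted to SMILES through the toolkit so both routes
#' deliver the same record format.
#'
#' @param path File path.
#' @return data.frame with columns `smiles`, `id`, `line`.
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  if (grepl("\\.sdf?$", tolower(path))) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    recs <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
    recs <- recs[grepl("V2000", recs)]
    smi <- vapply(recs, function(r) {
      out <- ChemmineOB::convertFormat("SDF", "SMI",
                                       source = paste0(r, "\n$$$$\n"))
      sub("[\t\n].*$", "", out)
    }, character(1), USE.NAMES = FALSE)
    titles <- vapply(recs, function(r) {
      trimws(strsplit(r, "\n")[[1]][1])
    }, character(1), USE.NAMES = FALSE)
    ids <- ifelse(nzchar(titles), titles, sprintf("SDF%04d", seq_along(smi)))
    data.frame(smiles = smi, id = ids, line = seq_along(smi),
               stringsAsFactors = FALSE)
  } else {
    read_smiles_file(path)
  }
}

#' Write an enumerated library as SDF V2000 with SD tags
#'
#' Each record carries its provenance (acid and aldehyde ids), formula,
#' monoisotopic mass, Fsp3, stereocenter count, canonical key and the C=N
#' geometry as SD tags. Masses are written with 5 decimals and descriptor
#' fractions with 4, so repeated runs are diff-stable.
#'
#' @param lib List of `nah_compound` objects.
#' @param path Output file.
#' @return Invisibly, the number of records written.
#' @export
write_library_sdf <- function(lib, path) {
  blocks <- vapply(lib, function(cmp) {
    d <- cmp$descriptors
    .mol_to_molblock(cmp$mol, title = cmp$id, tags = list(
      id = cmp$id,
      acid_id = cmp$provenance[["acid_id"]],
      aldehyde_id = cmp$provenance[["aldehyde_id"]],
      formula = d$formula_string,
      monoisotopic_mass = sprintf("%.5f", d$monoisotopic_mass),
      fsp3 = sprintf("%.4f", d$fsp3),
      n_stereocenters = d$n_stereocenters,
      canonical_key = cmp$mol$canonical_key,
      cn_geometry = if (is.na(cmp$mol$geometry)) "" else cmp$mol$geometry))
  }, character(1))
  writeLines(blocks, path)
  invisible(length(blocks))
}

#' Manifest table of an enumerated library
#'
#' @param lib List of `nah_compound` objects.
#' @return data.frame (id, canonical_key, acid_id, aldehyde_id, formula,
#'   monoisotopic_mass, fsp3, n_stereocenters).
#' @export
library_manifest <- function(lib) {
  data.frame(
    id = vapply(lib, `[[`, character(1), "id"),
    canonical_key = library_keys(lib),
    acid_id = vapply(lib, function(x) x$provenance[["acid_id"]], character(1)),
    aldehyde_id = vapply(lib, function(x) x$provenance[["aldehyde_id"]],
                         character(1)),
    formula = vapply(lib, function(x) x$descriptors$formula_string,
                     character(1)),
    monoisotopic_mass = round(vapply(lib, function(x)
      x$descriptors$monoisotopic_mass, numeric(1)), 5),
    fsp3 = round(vapply(lib, function(x) x$descriptors$fsp3, numeric(1)), 4),
    n_stereocenters = vapply(lib, function(x)
      x$descriptors$n_stereocenters, integer(1)),
    stringsAsFactors = FALSE)
}
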