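# PAMPA permeability classification.

#' Load the bundled PAMPA permeability records
#'
#' Effective permeability (Pe, 1e-6 cm/s) and, for the gastrointestinal
#' model, the predicted absorbed fraction (Fa, percent).
#'
#' @return data.frame with columns `compound_id`, `assay` (GIT or BBB),
#'   `pe`, `fa_percent`.
#' @export
pampa_records <- function() {
  path <- system.file("extdata", "pampa.csv", package = "nahdesign")
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(compound_id = "character"))
  stopifnot(all(tab$assay %in% c("GIT", "BBB")), all(tab$pe >= 0, na.rm = TRUE))
  tab
}

#' Classify a PAMPA permeability record
#'
#' Gastrointestinal (GIT) records are banded by predicted absorbed fraction:
#' high 70-100 percent, medium 30-69, low below 30 (band boundaries are
#' inclusive on the low edge of each band, so values in (69, 70) fall in the
#' medium band). Blood-brain-barrier (BBB) records are banded by Pe
#' (1e-6 cm/s): CNS+ at Pe >= 4.0, CNS- below 2.0, CNS+/- in between. The
#' printed CNS+ and CNS+/- bands overlap at exactly 4.0; the affirmative
#' CNS+ call wins there.
#'
#' @param assay `"GIT"` or `"BBB"`.
#' @param pe Effective permeability, 1e-6 cm/s (required for BBB).
#' @param fa_percent Predicted absorbed fraction, percent (required for GIT;
#'   it is an assay-derived input, not computed from Pe).
#' @return Classification label: `"high"`, `"medium"`, `"low"` (GIT) or
#'   `"CNS+"`, `"CNS-"`, `"CNS+/-"` (BBB).
#' @examples
#' classify_pampa("GIT", fa_percent = 74)   # "high"
#' classify_pampa("BBB", pe = 2.453)        # "CNS+/-"
#' @export
classify_pampa <- function(assay = c("GIT", "BBB"), pe = NA_real_,
                           fa_percent = NA_real_) {
  assay <- match.arg(assay)
  if (assay == "GIT") {
    if (is.na(fa_percent)) {
      stop("GIT classification requires field 'fa_percent'", call. = FALSE)
    }
    stopifnot(fa_percent >= 0, fa_percent <= 100)
    if (fa_percent >= 70) "high" else if (fa_percent >= 30) "medium" else "low"
  } else {
    if (is.na(pe)) stop("BBB classification requires field 'pe'", call. = FALSE)
    stopifnot(pe >= 0)
    if (pe >= 4.0) "CNS+" else if (pe < 2.0) "CNS-" else "CNS+/-"
  }
}

#' Classify every record of a PAMPA table
#'
#' @param records data.frame in [pampa_records()] format.
#' @return The table with a `classification` column appended.
#' @export
classify_pampa_table <- function(records = pampa_records()) {
  records$classification <- vapply(seq_len(nrow(records)), function(i) {
    classify_pampa(records$assay[i], pe = records$pe[i],
                   fa_percent = records$fa_percent[i])
  }, character(1))
  records
}
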