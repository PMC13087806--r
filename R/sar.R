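# Quantitative pharmacology analytics: potency records, fold ratios,
# Cheng-Prusoff conversion, kinase-panel summaries and matched-pair SAR
# reports.

#' Load the bundled kinase potency records
#'
#' IC50 values (micromolar) and single-dose percent-inhibition measurements
#' for the N-acylhydrazone series and reference hits against ROCK1/ROCK2,
#' plus the six-kinase selectivity panel (IKKbeta/IKBKB, JAK1, MLCK/MYLK,
#' PKAcbeta, PKCalpha, PKG1alpha) profiled at 500 nM.
#'
#' @param which `"rock"` for the ROCK1/2 records, `"panel"` for the kinase
#'   panel.
#' @return data.frame of potency records.
#' @export
potency_records <- function(which = c("rock", "panel")) {
  which <- match.arg(which)
  file <- if (which == "rock") "rock_ic50.csv" else "kinase_panel.csv"
  path <- system.file("extdata", file, package = "nahdesign")
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(compound_id = "character"))
  if (which == "panel") {
    tab$measure <- "percent_inhibition"
    tab$flags <- ""
    names(tab)[names(tab) == "percent_inhibition"] <- "value"
  }
  tab$flags[is.na(tab$flags)] <- ""
  bad <- tab$measure == "percent_inhibition" &
    (tab$value < -10 | tab$value > 110)
  if (any(bad)) stop("percent inhibition outside the tolerated [-10, 110] band")
  tab
}

.get_ic50 <- function(records, compound_id, kinase, allow_extrapolated) {
  hit <- records$compound_id == as.character(compound_id) &
    records$kinase == kinase & records$measure == "IC50"
  if (!any(hit)) {
    stop(sprintf("no IC50 record for compound %s on %s", compound_id, kinase),
         call. = FALSE)
  }
  row <- records[which(hit)[1], ]
  if (!allow_extrapolated && grepl("extrapolated", row$flags)) {
    stop(sprintf("IC50 of compound %s on %s is extrapolated; pass ",
                 row$compound_id, kinase),
         "allow_extrapolated = TRUE to use it", call. = FALSE)
  }
  row
}

#' Fold ratio between two IC50 measurements
#'
#' Computes `a / b` on unrounded IC50 values. Orientation is the caller's
#' choice: selectivity is IC50(off-isoform) / IC50(on-isoform), a potency
#' gain is IC50(old) / IC50(new). Percent-inhibition records cannot be
#' compared this way and raise an error; extrapolated IC50s are excluded by
#' default and flagged on the result when allowed in.
#'
#' @param records data.frame of potency records ([potency_records()] format).
#' @param numerator,denominator Compound ids.
#' @param kinase Kinase name shared by both records (e.g. `"ROCK1"`), or a
#'   pair `c(numerator_kinase, denominator_kinase)` for cross-isoform
#'   selectivity ratios of one compound.
#' @param allow_extrapolated Include extrapolated IC50s (flag propagated).
#' @return Numeric ratio with attributes `extrapolated` and `display`
#'   (2-significant-digit rounding used for reporting).
#' @examples
#' rec <- potency_records("rock")
#' fold_ratio(rec, 13, 12, "ROCK1")  # potency gain of 12 over 13
#' @export
fold_ratio <- function(records, numerator, denominator, kinase,
                       allow_extrapolated = FALSE) {
  kin <- rep_len(kinase, 2)
  a <- .get_ic50(records, numerator, kin[1], allow_extrapolated)
  b <- .get_ic50(records, denominator, kin[2], allow_extrapolated)
  if (a$unit != b$unit) stop("IC50 units differ between records")
  r <- a$value / b$value
  structure(r,
            extrapolated = grepl("extrapolated", a$flags) ||
              grepl("extrapolated", b$flags),
            display = signif(r, 2))
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For ATP-competitive inhibition assayed at ATP concentration `atp_conc`
#' against Michaelis constant `km_atp`:
#' `Ki = IC50 / (1 + atp_conc / km_atp)`. Assays run below the Km (here
#' 1 uM ATP against Km ~ 10 uM) give IC50s that closely approximate Ki.
#'
#' @param ic50 IC50, micromolar (> 0).
#' @param atp_conc ATP concentration, micromolar (>= 0). Default 1.
#' @param km_atp Km for ATP, micromolar (> 0). Default 10.
#' @return Ki in micromolar.
#' @examples
#' cheng_prusoff_ki(0.051)            # ~0.0464 uM
#' @export
cheng_prusoff_ki <- function(ic50, atp_conc = 1, km_atp = 10) {
  stopifnot(all(ic50 > 0), atp_conc >= 0)
  if (any(km_atp <= 0)) stop("km_atp must be positive", call. = FALSE)
  ic50 / (1 + atp_conc / km_atp)
}

#' Invert the Cheng-Prusoff conversion
#'
#' @param ki Ki, micromolar.
#' @inheritParams cheng_prusoff_ki
#' @return IC50 in micromolar; exact inverse of [cheng_prusoff_ki()].
#' @export
ki_to_ic50 <- function(ki, atp_conc = 1, km_atp = 10) {
  stopifnot(all(ki > 0), atp_conc >= 0)
  if (any(km_atp <= 0)) stop("km_atp must be positive", call. = FALSE)
  ki * (1 + atp_conc / km_atp)
}

#' Off-target kinase panel summary for one compound
#'
#' Summarizes single-dose percent-inhibition records over the off-target
#' kinases (ROCK1/ROCK2 are excluded from "off-target" by definition):
#' maximum off-target inhibition, the kinases above a threshold, and the
#' count below it.
#'
#' @param records Percent-inhibition records at a common dose
#'   ([potency_records("panel")] format).
#' @param compound_id Compound to summarize.
#' @param threshold_percent Threshold (percent) separating notable from
#'   minimal inhibition. Default 10.
#' @return List with `compound_id`, `dose_uM`, `max_kinase`, `max_percent`,
#'   `above_threshold` (data.frame kinase, percent, sorted descending) and
#'   `n_below`.
#' @export
panel_summary <- function(records, compound_id, threshold_percent = 10) {
  sub <- records[records$compound_id == as.character(compound_id) &
                   records$measure == "percent_inhibition" &
                   !(records$kinase %in% c("ROCK1", "ROCK2")), , drop = FALSE]
  if (nrow(sub) == 0) {
    return(list(compound_id = as.character(compound_id), dose_uM = NA_real_,
                max_kinase = character(0), max_percent = NA_real_,
                above_threshold = data.frame(kinase = character(0),
                                             percent = numeric(0)),
                n_below = 0L))
  }
  if (length(unique(sub$dose_uM)) != 1) {
    stop("panel records must share a common dose", call. = FALSE)
  }
  ord <- order(-sub$value)
  above <- sub[sub$value > threshold_percent, , drop = FALSE]
  above <- above[order(-above$value), , drop = FALSE]
  list(compound_id = as.character(compound_id),
       dose_uM = sub$dose_uM[1],
       max_kinase = sub$kinase[ord[1]],
       max_percent = sub$value[ord[1]],
       above_threshold = data.frame(kinase = above$kinase,
                                    percent = above$value),
       n_below = sum(sub$value <= threshold_percent))
}

#' Load the bundled structural annotations of the congeneric series
#'
#' @return data.frame with columns `compound_id`, `hinge_scaffold`
#'   (aldehyde-derived hinge-binding heteroaromatic), `linker_ch2_count`
#'   (methylene units between carbonyl and terminal ring) and
#'   `terminal_group`.
#' @export
sar_annotations <- function() {
  path <- system.file("extdata", "sar_annotations.csv", package = "nahdesign")
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(compound_id = "character"))
  names(tab)[names(tab) == "linker_ch2"] <- "linker_ch2_count"
  tab
}

#' Matched-pair SAR report
#'
#' Emits homologation pairs (same hinge scaffold and terminal group, linker
#' length differing by exactly one methylene) and bioisostere pairs (same
#' linker and terminal group, different hinge scaffold), with the IC50 fold
#' ratio per kinase. Within each pair the less potent compound is the
#' numerator, so ratios read as fold gains. Compounds without annotation are
#' excluded with a warning; extrapolated IC50s are excluded from ratios.
#'
#' @param records IC50 records ([potency_records("rock")] format).
#' @param annotations Annotation table ([sar_annotations()] format).
#' @param kinases Kinases to compute ratios for. Default ROCK1 and ROCK2.
#' @return data.frame with one row per pair x kinase: `pair_type`,
#'   `compound_a`, `compound_b`, `kinase`, `ic50_a`, `ic50_b`, `fold`
#'   (`ic50_a / ic50_b`).
#' @export
sar_table <- function(records, annotations = sar_annotations(),
                      kinases = c("ROCK1", "ROCK2")) {
  ids <- unique(records$compound_id[records$measure == "IC50" &
                                      !grepl("extrapolated", records$flags)])
  unann <- setdiff(ids, annotations$compound_id)
  if (length(unann) > 0) {
    warning("excluding unannotated compound(s): ",
            paste(unann, collapse = ", "))
    ids <- intersect(ids, annotations$compound_id)
  }
  ann <- annotations[annotations$compound_id %in% ids, , drop = FALSE]
  rows <- list()
  if (nrow(ann) >= 2) {
    combs <- utils::combn(seq_len(nrow(ann)), 2)
    for (k in seq_len(ncol(combs))) {
      a <- ann[combs[1, k], ]
      b <- ann[combs[2, k], ]
      type <- NULL
      if (a$hinge_scaffold == b$hinge_scaffold &&
          a$terminal_group == b$terminal_group &&
          abs(a$linker_ch2_count - b$linker_ch2_count) == 1) {
        type <- "homologation"
      } else if (a$linker_ch2_count == b$linker_ch2_count &&
                 a$terminal_group == b$terminal_group &&
                 a$hinge_scaffold != b$hinge_scaffold) {
        type <- "bioisostere"
      }
      if (is.null(type)) next
      for (kin in kinases) {
        va <- records$value[records$compound_id == a$compound_id &
                              records$kinase == kin & records$measure == "IC50"]
        vb <- records$value[records$compound_id == b$compound_id &
                              records$kinase == kin & records$measure == "IC50"]
        if (length(va) == 0 || length(vb) == 0) next
        hi <- if (va[1] >= vb[1]) a$compound_id else b$compound_id
        lo <- if (va[1] >= vb[1]) b$compound_id else a$compound_id
        rows[[length(rows) + 1]] <- data.frame(
          pair_type = type, compound_a = hi, compound_b = lo, kinase = kin,
          ic50_a = max(va[1], vb[1]), ic50_b = min(va[1], vb[1]),
          fold = max(va[1], vb[1]) / min(va[1], vb[1]))
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pair_type = character(0), compound_a = character(0),
                      compound_b = character(0), kinase = character(0),
                      ic50_a = numeric(0), ic50_b = numeric(0),
                      fold = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
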