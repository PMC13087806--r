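# Descriptor filtering of the enumerated library.

#' Descriptor filter specification
#'
#' The library prioritization keeps compounds with an sp3 carbon fraction of
#' at least `fsp3_min` and at most `max_stereocenters` tetrahedral
#' stereocenters. The defaults (0.1 and 0) retain flexible, achiral
#' candidates suitable for downstream docking.
#'
#' @param fsp3_min Minimum Fsp3, in \[0, 1\]. Default 0.1.
#' @param max_stereocenters Maximum number of stereocenters. Default 0.
#' @return `nah_filter_spec` object.
#' @export
filter_spec <- function(fsp3_min = 0.1, max_stereocenters = 0L) {
  stopifnot(is.numeric(fsp3_min), fsp3_min >= 0, fsp3_min <= 1,
            max_stereocenters >= 0)
  structure(list(fsp3_min = fsp3_min,
                 max_stereocenters = as.integer(max_stereocenters)),
            class = "nah_filter_spec")
}

#' @export
print.nah_filter_spec <- function(x, ...) {
  cat(sprintf("<filter spec> Fsp3 >= %g, stereocenters <= %d\n",
              x$fsp3_min, x$max_stereocenters))
  invisible(x)
}

#' Apply the descriptor filter to a compound library
#'
#' Retains exactly the compounds with `fsp3 >= fsp3_min` and
#' `n_stereocenters <= max_stereocenters`. The operation is idempotent and
#' independent of input order.
#'
#' @param lib List of `nah_compound` objects (descriptors present).
#' @param spec A [filter_spec()].
#' @return Filtered list (subset of `lib`, order preserved).
#' @export
apply_filters <- function(lib, spec = filter_spec()) {
  stopifnot(inherits(spec, "nah_filter_spec"))
  keep <- vapply(lib, function(x) {
    d <- x$descriptors
    d$fsp3 >= spec$fsp3_min && d$n_stereocenters <= spec$max_stereocenters
  }, logical(1))
  lib[keep]
}
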