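# Two-dimensional chemical-space embedding of fingerprint bit matrices:
# Z-score standardization of the informative bits, PCA to two components,
# then min-max scaling of the scores to [0, 1] over the fitted set.

#' Fit the chemical-space embedding
#'
#' Constant fingerprint bits are dropped (their Z-score is undefined), the
#' remaining bit columns are standardized to zero mean and unit variance,
#' and the top two principal components are extracted. Each component is
#' sign-fixed so that its largest-magnitude loading is positive, giving a
#' reproducible orientation. The per-axis score ranges over the fitted set
#' are stored for the final min-max normalization to \[0, 1\].
#'
#' @param fps List of fingerprints (or an already-stacked bit matrix).
#' @return An object of class `nah_embedding` with elements `kept_bits`,
#'   `center`, `scale`, `rotation` (p x 2), `axis_ranges` (2 x 2),
#'   `explained_variance` (proportions for the two components) and `scores`
#'   (scaled training coordinates).
#' @export
fit_embedding <- function(fps) {
  x <- if (is.matrix(fps)) fps else fp_matrix(fps)
  if (nrow(unique(x)) < 3) {
    stop("degenerate input: need at least 3 distinct fingerprints to fit a ",
         "2D embedding", call. = FALSE)
  }
  sds <- apply(x, 2, sd)
  kept <- which(sds > 0)
  xs <- scale(x[, kept, drop = FALSE])
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  # deterministic sign convention: largest |loading| of each component
  # is positive
  for (j in 1:2) {
    peak <- which.max(abs(rot[, j]))
    if (rot[peak, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- xs %*% rot
  ranges <- apply(scores, 2, range)
  model <- structure(list(
    kept_bits = kept,
    center = attr(xs, "scaled:center"),
    scale = attr(xs, "scaled:scale"),
    rotation = rot,
    axis_ranges = ranges,
    explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[1:2],
    n_fit = nrow(x)
  ), class = "nah_embedding")
  model$scores <- project(model, x)
  model
}

#' @export
print.nah_embedding <- function(x, ...) {
  cat(sprintf(paste0("<chemical-space embedding> fitted on %d fingerprints, ",
                     "%d informative bits\n  explained variance: ",
                     "PC1 %.1f%%, PC2 %.1f%%\n"),
              x$n_fit, length(x$kept_bits),
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  invisible(x)
}

#' Project fingerprints into the fitted chemical space
#'
#' Coordinates are min-max scaled with the ranges stored at fit time, so the
#' fitted set spans exactly \[0, 1\] on each axis. Held-out fingerprints may
#' fall outside \[0, 1\]; they are reported unclamped and flagged in the
#' `out_of_range` column. A zero-range axis maps to 0 with a warning.
#'
#' @param model A fitted `nah_embedding`.
#' @param fps List of fingerprints or a bit matrix (full fingerprint length).
#' @return data.frame with columns `x`, `y`, `out_of_range`.
#' @export
project <- function(model, fps) {
  stopifnot(inherits(model, "nah_embedding"))
  m <- if (is.matrix(fps)) fps else fp_matrix(fps)
  xs <- sweep(m[, model$kept_bits, drop = FALSE], 2, model$center)
  xs <- sweep(xs, 2, model$scale, "/")
  raw <- xs %*% model$rotation
  out <- matrix(0, nrow(raw), 2)
  for (j in 1:2) {
    rng <- model$axis_ranges[, j]
    span <- rng[2] - rng[1]
    if (span <= 0) {
      warning(sprintf("axis %d has zero range over the fitted set; ",
                      j), "coordinates set to 0")
      out[, j] <- 0
    } else {
      out[, j] <- (raw[, j] - rng[1]) / span
    }
  }
  eps <- 1e-9
  data.frame(x = out[, 1], y = out[, 2],
             out_of_range = out[, 1] < -eps | out[, 1] > 1 + eps |
               out[, 2] < -eps | out[, 2] > 1 + eps)
}

#' @export
predict.nah_embedding <- function(object, newdata, ...) {
  project(object, newdata)
}

#' Embed a compound library into chemical space
#'
#' Convenience wrapper: fingerprints every compound, fits the embedding and
#' attaches `(x, y)` coordinates to each compound.
#'
#' @param lib List of `nah_compound` objects.
#' @return List with `lib` (compounds with `$embedding` set), `model` and
#'   `coords` (data.frame id, x, y, fsp3 - the columns used for
#'   chemical-space scatter plots color-coded by Fsp3).
#' @export
embed_library <- function(lib) {
  fps <- lapply(lib, function(cmp) {
    if (is.null(cmp$fingerprint)) ecfp4(cmp$mol) else cmp$fingerprint
  })
  model <- fit_embedding(fps)
  coords <- project(model, fps)
  for (k in seq_along(lib)) {
    lib[[k]]$fingerprint <- fps[[k]]
    lib[[k]]$embedding <- c(x = coords$x[k], y = coords$y[k])
  }
  list(lib = lib, model = model,
       coords = data.frame(id = vapply(lib, `[[`, character(1), "id"),
                           x = coords$x, y = coords$y,
                           fsp3 = vapply(lib, function(z) z$descriptors$fsp3,
                                         numeric(1))))
}
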