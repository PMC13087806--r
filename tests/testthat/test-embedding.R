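test_that("embedding requires at least three distinct fingerprints", {
  fp1 <- ecfp4(mol_parse("CCO"))
  fp2 <- ecfp4(mol_parse("CCN"))
  expect_error(fit_embedding(c(rep(list(fp1), 10), list(fp2))), "degenerate")
})

test_that("components are orthogonal and training coordinates span [0,1]", {
  lib <- ref_library()
  fps <- lapply(lib, function(x) ecfp4(x$mol))
  model <- fit_embedding(fps)
  expect_lt(abs(sum(model$rotation[, 1] * model$rotation[, 2])), 1e-8)
  coords <- project(model, fps)
  expect_equal(min(coords$x), 0, tolerance = 1e-12)
  expect_equal(max(coords$x), 1, tolerance = 1e-12)
  expect_equal(min(coords$y), 0, tolerance = 1e-12)
  expect_equal(max(coords$y), 1, tolerance = 1e-12)
  expect_false(any(coords$out_of_range))
})

test_that("pipeline agrees with a dense eigendecomposition oracle", {
  set.seed(2024)
  x <- matrix(rbinom(50 * 1024, 1, 0.08), nrow = 50, ncol = 1024)
  # plant a dominant variance direction
  x[1:25, 3:40] <- 1L
  model <- fit_embedding(x)
  kept <- which(apply(x, 2, sd) > 0)
  xs <- scale(x[, kept, drop = FALSE])
  ev <- eigen(crossprod(xs) / (nrow(xs) - 1), symmetric = TRUE)
  expect_equal(model$explained_variance[1],
               ev$values[1] / sum(ev$values), tolerance = 1e-6)
  ref <- xs %*% ev$vectors[, 1:2]
  mine <- project(model, x)
  for (j in 1:2) {
    r <- ref[, j]
    r01 <- (r - min(r)) / (max(r) - min(r))
    dev <- min(max(abs(mine[[j]] - r01)), max(abs(mine[[j]] - (1 - r01))))
    expect_lt(dev, 1e-6)
  }
})

test_that("min-max scaling pins the axis extremes to 0 and 1", {
  fps <- list(ecfp4(mol_parse("CCO")), ecfp4(mol_parse("c1ccccc1")),
              ecfp4(mol_parse("CCCCN")))
  model <- fit_embedding(fps)
  full <- project(model, fps)
  expect_setequal(round(range(full$x), 12), c(0, 1))
  expect_setequal(round(range(full$y), 12), c(0, 1))
})

test_that("held-out projections may leave [0,1] and are flagged, not clamped", {
  set.seed(7)
  x <- matrix(rbinom(12 * 256, 1, 0.3), nrow = 12)
  model <- fit_embedding(cbind(x, matrix(0L, 12, 1024 - 256)))
  # bit vector maximizing the PC1 score over all binary vectors: it can only
  # land at or beyond the training maximum, and beyond it for random data
  out <- integer(1024)
  out[model$kept_bits] <- as.integer(model$rotation[, 1] > 0)
  held <- project(model, matrix(out, nrow = 1))
  expect_true(held$out_of_range[1])
  expect_true(held$x[1] < 0 || held$x[1] > 1 || held$y[1] < 0 || held$y[1] > 1)
})

test_that("predict method matches project", {
  lib <- ref_library()[1:6]
  fps <- lapply(lib, function(x) ecfp4(x$mol))
  model <- fit_embedding(fps)
  expect_identical(predict(model, fps), project(model, fps))
})
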