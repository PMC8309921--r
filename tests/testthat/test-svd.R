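# Singular-vector basis: SVD contracts, sign convention, projection.

test_that("a rank-1 training set yields its normalized spectrum with p1 = 1", {
  wl <- spectralGrid(770, 778, 0.1)
  s <- 100 + sin(wl)
  x <- outer(c(1, 2, 3, 0.5), s)
  basis <- computeSVs(x, nKeep = 1, wavelengths = wl)
  expect_equal(drop(basisVectors(basis)), s / sqrt(sum(s^2)), tolerance = 1e-10)
  expect_equal(explainedVariance(basis), 1, tolerance = 1e-10)
})

test_that("the full SVD reconstructs the training matrix", {
  tr <- fxTraining(nScenes = 50)
  x <- t(radianceValues(tr))
  basis <- computeSVs(tr, nKeep = 50)
  w <- crossprod(basisVectors(basis), t(x))  # coefficients of each scene
  recon <- t(basisVectors(basis) %*% w)
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-8)
  expect_equal(sum(explainedVariance(basis)), 1, tolerance = 1e-10)
})

test_that("vectors and singular values match a Gram-matrix eigendecomposition", {
  set.seed(99)
  wl <- spectralGrid(771, 778, 0.044)[1:160]
  x <- matrix(rnorm(50 * 160, mean = 10), 50, 160)
  basis <- computeSVs(x, nKeep = 6, wavelengths = wl)
  eg <- eigen(crossprod(x), symmetric = TRUE)  # channels x channels Gram
  for (j in 1:6) {
    expect_equal(singularValues(basis)[j], sqrt(eg$values[j]),
                 tolerance = 1e-6)
    v <- basisVectors(basis)[, j]
    u <- eg$vectors[, j]
    expect_lt(min(sum(abs(v - u)), sum(abs(v + u))) / sum(abs(v)), 1e-6)
  }
})

test_that("basis contracts hold: orthonormality, ordering, variance fractions", {
  basis <- fxBasis()
  v <- basisVectors(basis)
  gram <- crossprod(v)
  expect_lt(max(abs(gram - diag(ncol(v)))), 1e-10)
  expect_false(is.unsorted(rev(singularValues(basis))))
  p <- explainedVariance(basis)
  expect_true(all(p >= 0 & p <= 1))
  expect_lte(sum(p), 1 + 1e-10)
})

test_that("explained variance is invariant to global scaling of the training set", {
  tr <- fxTraining(nScenes = 50)
  x <- t(radianceValues(tr))
  p1 <- explainedVariance(computeSVs(x, 5, wavelengths(tr)))
  p2 <- explainedVariance(computeSVs(x * 37.5, 5, wavelengths(tr)))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the sign convention aligns the leading vector with the mean spectrum", {
  tr <- fxTraining(nScenes = 50)
  basis <- computeSVs(tr, nKeep = 8)
  mn <- rowMeans(radianceValues(tr))
  expect_gt(cor(basisVectors(basis)[, 1], mn), 0.99)
  # the convention is defined relative to the input's own mean spectrum
  basis2 <- computeSVs(-t(radianceValues(tr)), nKeep = 1,
                       wavelengths = wavelengths(tr))
  expect_gte(sum(basisVectors(basis2)[, 1] * rowMeans(-radianceValues(tr))), 0)
})

test_that("degenerate and oversized requests are rejected", {
  wl <- spectralGrid(770, 771, 0.1)
  expect_error(computeSVs(matrix(0, 5, length(wl)), 2, wl), "zero")
  expect_error(computeSVs(matrix(1, 5, length(wl)), 9, wl), "nKeep")
  expect_error(computeSVs(matrix(1, 1, length(wl)), 1, wl), "2 scenes")
})

test_that("projection is the orthonormal expansion and leaves an orthogonal residual", {
  basis <- fxBasis()
  v <- basisVectors(basis)
  expect_equal(unname(projectSpectrum(basis, v[, 1])),
               c(1, rep(0, ncol(v) - 1)), tolerance = 1e-10)
  expect_equal(unname(projectSpectrum(basis, 2 * v[, 1] + 3 * v[, 2])),
               c(2, 3, rep(0, ncol(v) - 2)), tolerance = 1e-10)
  spec <- radianceValues(fxTraining())[, 3]
  w <- projectSpectrum(basis, spec)
  resid <- spec - drop(v %*% w)
  expect_lt(max(abs(crossprod(v, resid))) / sqrt(sum(spec^2)), 1e-10)
  expect_error(projectSpectrum(basis, spec[-1]), "length")
  expect_error(projectSpectrum(basis, spec, wavelengths = wavelengths(basis) + 1),
               "match")
})

test_that("rank-limited reconstruction is a projection", {
  basis <- fxBasis()
  spec <- radianceValues(fxTraining())[, 10]
  r5 <- reconstructSpectrum(basis, spec, nUse = 5)
  # idempotent and within-span
  expect_equal(reconstructSpectrum(basis, r5, nUse = 5), r5, tolerance = 1e-9)
  w <- projectSpectrum(basis, r5)
  expect_equal(unname(w[6:8]), rep(0, 3), tolerance = 1e-8)
})
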