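# Weighted least squares, BIC model selection and the end-to-end retrieval.

test_that("fit weights are the reciprocal radiance uncertainty", {
  expect_equal(computeWeights(rep(100, 4), snrModel(300)), rep(3, 4))
  # doubling the radiance halves the weight under constant SNR
  expect_equal(computeWeights(rep(200, 4), snrModel(300)), rep(1.5, 4))
  expect_equal(computeWeights(rep(100, 4)), rep(1, 4))  # unweighted mode
})

test_that("non-positive channels are masked, keep vector length, and drop out of the RSS", {
  l <- rep(100, 160)
  l[37] <- -1
  expect_warning(w <- computeWeights(l, snrModel(300)), "masked")
  expect_length(w, 160)
  expect_equal(w[37], 0)
  resid <- rep(1, 160)
  expect_equal(computeRss(l, l - resid, w), sum((3 * 1)^2) * 159)
})

test_that("weighted fits match the normal-equations oracle", {
  basis <- fxBasis()
  cfg <- retrievalConfig()
  wl <- fxGrid()
  set.seed(17)
  for (rep in 1:5) {
    sc <- simulateScenes(1, wl, fxSolar(), fsTrue = runif(1, 0, 2),
                         seed = 800 + rep)
    idx <- which(wl >= 771 & wl < 778)
    y <- radianceValues(sc)[idx, 1]
    w <- computeWeights(y, snrValues(sc)[idx, 1])
    dm <- buildDesignMatrix(basis, cfg, nv = 5)
    fit <- fitLinearModel(dm, y, w)
    oracle <- normalEquationsFit(dm@matrix, y, w)
    expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-6)
  }
})

test_that("a duplicated column raises a rank-deficiency error naming it", {
  basis <- fxBasis()
  dm <- buildDesignMatrix(basis, retrievalConfig(), nv = 3)
  x <- cbind(dm@matrix, dup = dm@matrix[, "sv2"])
  y <- rowSums(x)
  expect_error(fitLinearModel(x, y), "rank deficient.*(sv2|dup)")
})

test_that("too few unmasked channels is an error", {
  basis <- fxBasis()
  dm <- buildDesignMatrix(basis, retrievalConfig(), nv = 3)
  y <- rowSums(dm@matrix)
  w <- rep(0, length(y)); w[1:4] <- 1
  expect_error(fitLinearModel(dm, y, w), "unmasked")
})

test_that("residual sum of squares follows the weighting convention", {
  expect_equal(computeRss(c(5), c(2), c(2)), 36)          # (2 * 3)^2
  expect_equal(computeRss(c(5), c(2), c(2), form = "linear"), 18)  # 2 * 9
  x <- rnorm(50); p <- rnorm(50)
  expect_equal(computeRss(x, p, rep(1, 50)), sum((x - p)^2))
  expect_equal(computeRss(x, x, runif(50, 1, 2)), 0)
})

test_that("BIC matches its closed form and penalizes parameters monotonically", {
  expect_equal(computeBic(160, 160, 7), 7 * log(160), tolerance = 1e-12)
  expect_equal(computeBic(100, 160, 9) - computeBic(100, 160, 7),
               2 * log(160), tolerance = 1e-12)
  expect_error(computeBic(0, 160, 7), "rss")
  expect_error(computeBic(1, 0, 7), "nChannels")
})

test_that("BIC selection returns the verified minimizer over candidates", {
  basis <- fxBasis()
  wl <- fxGrid()
  sc <- simulateScenes(1, wl, fxSolar(), fsTrue = 0.8, seed = 31)
  idx <- which(wl >= 771 & wl < 778)
  y <- radianceValues(sc)[idx, 1]
  w <- computeWeights(y, snrValues(sc)[idx, 1])

  one <- selectNumSvs(basis, retrievalConfig(nvCandidates = 5), y, w)
  expect_equal(one$nvSelected, 5)

  cfg <- retrievalConfig(nvCandidates = 3:6)
  sel <- selectNumSvs(basis, cfg, y, w)
  expect_setequal(names(sel$bicByNv), as.character(3:6))
  best <- sel$bicByNv[as.character(sel$nvSelected)]
  expect_true(all(best <= sel$bicByNv + 1e-12))
  # re-verify every reported BIC value independently
  for (nv in 3:6) {
    dm <- buildDesignMatrix(basis, cfg, nv)
    fit <- fitLinearModel(dm, y, w)
    rss <- computeRss(y, fit$fitted, w)
    expect_equal(unname(sel$bicByNv[as.character(nv)]),
                 computeBic(rss, length(y), ncol(dm@matrix)),
                 tolerance = 1e-10)
  }
})

test_that("noiseless in-span scenes are recovered exactly", {
  basis <- fxBasis()
  wl <- fxGrid()
  nf <- reconstructSpectrum(basis, radianceValues(fxTraining())[, 2], nUse = 5)
  spec <- nf + 0.8 * gaussianHf(wl, 30)
  res <- retrieveSif(spec, basis, retrievalConfig())
  expect_true(res@valid)
  expect_lt(abs(res@fs - 0.8) / 0.8, 1e-6)
  expect_equal(res@sifAtRef, res@fs * gaussianHf(775, 30), tolerance = 1e-12)
})

test_that("retrieval is scale equivariant and additive in the emission term", {
  basis <- fxBasis()
  wl <- fxGrid()
  sc <- simulateScenes(1, wl, fxSolar(), fsTrue = 0.6, seed = 55)
  y <- radianceValues(sc)[, 1]
  cfg <- retrievalConfig(nvCandidates = 5)
  f1 <- retrieveSif(y, basis, cfg)@fs
  # scale equivariance (unit-norm basis vectors are scale-free)
  f10 <- retrieveSif(10 * y, basis, cfg)@fs
  expect_equal(f10, 10 * f1, tolerance = 1e-9)
  # adding c * hF raises the retrieved amplitude by exactly c
  f2 <- retrieveSif(y + 1.3 * gaussianHf(wl, 30), basis, cfg)@fs
  expect_equal(f2 - f1, 1.3, tolerance = 1e-8)
})

test_that("BIC selection is invariant to radiance rescaling", {
  basis <- fxBasis()
  wl <- fxGrid()
  sc <- simulateScenes(3, wl, fxSolar(), fsTrue = c(0, 0.5, 1.5), seed = 91)
  cfg <- retrievalConfig(weighting = FALSE)
  for (i in 1:3) {
    y <- radianceValues(sc)[, i]
    a <- retrieveSif(y, basis, cfg)
    b <- retrieveSif(2 * y, basis, cfg)
    expect_equal(a@nvSelected, b@nvSelected)
    # BIC values shift by the common additive constant n * ln(c^2)
    shift <- length(a@residuals) * log(4)
    expect_equal(unname(b@bicByNv - a@bicByNv),
                 rep(shift, length(a@bicByNv)), tolerance = 1e-6)
  }
})

test_that("nested models cannot increase the residual sum of squares", {
  basis <- fxBasis()
  wl <- fxGrid()
  sc <- simulateScenes(1, wl, fxSolar(), fsTrue = 1, seed = 12)
  idx <- which(wl >= 771 & wl < 778)
  y <- radianceValues(sc)[idx, 1]
  w <- computeWeights(y, snrValues(sc)[idx, 1])
  rss <- vapply(2:8, function(nv) {
    dm <- buildDesignMatrix(basis, retrievalConfig(), nv)
    fit <- fitLinearModel(dm, y, w)
    computeRss(y, fit$fitted, w)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("reported uncertainty is calibrated against the empirical spread", {
  # fixed model order: this checks the weighted-least-squares covariance
  # itself; BIC selection adds post-selection spread on top of it
  basis <- fxBasis()
  wl <- fxGrid()
  sc <- simulateScenes(500, wl, fxSolar(), fsTrue = 0.8, seed = 13)
  out <- retrieveBatch(sc, basis, retrievalConfig(nvCandidates = 5))
  ratio <- sd(out$fs) / mean(out$fs_uncertainty)
  expect_lt(abs(ratio - 1), 0.25)
})

test_that("batch retrieval recovers amplitudes with near-unit slope", {
  basis <- fxBasis()
  wl <- fxGrid()
  set.seed(2)
  fsv <- runif(100, 0, 2)
  sc <- simulateScenes(100, wl, fxSolar(), fsTrue = fsv, seed = 9)
  out <- retrieveBatch(sc, basis, retrievalConfig())
  expect_equal(nrow(out), 100)
  expect_true(all(out$flag == "ok"))
  slope <- unname(coef(lm(out$fs ~ colData(sc)$fs_true))[2])
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("batch retrieval isolates failures and handles empty input", {
  basis <- fxBasis()
  wl <- fxGrid()
  sc <- simulateScenes(5, wl, fxSolar(), fsTrue = 0.5, seed = 3)
  rad <- radianceValues(sc)
  rad[, 3] <- NA_real_
  bad <- SpectraSet(rad, wl, snr = snrValues(sc))
  out <- suppressWarnings(retrieveBatch(bad, basis, retrievalConfig()))
  expect_equal(sum(out$flag == "ok"), 4)
  expect_match(out$flag[3], "error")
  expect_true(is.na(out$fs[3]))
  expect_false(any(is.na(out$fs[-3])))

  empty <- SpectraSet(matrix(numeric(0), 0, 0), numeric(0))
  expect_warning(res <- retrieveBatch(empty, basis, retrievalConfig()),
                 "empty")
  expect_equal(nrow(res), 0)
})

test_that("retrieval failures carry diagnostics instead of silent NaN", {
  basis <- fxBasis()
  expect_error(retrieveSif(rep(1, 10), basis, retrievalConfig()), "length")
  expect_error(retrieveSif(radianceValues(fxTraining())[, 1], basis,
                           retrievalConfig(window = c(600, 601))),
               "no channels")
})
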