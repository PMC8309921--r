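# Forward model: Gaussian emission shape and design-matrix assembly.

test_that("the Gaussian emission shape matches its closed form", {
  expect_equal(gaussianHf(740, sigma = 30), 1, tolerance = 1e-12)
  expect_equal(gaussianHf(770, sigma = 30), exp(-0.5), tolerance = 1e-12)
  expect_equal(gaussianHf(775, sigma = 30), exp(-35^2 / 1800),
               tolerance = 1e-12)
  # symmetry about the peak and peak height phi
  expect_equal(gaussianHf(740 + 13.7, 30), gaussianHf(740 - 13.7, 30))
  expect_equal(gaussianHf(740, 30, phi = 2.5), 2.5)
  expect_error(gaussianHf(740, sigma = -1), "sigma")
})

test_that("emission-shape integral is stable under grid refinement", {
  trap <- function(step) {
    wl <- seq(771, 778, by = step)
    h <- gaussianHf(wl, 30)
    sum((h[-1] + h[-length(h)]) / 2 * diff(wl))
  }
  expect_equal(trap(0.044), trap(0.0044), tolerance = 1e-6)
})

test_that("design matrix has the documented block structure", {
  basis <- fxBasis()
  cfg0 <- retrievalConfig(nP = 0)
  dm0 <- buildDesignMatrix(basis, cfg0, nv = 1)
  expect_equal(ncol(dm0@matrix), 2)
  expect_equal(colnames(dm0@matrix), c("v1.l0", "Fs"))

  cfg1 <- retrievalConfig(nP = 1)
  dm5 <- buildDesignMatrix(basis, cfg1, nv = 5)
  expect_equal(ncol(dm5@matrix), 7)  # (1+1) + 4 + 1

  # column count law over a grid of model orders
  for (nP in 0:2) {
    for (nv in c(1, 2, 4, 8)) {
      dm <- buildDesignMatrix(basis, retrievalConfig(nP = nP), nv)
      expect_equal(ncol(dm@matrix), (nP + 1) + (nv - 1) + 1)
    }
  }

  # last column is the emission shape on the window grid
  idx <- which(wavelengths(basis) >= 771 & wavelengths(basis) < 778)
  expect_equal(unname(dm5@matrix[, "Fs"]),
               gaussianHf(wavelengths(basis)[idx], 30))
  # window channels are half-open [min, max)
  expect_true(all(wavelengths(dm5) >= 771 & wavelengths(dm5) < 778))
})

test_that("invalid design requests raise errors", {
  basis <- fxBasis()
  expect_error(buildDesignMatrix(basis, retrievalConfig(window = c(750, 751)), 3),
               "no channels")
  expect_error(buildDesignMatrix(basis, retrievalConfig(), nv = 99), "basis size")
})

test_that("the normalized coordinate keeps the design well conditioned", {
  basis <- fxBasis()
  dm <- buildDesignMatrix(basis, retrievalConfig(nP = 1), nv = 5)
  expect_lt(designCondition(dm), 1e6)
})

test_that("forward evaluation is the linear combination of columns", {
  basis <- fxBasis()
  dm <- buildDesignMatrix(basis, retrievalConfig(), nv = 4)
  k <- ncol(dm@matrix)
  expect_equal(predictRadiance(dm, rep(0, k)), rep(0, nrow(dm@matrix)))
  cf <- rep(0, k); cf[k] <- 2.5
  expect_equal(predictRadiance(dm, cf), 2.5 * unname(dm@matrix[, k]))
  expect_error(predictRadiance(dm, rep(0, k - 1)), "coefficients")

  # solve-then-evaluate round trip on an in-span spectrum
  truthCf <- c(5, 0.7, 0.2, -0.1, 0.05, 0.6)
  spec <- predictRadiance(dm, truthCf)
  fit <- fitLinearModel(dm, spec)
  expect_lt(max(abs(fit$residuals)) / max(abs(spec)), 1e-8)
  expect_equal(unname(fit$coefficients), truthCf, tolerance = 1e-6)
})
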