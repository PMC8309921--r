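# Synthetic-spectrum simulator: solar irradiance, scene radiance, noise and
# training-set generation.

test_that("solar irradiance reproduces its closed form on the grid", {
  wl <- spectralGrid(773, 775, 0.05)  # 774.00 is exactly on this grid
  flat <- solarModel(continuumCoeffs = 100, lines = data.frame())
  expect_equal(makeSolarIrradiance(wl, flat), rep(100, length(wl)))

  one <- solarModel(continuumCoeffs = 100,
                    lines = data.frame(center = 774, depth = 0.5,
                                       width = 0.05))
  isc <- makeSolarIrradiance(wl, one)
  expect_equal(isc[wl == 774], 50)

  two <- solarModel(continuumCoeffs = 100,
                    lines = data.frame(center = c(773.5, 774.5),
                                       depth = c(0.3, 0.6),
                                       width = c(0.05, 0.05)))
  isc2 <- makeSolarIrradiance(wl, two)
  # closed-form product evaluated independently
  ref <- 100 *
    (1 - 0.3 * exp(-(wl - 773.5)^2 / (2 * 0.05^2))) *
    (1 - 0.6 * exp(-(wl - 774.5)^2 / (2 * 0.05^2)))
  expect_equal(isc2, ref)
  expect_lt(abs(wl[which.min(isc2)] - 774.5), 0.05 + 1e-12)
  expect_equal(min(isc2), min(ref))
  expect_true(all(isc2 > 0))
})

test_that("non-positive continuum is rejected", {
  wl <- spectralGrid(770, 778, 0.1)
  bad <- solarModel(continuumCoeffs = c(1, -5), lines = data.frame())
  expect_error(makeSolarIrradiance(wl, bad), "non-positive")
})

test_that("scene radiance follows the Lambertian forward equation", {
  wl <- spectralGrid(770, 778, 0.1)
  flat <- solarModel(continuumCoeffs = 100, lines = data.frame())

  # Fs = 0, flat reflectance r, mu0 = 1 -> constant r * I / pi
  tr0 <- sceneTruth(reflectanceCoeffs = 0.4, mu0 = 1, fsTrue = 0)
  s0 <- simulateToaRadiance(wl, flat, tr0)
  expect_equal(s0$radiance, rep(0.4 * 100 / pi, length(wl)))

  # zero reflectance isolates the fluorescence term exactly
  tr1 <- sceneTruth(reflectanceCoeffs = 0, mu0 = 1, fsTrue = 1)
  s1 <- simulateToaRadiance(wl, flat, tr1)
  expect_equal(s1$radiance, gaussianHf(wl, 30))
})

test_that("fluorescence is exactly additive and scales with its amplitude", {
  wl <- spectralGrid(730, 750, 0.05)  # contains the 740 nm emission peak
  sun <- solarModel()
  hf <- gaussianHf(wl, 30)
  base <- simulateToaRadiance(wl, sun, sceneTruth(fsTrue = 0))$radiance
  for (a in c(0.3, 0.8, 2.5)) {
    s <- simulateToaRadiance(wl, sun, sceneTruth(fsTrue = a))$radiance
    expect_equal(s - base, a * hf, tolerance = 1e-12)
  }
  # at the emission peak the difference equals fs * phi exactly
  i740 <- which(abs(wl - 740) < 1e-9)
  expect_length(i740, 1)
  s <- simulateToaRadiance(wl, sun, sceneTruth(fsTrue = 0.8))$radiance
  expect_equal(s[i740] - base[i740], 0.8)
})

test_that("reflected term is linear in the solar zenith cosine", {
  wl <- spectralGrid()
  sun <- solarModel()
  s1 <- simulateToaRadiance(wl, sun, sceneTruth(mu0 = 1))$radiance
  s05 <- simulateToaRadiance(wl, sun, sceneTruth(mu0 = 0.5))$radiance
  expect_equal(s05, 0.5 * s1, tolerance = 1e-12)
})

test_that("noise realization is reproducible, scaled by L/SNR, and vanishes at high SNR", {
  l <- rep(100, 10000)
  expect_identical(addNoise(l, snrModel(300), seed = 7),
                   addNoise(l, snrModel(300), seed = 7))
  expect_false(identical(addNoise(l, snrModel(300), seed = 7),
                         addNoise(l, snrModel(300), seed = 8)))
  # SNR -> infinity: output equals input to float precision
  expect_equal(addNoise(l, snrModel(1e12), seed = 1), l, tolerance = 1e-9)
  # Monte-Carlo check of the noise scale: sd should be L/SNR = 1.0
  n <- addNoise(l, snrModel(100), seed = 42) - l
  expect_lt(abs(sd(n) - 1), 0.05)
  # noise must not disturb the caller's RNG state
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(addNoise(l[1:10], snrModel(10), seed = 3))
  expect_identical(rnorm(3), before)
})

test_that("non-positive SNR is rejected", {
  expect_error(addNoise(rep(1, 5), snrModel(1)@coef * -1, seed = 1))
  expect_error(snrModel(-5), "SNR")
})

test_that("training sets are reproducible and reject a single scene", {
  wl <- spectralGrid()
  sun <- solarModel()
  expect_error(makeTrainingSet(wl, sun, nScenes = 1, seed = 1), "nScenes")
  a <- makeTrainingSet(wl, sun, nScenes = 15, seed = 5)
  b <- makeTrainingSet(wl, sun, nScenes = 15, seed = 5)
  expect_identical(radianceValues(a), radianceValues(b))
  expect_true(all(colData(a)$fs_true == 0))
})

test_that("without lines the training matrix has polynomial rank", {
  wl <- spectralGrid()
  flat <- solarModel(continuumCoeffs = 100, lines = data.frame())
  # degree-2 reflectance times flat continuum: rank at most 3
  tr <- makeTrainingSet(wl, flat, nScenes = 60, seed = 3)
  d <- svd(t(radianceValues(tr)))$d
  expect_lt(d[4] / d[1], 1e-8)
})
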