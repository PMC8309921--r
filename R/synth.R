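# Synthetic-spectrum simulator: solar continuum with Fraunhofer-analogue
# lines, smooth effective reflectance, additive Gaussian fluorescence,
# optional unmodelled O2-like absorption, and SNR-scaled noise.

#' Evaluate the synthetic solar irradiance on a grid
#'
#' Continuum polynomial (in the grid-normalized coordinate) multiplied by the
#' product of Gaussian absorption lines,
#' `Isc = continuum * prod(1 - depth * exp(-(lambda - center)^2 / (2 width^2)))`.
#'
#' @param wavelengths strictly increasing wavelengths (nm).
#' @param model a [SolarModel-class].
#' @param lineShift optional calibration perturbation `c(offset, stretch)` in
#'   nm: line centers move by `offset + stretch * t(center)`, `t` being the
#'   grid-normalized coordinate.
#' @param widthScale optional multiplicative factor on line widths
#'   (instrument-line-shape drift).
#' @return numeric vector of irradiance values, strictly positive.
#' @examples
#' wl <- spectralGrid()
#' isc <- makeSolarIrradiance(wl, solarModel())
#' @export
makeSolarIrradiance <- function(wavelengths, model, lineShift = c(0, 0),
                                widthScale = 1) {
  .checkGrid(wavelengths)
  stopifnot(is(model, "SolarModel"))
  t <- .normCoord(wavelengths)
  cont <- .polyEval(model@continuumCoeffs, t)
  if (any(cont <= 0)) {
    stop("solar continuum is non-positive over part of the grid")
  }
  out <- cont
  ln <- model@lines
  if (nrow(ln) > 0) {
    tc <- .normCoord(ln$center, range = range(wavelengths))
    centers <- ln$center + lineShift[1] + lineShift[2] * tc
    widths <- ln$width * widthScale
    for (i in seq_len(nrow(ln))) {
      out <- out * (1 - ln$depth[i] *
                      exp(-(wavelengths - centers[i])^2 / (2 * widths[i]^2)))
    }
  }
  out
}

# Fixed O2-like absorption band near 769-771 nm: a cluster of strong Gaussian
# lines whose tail is negligible beyond 771 nm.  Returns the transmittance
# factor A(lambda) = prod(1 - depth * strength_l * G_l), A == 1 when depth = 0.
.o2Transmittance <- function(wavelengths, depth) {
  if (depth == 0) return(rep(1, length(wavelengths)))
  centers  <- c(769.14, 769.51, 769.86, 770.18, 770.47, 770.74)
  strength <- c(0.55, 0.80, 1.00, 0.90, 0.70, 0.50)
  width <- 0.09
  a <- rep(1, length(wavelengths))
  for (i in seq_along(centers)) {
    a <- a * (1 - depth * strength[i] *
                exp(-(wavelengths - centers[i])^2 / (2 * width^2)))
  }
  a
}

#' Simulate noiseless top-of-atmosphere radiance for one scene
#'
#' Lambertian scene radiance: reflected sunlight plus additive fluorescence,
#' `L = rho(lambda)/pi * Isc(lambda) * mu0 * A(lambda) +
#' Fs * hF(lambda) * A(lambda)`, where `A` is an optional unmodelled
#' absorption factor (`A == 1` when `o2Depth = 0`, the Fraunhofer-only
#' assumption) and `hF` is the Gaussian emission shape.
#'
#' @param wavelengths strictly increasing wavelengths (nm).
#' @param solar a [SolarModel-class].
#' @param truth a [SceneTruth-class].
#' @return list with elements `radiance` (numeric vector, noiseless) and
#'   `truth` (the SceneTruth actually used).
#' @examples
#' wl <- spectralGrid()
#' sc <- simulateToaRadiance(wl, solarModel(), sceneTruth(fsTrue = 0.8))
#' @export
simulateToaRadiance <- function(wavelengths, solar, truth) {
  .checkGrid(wavelengths)
  stopifnot(is(solar, "SolarModel"), is(truth, "SceneTruth"))
  isc <- makeSolarIrradiance(wavelengths, solar, lineShift = truth@lineShift,
                             widthScale = truth@widthScale)
  t <- .normCoord(wavelengths)
  rho <- .polyEval(truth@reflectanceCoeffs, t)
  if (any(rho < 0) || any(rho > 1)) {
    stop("reflectance polynomial leaves (0, 1] over the grid")
  }
  a <- .o2Transmittance(wavelengths, truth@o2Depth)
  hf <- gaussianHf(wavelengths, truth@sigmaF, truth@phi, truth@center)
  radiance <- rho / pi * isc * truth@mu0 * a + truth@fsTrue * hf * a
  if (any(radiance < 0)) {
    stop("simulated radiance is negative: inconsistent scene configuration")
  }
  list(radiance = radiance, truth = truth)
}

#' Add SNR-scaled Gaussian noise to a spectrum
#'
#' Adds zero-mean Gaussian noise with per-channel standard deviation
#' `un(lambda) = L(lambda) / SNR(lambda)`.  The realization is a pure function
#' of (spectrum, snr, seed): a fixed seed reproduces it bitwise and the global
#' RNG state is untouched.
#'
#' @param radiance numeric spectrum.
#' @param snr an [SnrModel-class] or positive numeric SNR vector.
#' @param seed integer seed.
#' @return noisy spectrum of the same length.
#' @examples
#' addNoise(rep(100, 5), snrModel(300), seed = 1)
#' @export
addNoise <- function(radiance, snr, seed) {
  sn <- .evalSnr(snr, radiance)
  .withSeed(seed, radiance + stats::rnorm(length(radiance), sd = abs(radiance) / sn))
}

#' Sampler of smooth effective-reflectance polynomials
#'
#' Returns a function drawing `n` coefficient rows for reflectance polynomials
#' on the grid-normalized coordinate: intercept uniform in `baseRange`, higher
#' orders zero-mean Gaussian with standard deviations `orderSd`.  Draws whose
#' reflectance leaves (0.02, 0.95) anywhere on \[-1, 1\] are resampled, keeping
#' every scene physically plausible.
#'
#' @param baseRange range of the constant term (mean reflectance).
#' @param orderSd standard deviations of the order-1..d coefficients; its
#'   length sets the polynomial degree (default degree 2).
#' @return function(n) returning an n x (degree + 1) coefficient matrix; uses
#'   the R RNG of the calling scope.
#' @export
reflectanceSampler <- function(baseRange = c(0.15, 0.55),
                               orderSd = c(0.08, 0.03)) {
  force(baseRange); force(orderSd)
  tchk <- seq(-1, 1, by = 0.02)
  function(n) {
    d <- length(orderSd)
    out <- matrix(NA_real_, n, d + 1L)
    for (i in seq_len(n)) {
      repeat {
        cf <- c(stats::runif(1, baseRange[1], baseRange[2]),
                stats::rnorm(d, sd = orderSd))
        r <- .polyEval(cf, tchk)
        if (all(r > 0.02 & r < 0.95)) break
      }
      out[i, ] <- cf
    }
    out
  }
}

# Shared scene generator: draws per-scene reflectance, geometry and
# calibration perturbations, simulates radiance, optionally adds noise.  Runs
# inside one seeded RNG scope so the whole batch is reproducible from a
# single integer.
.simulateBatch <- function(nScenes, wavelengths, solar, fsTrue, seed,
                           snr, noise, o2Depth, sigmaF, phi, center,
                           sampler, mu0Range, shiftSd, stretchSd,
                           widthJitterSd) {
  fsTrue <- rep_len(fsTrue, nScenes)
  o2Depth <- rep_len(o2Depth, nScenes)
  .withSeed(seed, {
    coefs <- sampler(nScenes)
    if (nScenes > 1L && all(apply(coefs, 2L, function(x) diff(range(x)) == 0))) {
      warning("degenerate reflectance sampler: all training scenes identical")
    }
    mu0 <- stats::runif(nScenes, mu0Range[1], mu0Range[2])
    shift0 <- stats::rnorm(nScenes, 0, shiftSd)
    shift1 <- stats::rnorm(nScenes, 0, stretchSd)
    wscale <- pmax(stats::rnorm(nScenes, 1, widthJitterSd), 0.5)
    rad <- matrix(NA_real_, length(wavelengths), nScenes)
    for (i in seq_len(nScenes)) {
      tr <- sceneTruth(reflectanceCoeffs = coefs[i, ], mu0 = mu0[i],
                       fsTrue = fsTrue[i], sigmaF = sigmaF, phi = phi,
                       center = center, o2Depth = o2Depth[i],
                       lineShift = c(shift0[i], shift1[i]),
                       widthScale = wscale[i],
                       snr = if (is.null(snr)) snrModel(300) else snr)
      rad[, i] <- simulateToaRadiance(wavelengths, solar, tr)$radiance
      if (noise && !is.null(snr)) {
        sn <- .evalSnr(snr, rad[, i])
        rad[, i] <- rad[, i] + stats::rnorm(length(wavelengths),
                                            sd = rad[, i] / sn)
      }
    }
    snrAssay <- if (!is.null(snr)) {
      apply(rad, 2L, function(L) .evalSnr(snr, L))
    } else NULL
    SpectraSet(rad, wavelengths, snr = snrAssay,
               colData = data.frame(fs_true = fsTrue, mu0 = mu0,
                                    o2_depth = o2Depth))
  })
}

#' Generate a non-fluorescent training set
#'
#' Simulates `nScenes` soundings with zero fluorescence, reflectance drawn
#' from the sampler, per-scene solar geometry, and per-scene spectral
#' calibration and line-width perturbations (the footprint-to-footprint
#' variability that gives a real soil/water training archive its
#' high-frequency spectral patterns).  Noiseless by default; pass an SNR
#' model to add measurement noise.
#'
#' @param wavelengths strictly increasing wavelengths (nm).
#' @param solar a [SolarModel-class].
#' @param nScenes number of training scenes, >= 2.
#' @param reflectanceSampler function(n) -> coefficient matrix; default
#'   [reflectanceSampler()].
#' @param seed integer seed.
#' @param snr optional [SnrModel-class]; NULL (default) keeps spectra
#'   noiseless.
#' @param mu0Range range of the per-scene cosine of solar zenith angle.
#' @param shiftSd standard deviation (nm) of the per-scene wavelength
#'   registration offset of the line pattern.
#' @param stretchSd standard deviation (nm at the band edges) of the
#'   per-scene dispersion stretch.
#' @param widthJitterSd standard deviation of the per-scene line-width factor
#'   around 1.
#' @return a [SpectraSet-class] with `fs_true = 0` for every sounding.
#' @examples
#' wl <- spectralGrid()
#' tr <- makeTrainingSet(wl, solarModel(), nScenes = 20, seed = 1)
#' @export
makeTrainingSet <- function(wavelengths, solar, nScenes,
                            reflectanceSampler = NULL, seed = 1,
                            snr = NULL, mu0Range = c(0.5, 0.9),
                            shiftSd = 0.001, stretchSd = 0.00075,
                            widthJitterSd = 0.005) {
  if (nScenes < 2L) {
    stop("nScenes must be >= 2: a single spectrum cannot separate shape from variation")
  }
  sampler <- if (is.null(reflectanceSampler)) {
    sifsvd::reflectanceSampler()
  } else reflectanceSampler
  .simulateBatch(nScenes, wavelengths, solar, fsTrue = 0, seed = seed,
                 snr = snr, noise = !is.null(snr), o2Depth = 0,
                 sigmaF = 30, phi = 1, center = 740, sampler = sampler,
                 mu0Range = mu0Range, shiftSd = shiftSd,
                 stretchSd = stretchSd, widthJitterSd = widthJitterSd)
}

#' Simulate a batch of fluorescent scenes
#'
#' Same scene statistics as [makeTrainingSet()] but with per-sounding
#' fluorescence amplitudes and, by default, SNR-scaled noise; the per-sounding
#' truth is stored in `colData` for parameter-recovery experiments.
#'
#' @param nScenes number of soundings.
#' @param wavelengths strictly increasing wavelengths (nm).
#' @param solar a [SolarModel-class].
#' @param fsTrue fluorescence amplitude(s), recycled to `nScenes`.
#' @param seed integer seed.
#' @param snr an [SnrModel-class] (default constant 300); NULL disables noise.
#' @param noise logical; FALSE returns noiseless radiance.
#' @param o2Depth unmodelled O2-like absorption depth(s) in \[0, 1).
#' @param sigmaF,phi,center true Gaussian emission parameters.
#' @param reflectanceSampler function(n) -> coefficient matrix.
#' @param mu0Range,shiftSd,stretchSd,widthJitterSd scene variability
#'   controls, as in [makeTrainingSet()].
#' @return a [SpectraSet-class] with truth columns `fs_true`, `mu0`,
#'   `o2_depth`.
#' @examples
#' wl <- spectralGrid()
#' sc <- simulateScenes(5, wl, solarModel(), fsTrue = 0.8, seed = 7)
#' @export
simulateScenes <- function(nScenes, wavelengths, solar, fsTrue = 0, seed = 1,
                           snr = snrModel(300), noise = TRUE, o2Depth = 0,
                           sigmaF = 30, phi = 1, center = 740,
                           reflectanceSampler = NULL,
                           mu0Range = c(0.5, 0.9), shiftSd = 0.001,
                           stretchSd = 0.00075, widthJitterSd = 0.005) {
  sampler <- if (is.null(reflectanceSampler)) {
    sifsvd::reflectanceSampler()
  } else reflectanceSampler
  .simulateBatch(nScenes, wavelengths, solar, fsTrue = fsTrue, seed = seed,
                 snr = snr, noise = noise && !is.null(snr), o2Depth = o2Depth,
                 sigmaF = sigmaF, phi = phi, center = center,
                 sampler = sampler, mu0Range = mu0Range, shiftSd = shiftSd,
                 stretchSd = stretchSd, widthJitterSd = widthJitterSd)
}
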