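#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# ---------------------------------------------------------------------------
# SnrModel -------------------------------------------------------------------

#' Signal-to-noise model
#'
#' Per-channel SNR as a function of radiance: either constant
#' (`SNR(L) = snr`) or affine (`SNR(L) = a + b * L`).  Radiance uncertainty is
#' `un(lambda) = L(lambda) / SNR(lambda)` and fit weights are its reciprocal.
#'
#' @slot type `"constant"` or `"affine"`.
#' @slot coef numeric; `snr` for constant, `c(a, b)` for affine.
#' @name SnrModel-class
#' @export
setClass("SnrModel", representation(type = "character", coef = "numeric"))

setValidity("SnrModel", function(object) {
  if (!object@type %in% c("constant", "affine")) {
    return("type must be 'constant' or 'affine'")
  }
  n <- if (object@type == "constant") 1L else 2L
  if (length(object@coef) != n) {
    return(sprintf("coef must have length %d for type '%s'", n, object@type))
  }
  if (object@type == "constant" && object@coef[1] <= 0) {
    return("constant SNR must be > 0")
  }
  TRUE
})

#' Construct an SNR model
#'
#' @param snr constant SNR value (used when `a`, `b` are missing).
#' @param a,b affine coefficients, `SNR(L) = a + b * L`.
#' @return an [SnrModel-class] object.
#' @examples
#' snrModel(300)
#' snrModel(a = 100, b = 2)
#' @export
snrModel <- function(snr = 300, a = NULL, b = NULL) {
  if (is.null(a) && is.null(b)) {
    new("SnrModel", type = "constant", coef = as.numeric(snr))
  } else {
    if (is.null(a) || is.null(b)) stop("affine model needs both 'a' and 'b'")
    new("SnrModel", type = "affine", coef = c(as.numeric(a), as.numeric(b)))
  }
}

# Evaluate an SNR model (or accept a raw positive numeric vector of SNRs).
.evalSnr <- function(snr, radiance) {
  if (is(snr, "SnrModel")) {
    out <- switch(snr@type,
                  constant = rep(snr@coef[1], length(radiance)),
                  affine = snr@coef[1] + snr@coef[2] * radiance)
  } else if (is.numeric(snr)) {
    out <- rep_len(as.numeric(snr), length(radiance))
  } else {
    stop("'snr' must be an SnrModel or a numeric vector")
  }
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop("SNR must be positive and finite on every channel")
  }
  out
}

setMethod("show", "SnrModel", function(object) {
  if (object@type == "constant") {
    cat(sprintf("SnrModel: constant SNR = %g\n", object@coef[1]))
  } else {
    cat(sprintf("SnrModel: affine SNR(L) = %g + %g * L\n",
                object@coef[1], object@coef[2]))
  }
})

# ---------------------------------------------------------------------------
# SolarModel -----------------------------------------------------------------

#' Synthetic solar irradiance model
#'
#' A smooth continuum (polynomial in the grid-normalized wavelength
#' coordinate) multiplied by narrow Gaussian absorption lines standing in for
#' solar Fraunhofer lines.  Line depths are fixed — solar line depths are
#' stable, which is what makes fluorescence in-filling detectable — while the
#' simulator may vary the wavelength registration and line width per scene
#' (spectral calibration and instrument-line-shape drift).
#'
#' @slot continuumCoeffs polynomial coefficients (radiance units,
#'   mW m-2 sr-1 nm-1 scale) in the normalized coordinate of the evaluation
#'   grid.
#' @slot lines data.frame with columns `center` (nm), `depth` (fraction in
#'   \[0, 1)), `width` (nm, Gaussian sigma; the instrument line shape is
#'   folded into this width).
#' @name SolarModel-class
#' @export
setClass("SolarModel",
         representation(continuumCoeffs = "numeric", lines = "data.frame"))

setValidity("SolarModel", function(object) {
  ln <- object@lines
  need <- c("center", "depth", "width")
  if (nrow(ln) > 0 && !all(need %in% names(ln))) {
    return(sprintf("lines must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(ln) > 0) {
    if (any(ln$depth < 0 | ln$depth >= 1)) return("line depths must be in [0, 1)")
    if (any(ln$width <= 0)) return("line widths must be > 0")
  }
  if (length(object@continuumCoeffs) < 1L) return("continuumCoeffs is empty")
  TRUE
})

#' Fraunhofer-analogue absorption lines
#'
#' Fixed synthetic line list spanning 758--778 nm with several lines inside
#' the default 771--778 nm retrieval window; depths 0.25--0.6, Gaussian
#' widths 0.05--0.08 nm (the instrument line shape is folded into the width).
#'
#' @return data.frame with columns center, depth, width.
#' @export
defaultFraunhoferLines <- function() {
  data.frame(
    center = c(759.37, 761.05, 763.82, 766.49, 768.21, 769.90,
               771.45, 772.09, 772.88, 773.69, 774.42, 775.31,
               776.12, 776.98, 777.62),
    depth  = c(0.40, 0.55, 0.30, 0.60, 0.25, 0.50,
               0.30, 0.55, 0.40, 0.25, 0.60, 0.35,
               0.45, 0.30, 0.50),
    width  = c(0.06, 0.05, 0.08, 0.07, 0.06, 0.06,
               0.05, 0.06, 0.05, 0.07, 0.05, 0.06,
               0.05, 0.07, 0.06)
  )
}

#' Construct a solar irradiance model
#'
#' @param continuumCoeffs polynomial coefficients of the continuum on the
#'   grid-normalized coordinate in \[-1, 1\]; default `c(1200, -60)` gives a
#'   gently sloping ~1200 mW m-2 nm-1 continuum, the magnitude of solar
#'   irradiance near 760 nm.
#' @param lines absorption-line table, see [defaultFraunhoferLines()].
#' @return a [SolarModel-class] object.
#' @examples
#' sun <- solarModel()
#' @export
solarModel <- function(continuumCoeffs = c(1200, -60),
                       lines = defaultFraunhoferLines()) {
  new("SolarModel", continuumCoeffs = as.numeric(continuumCoeffs),
      lines = as.data.frame(lines))
}

setMethod("show", "SolarModel", function(object) {
  cat(sprintf("SolarModel: continuum degree %d, %d absorption lines\n",
              length(object@continuumCoeffs) - 1L, nrow(object@lines)))
})

# ---------------------------------------------------------------------------
# SceneTruth -----------------------------------------------------------------

#' Ground truth of one simulated sounding
#'
#' Holds every parameter the simulator used for one scene, for
#' parameter-recovery experiments: smooth effective surface reflectance
#' (polynomial in the grid-normalized coordinate; atmospheric path reflectance
#' and spherical-albedo coupling are deliberately absorbed into this single
#' smooth term, since in a Fraunhofer-only window they are spectrally smooth
#' and not separately identifiable), solar geometry, fluorescence amplitude
#' and shape, optional unmodelled O2-like absorption, line-depth factors and
#' the noise model.
#'
#' @slot reflectanceCoeffs polynomial coefficients of effective reflectance,
#'   values in (0, 1\] over the grid.
#' @slot mu0 cosine of the solar zenith angle, in (0, 1].
#' @slot fsTrue fluorescence amplitude Fs at the emission peak (radiance
#'   units), >= 0.
#' @slot sigmaF Gaussian emission width sigma in nm.
#' @slot phi emission peak height (unitless shape scale).
#' @slot center emission peak wavelength in nm (default 740).
#' @slot o2Depth depth in \[0, 1) of an optional O2-like absorption band near
#'   769--771 nm standing in for ground-to-sensor transmittance; 0 means the
#'   Fraunhofer-only assumption T = 1 holds exactly.
#' @slot lineShift spectral-calibration perturbation of the line pattern,
#'   `c(offset, stretch)` in nm: lines shift by
#'   `offset + stretch * t(center)` with `t` the grid-normalized coordinate.
#' @slot widthScale multiplicative factor on line widths (instrument
#'   line-shape width drift), > 0.
#' @slot snr an [SnrModel-class].
#' @slot seed integer seed used for the noise realization (NA if none).
#' @name SceneTruth-class
#' @export
setClass("SceneTruth",
         representation(reflectanceCoeffs = "numeric", mu0 = "numeric",
                        fsTrue = "numeric", sigmaF = "numeric",
                        phi = "numeric", center = "numeric",
                        o2Depth = "numeric", lineShift = "numeric",
                        widthScale = "numeric",
                        snr = "SnrModel", seed = "integer"))

setValidity("SceneTruth", function(object) {
  if (object@fsTrue < 0) return("fsTrue must be >= 0")
  if (object@mu0 <= 0 || object@mu0 > 1) return("mu0 must be in (0, 1]")
  if (object@sigmaF <= 0) return("sigmaF must be > 0")
  if (object@phi <= 0) return("phi must be > 0")
  if (object@o2Depth < 0 || object@o2Depth >= 1) {
    return("o2Depth must be in [0, 1)")
  }
  if (length(object@lineShift) != 2L) {
    return("lineShift must be c(offset, stretch) in nm")
  }
  if (object@widthScale <= 0) return("widthScale must be > 0")
  TRUE
})

#' Construct a scene truth
#'
#' @param reflectanceCoeffs polynomial coefficients of the smooth effective
#'   reflectance on the grid-normalized coordinate.
#' @param mu0 cosine of solar zenith angle, (0, 1].
#' @param fsTrue fluorescence amplitude at the emission peak (radiance units).
#' @param sigmaF Gaussian emission width (nm).
#' @param phi emission peak height.
#' @param center emission peak wavelength (nm).
#' @param o2Depth optional unmodelled absorption depth in \[0, 1).
#' @param lineShift calibration perturbation `c(offset, stretch)` in nm.
#' @param widthScale line-width factor, > 0.
#' @param snr an [SnrModel-class] or a single SNR value.
#' @param seed integer noise seed (NA for noiseless).
#' @return a [SceneTruth-class] object.
#' @examples
#' tr <- sceneTruth(fsTrue = 0.8)
#' @export
sceneTruth <- function(reflectanceCoeffs = c(0.35, 0.08, -0.03), mu0 = 0.7,
                       fsTrue = 0, sigmaF = 30, phi = 1, center = 740,
                       o2Depth = 0, lineShift = c(0, 0), widthScale = 1,
                       snr = snrModel(300), seed = NA_integer_) {
  if (is.numeric(snr)) snr <- snrModel(snr)
  new("SceneTruth", reflectanceCoeffs = as.numeric(reflectanceCoeffs),
      mu0 = as.numeric(mu0), fsTrue = as.numeric(fsTrue),
      sigmaF = as.numeric(sigmaF), phi = as.numeric(phi),
      center = as.numeric(center), o2Depth = as.numeric(o2Depth),
      lineShift = as.numeric(lineShift), widthScale = as.numeric(widthScale),
      snr = snr, seed = as.integer(seed))
}

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(paste0("SceneTruth: Fs = %g, mu0 = %g, sigmaF = %g nm, ",
                     "o2Depth = %g, reflectance degree %d\n"),
              object@fsTrue, object@mu0, object@sigmaF, object@o2Depth,
              length(object@reflectanceCoeffs) - 1L))
})

# ---------------------------------------------------------------------------
# SpectraSet -----------------------------------------------------------------

#' Container for a batch of soundings
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with channels as rows (wavelength in `rowData`) and soundings as columns;
#' assay `"radiance"` is mandatory, assay `"snr"` optional, and simulated sets
#' carry per-sounding truth (`fs_true`, `mu0`, `o2_depth`) in `colData`.
#'
#' @name SpectraSet-class
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  if (!"radiance" %in% assayNames(object)) {
    return("assay 'radiance' is required")
  }
  wl <- rowData(object)$wavelength
  if (is.null(wl) && nrow(object) > 0) {
    return("rowData column 'wavelength' is required")
  }
  if (nrow(object) > 0) {
    ok <- tryCatch({ .checkGrid(wl); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
  }
  TRUE
})

#' Construct a SpectraSet
#'
#' @param radiance numeric matrix, channels x soundings (a vector is treated
#'   as a single sounding).
#' @param wavelengths channel-center wavelengths (nm), strictly increasing.
#' @param snr optional per-channel SNR matrix/vector of the same shape.
#' @param colData optional per-sounding metadata (data.frame or DataFrame).
#' @return a [SpectraSet-class].
#' @examples
#' wl <- spectralGrid(770, 772, 0.1)
#' ss <- SpectraSet(matrix(100, length(wl), 3), wl)
#' @export
SpectraSet <- function(radiance, wavelengths, snr = NULL, colData = NULL) {
  if (is.null(dim(radiance))) radiance <- matrix(radiance, ncol = 1L)
  radiance <- as.matrix(radiance)
  if (length(wavelengths) > 0) .checkGrid(wavelengths)
  if (nrow(radiance) != length(wavelengths)) {
    stop("nrow(radiance) must equal length(wavelengths)")
  }
  if (is.null(colnames(radiance))) {
    colnames(radiance) <- sprintf("s%04d", seq_len(ncol(radiance)))
  }
  assays <- list(radiance = radiance)
  if (!is.null(snr)) {
    if (is.null(dim(snr))) snr <- matrix(snr, nrow = nrow(radiance),
                                         ncol = ncol(radiance))
    dimnames(snr) <- dimnames(radiance)
    assays$snr <- snr
  }
  cd <- if (is.null(colData)) {
    DataFrame(row.names = colnames(radiance))
  } else {
    DataFrame(colData, row.names = colnames(radiance))
  }
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(wavelength = as.numeric(wavelengths)),
    colData = cd
  )
  new("SpectraSet", se)
}

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet",
          function(x) rowData(x)$wavelength)

#' @rdname radianceValues
#' @export
setMethod("radianceValues", "SpectraSet",
          function(x) assay(x, "radiance"))

#' @rdname snrValues
#' @export
setMethod("snrValues", "SpectraSet", function(x) {
  if ("snr" %in% assayNames(x)) assay(x, "snr") else NULL
})

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  if (length(wl) > 0) {
    cat(sprintf("SpectraSet: %d soundings x %d channels, %.3f-%.3f nm%s\n",
                ncol(object), nrow(object), min(wl), max(wl),
                if ("snr" %in% assayNames(object)) ", with SNR" else ""))
  } else {
    cat("SpectraSet: empty (no soundings)\n")
  }
  callNextMethod()
})

# ---------------------------------------------------------------------------
# SingularBasis --------------------------------------------------------------

#' Singular-vector basis of non-fluorescent spectra
#'
#' Right-singular vectors of a (scenes x channels) training matrix of
#' non-fluorescent radiance spectra, in descending singular-value order, with
#' the fraction of total training variance each vector explains.
#'
#' @slot wavelengths channel wavelengths (nm).
#' @slot vectors channels x m matrix of unit-norm, mutually orthonormal
#'   spectral patterns v_1..v_m.
#' @slot singularValues non-increasing, non-negative singular values of the
#'   retained vectors.
#' @slot explainedVariance p_j = s_j^2 / sum over all singular values s_k^2;
#'   sums to 1 when all vectors are retained.
#' @name SingularBasis-class
#' @export
setClass("SingularBasis",
         representation(wavelengths = "numeric", vectors = "matrix",
                        singularValues = "numeric",
                        explainedVariance = "numeric"))

setValidity("SingularBasis", function(object) {
  v <- object@vectors
  if (nrow(v) != length(object@wavelengths)) {
    return("vectors must have one row per wavelength")
  }
  m <- ncol(v)
  if (length(object@singularValues) != m ||
      length(object@explainedVariance) != m) {
    return("singularValues and explainedVariance must match ncol(vectors)")
  }
  if (any(object@singularValues < 0)) return("singular values must be >= 0")
  if (is.unsorted(rev(object@singularValues))) {
    return("singular values must be non-increasing")
  }
  g <- crossprod(v) - diag(m)
  if (max(abs(g)) > 1e-8) return("vectors are not orthonormal")
  p <- object@explainedVariance
  if (any(p < -1e-12) || any(p > 1 + 1e-12) || sum(p) > 1 + 1e-8) {
    return("explainedVariance fractions must lie in [0, 1] and sum to <= 1")
  }
  TRUE
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SingularBasis", function(x) x@wavelengths)

#' @rdname basisVectors
#' @export
setMethod("basisVectors", "SingularBasis", function(x) x@vectors)

#' @rdname singularValues
#' @export
setMethod("singularValues", "SingularBasis", function(x) x@singularValues)

#' @rdname explainedVariance
#' @export
setMethod("explainedVariance", "SingularBasis", function(x) x@explainedVariance)

setMethod("show", "SingularBasis", function(object) {
  p <- object@explainedVariance
  cat(sprintf("SingularBasis: %d vectors over %d channels (%.3f-%.3f nm)\n",
              ncol(object@vectors), nrow(object@vectors),
              min(object@wavelengths), max(object@wavelengths)))
  cat("  explained variance:",
      paste(sprintf("%.4g", utils::head(p, 6L)), collapse = " "),
      if (length(p) > 6L) "..." else "", "\n")
})

# ---------------------------------------------------------------------------
# RetrievalConfig ------------------------------------------------------------

#' Retrieval configuration
#'
#' @slot window numeric c(min, max) retrieval window in nm; channels are
#'   included half-open, `min <= lambda < max`.
#' @slot nP order of the wavelength polynomial modulating the first singular
#'   vector (default 1).
#' @slot nvCandidates candidate numbers of singular vectors (counted
#'   inclusive of v_1); the Bayesian Information Criterion picks one.
#' @slot sigma Gaussian emission width in nm (default 30).
#' @slot phi emission peak height (default 1).
#' @slot center emission peak wavelength in nm (default 740).
#' @slot lambdaRef wavelength at which SIF is reported (default 775 nm).
#' @slot weighting logical; weight the fit by SNR/L when SNR is available.
#' @slot rssForm `"quadratic"` for sum((w * r)^2) (default) or `"linear"` for
#'   sum(w * r^2).
#' @name RetrievalConfig-class
#' @export
setClass("RetrievalConfig",
         representation(window = "numeric", nP = "integer",
                        nvCandidates = "integer", sigma = "numeric",
                        phi = "numeric", center = "numeric",
                        lambdaRef = "numeric", weighting = "logical",
                        rssForm = "character"))

setValidity("RetrievalConfig", function(object) {
  if (length(object@window) != 2L || object@window[1] >= object@window[2]) {
    return("window must be c(min, max) with min < max")
  }
  if (object@nP < 0L) return("nP must be >= 0")
  if (length(object@nvCandidates) < 1L || any(object@nvCandidates < 1L)) {
    return("nvCandidates must be a non-empty set of integers >= 1")
  }
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@phi <= 0) return("phi must be > 0")
  if (!object@rssForm %in% c("quadratic", "linear")) {
    return("rssForm must be 'quadratic' or 'linear'")
  }
  TRUE
})

#' Construct a retrieval configuration
#'
#' Defaults follow the reference setup for a 7 nm Fraunhofer-only window:
#' first-order polynomial, candidate singular-vector counts 2..8, emission
#' width 30 nm with unit peak at 740 nm, SIF reported at 775 nm, SNR-weighted
#' fit.
#'
#' @param window retrieval window c(min, max) in nm.
#' @param nP polynomial order.
#' @param nvCandidates candidate numbers of singular vectors (inclusive of
#'   v_1).
#' @param sigma,phi,center Gaussian emission shape parameters.
#' @param lambdaRef reporting wavelength (nm).
#' @param weighting logical, SNR weighting on/off.
#' @param rssForm `"quadratic"` or `"linear"` residual weighting convention.
#' @return a [RetrievalConfig-class].
#' @examples
#' cfg <- retrievalConfig()
#' @export
retrievalConfig <- function(window = c(771, 778), nP = 1L, nvCandidates = 2:8,
                            sigma = 30, phi = 1, center = 740,
                            lambdaRef = 775, weighting = TRUE,
                            rssForm = "quadratic") {
  new("RetrievalConfig", window = as.numeric(window), nP = as.integer(nP),
      nvCandidates = sort(unique(as.integer(nvCandidates))),
      sigma = as.numeric(sigma), phi = as.numeric(phi),
      center = as.numeric(center), lambdaRef = as.numeric(lambdaRef),
      weighting = as.logical(weighting), rssForm = rssForm)
}

setMethod("show", "RetrievalConfig", function(object) {
  cat(sprintf(paste0("RetrievalConfig: window [%g, %g) nm, nP = %d, ",
                     "nv in {%s}, sigma = %g nm, phi = %g, ref %g nm, %s\n"),
              object@window[1], object@window[2], object@nP,
              paste(object@nvCandidates, collapse = ","), object@sigma,
              object@phi, object@lambdaRef,
              if (object@weighting) "SNR-weighted" else "unweighted"))
})

# ---------------------------------------------------------------------------
# DesignMatrix ---------------------------------------------------------------

#' Linear forward-model design matrix
#'
#' Columns, in order: v_1 times powers 0..nP of the normalized wavelength
#' coordinate, the free singular vectors v_2..v_nv, and the Gaussian emission
#' shape hF.  The fluorescence amplitude Fs is the coefficient of the last
#' column.
#'
#' @slot matrix numeric matrix, window channels x k columns,
#'   k = (nP + 1) + (nv - 1) + 1.
#' @slot wavelengths window channel wavelengths (nm).
#' @slot nP,nv model orders.
#' @name DesignMatrix-class
#' @export
setClass("DesignMatrix",
         representation(matrix = "matrix", wavelengths = "numeric",
                        nP = "integer", nv = "integer"))

setValidity("DesignMatrix", function(object) {
  k <- (object@nP + 1L) + (object@nv - 1L) + 1L
  if (ncol(object@matrix) != k) {
    return(sprintf("expected %d columns, found %d", k, ncol(object@matrix)))
  }
  if (nrow(object@matrix) != length(object@wavelengths)) {
    return("one row per window channel required")
  }
  TRUE
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "DesignMatrix", function(x) x@wavelengths)

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d channels x %d columns (nP = %d, nv = %d)\n",
              nrow(object@matrix), ncol(object@matrix), object@nP, object@nv))
})

# ---------------------------------------------------------------------------
# RetrievalResult ------------------------------------------------------------

#' Result of one SIF retrieval
#'
#' @slot fs fluorescence amplitude Fs, i.e. the fitted coefficient of the
#'   emission-shape column (radiance units at the emission peak when phi = 1).
#'   Negative estimates are reported as-is, never clipped.
#' @slot sifAtRef Fs times the emission shape at the reporting wavelength.
#' @slot coefficients full fitted coefficient vector (polynomial a_0..a_nP,
#'   singular-vector weights omega_2..omega_nv, Fs).
#' @slot nvSelected number of singular vectors chosen by BIC.
#' @slot bicByNv named numeric vector, BIC per evaluated candidate.
#' @slot rss weighted residual sum of squares of the selected model.
#' @slot residuals per-channel residual spectrum over the window.
#' @slot wavelengths window channel wavelengths (nm).
#' @slot fsUncertainty 1-sigma uncertainty of Fs from the weighted
#'   least-squares covariance with residual-based variance rescaling.
#' @slot valid logical flag; FALSE when the retrieval failed.
#' @slot message diagnostic message (empty when valid).
#' @name RetrievalResult-class
#' @export
setClass("RetrievalResult",
         representation(fs = "numeric", sifAtRef = "numeric",
                        coefficients = "numeric", nvSelected = "integer",
                        bicByNv = "numeric", rss = "numeric",
                        residuals = "numeric", wavelengths = "numeric",
                        fsUncertainty = "numeric", valid = "logical",
                        message = "character"))

setMethod("show", "RetrievalResult", function(object) {
  if (!object@valid) {
    cat("RetrievalResult: INVALID —", object@message, "\n")
    return(invisible(NULL))
  }
  cat(sprintf(paste0("RetrievalResult: Fs = %.4g +/- %.3g, SIF(ref) = %.4g, ",
                     "nv = %d, RSS = %.4g\n"),
              object@fs, object@fsUncertainty, object@sifAtRef,
              object@nvSelected, object@rss))
})
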