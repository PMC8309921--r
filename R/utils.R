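# Internal helpers shared across modules.

#' Evaluate expression with a local, reproducible RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `expr`, and restores the previous state on exit, so that every stochastic
#' operation in the package is a pure function of its explicit seed and never
#' perturbs global RNG state.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
.withSeed <- function(seed, expr) {
  if (length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Validate a wavelength axis: numeric, finite, strictly increasing.
.checkGrid <- function(wavelengths, what = "wavelengths") {
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L) {
    stop(sprintf("'%s' must be a numeric vector of length >= 2", what),
         call. = FALSE)
  }
  if (any(!is.finite(wavelengths))) {
    stop(sprintf("'%s' contains non-finite values", what), call. = FALSE)
  }
  d <- diff(wavelengths)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop(sprintf("'%s' must be strictly increasing (violated at element %d)",
                 what, bad), call. = FALSE)
  }
  invisible(wavelengths)
}

#' Default spectral grid
#'
#' Wavelength axis of the far-red band used throughout: 758--778 nm sampled
#' at 0.044 nm (455 channels), matching an ultra-high-resolution grating
#' spectrometer in the O2-A band region.
#'
#' @param lambdaMin,lambdaMax window bounds in nm.
#' @param step sampling step in nm (default 0.044).
#' @return numeric vector of channel-center wavelengths (nm).
#' @examples
#' wl <- spectralGrid()
#' length(wl)
#' @export
spectralGrid <- function(lambdaMin = 758, lambdaMax = 778, step = 0.044) {
  if (!(lambdaMin < lambdaMax)) stop("lambdaMin must be < lambdaMax")
  if (step <= 0) stop("step must be > 0")
  wl <- seq(lambdaMin, lambdaMax, by = step)
  .checkGrid(wl)
}

# Map wavelengths to a normalized coordinate.  Over a full grid we use
# t = (lambda - mid)/halfspan in [-1, 1]; the design-matrix polynomial uses
# (lambda - mid)/(max - min) in [-0.5, 0.5] (see buildDesignMatrix).
.normCoord <- function(wavelengths, range = base::range(wavelengths),
                       half = TRUE) {
  mid <- mean(range)
  span <- diff(range)
  if (span <= 0) stop("degenerate wavelength range")
  if (half) (wavelengths - mid) / (span / 2) else (wavelengths - mid) / span
}

# Horner evaluation of a polynomial with coefficients c0, c1, ... in x.
.polyEval <- function(coeffs, x) {
  out <- rep(coeffs[length(coeffs)], length(x))
  if (length(coeffs) > 1L) {
    for (i in rev(seq_len(length(coeffs) - 1L))) out <- out * x + coeffs[i]
  }
  out
}

# Channel indices falling in a half-open window [min, max) on channel centers.
.windowChannels <- function(wavelengths, window) {
  if (length(window) != 2L || !is.numeric(window) || window[1] >= window[2]) {
    stop("'window' must be numeric c(min, max) with min < max", call. = FALSE)
  }
  which(wavelengths >= window[1] & wavelengths < window[2])
}
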