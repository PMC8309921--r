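# Linear forward model: v_1 modulated by a wavelength polynomial, the
# remaining singular vectors, and a Gaussian fluorescence emission term.

#' Gaussian fluorescence emission shape
#'
#' `hF(lambda) = phi * exp(-(lambda - center)^2 / (2 sigma^2))`: the
#' normalized far-red chlorophyll fluorescence emission spectrum, peaking at
#' 740 nm by default with unit height.
#'
#' @param wavelengths wavelengths (nm), any numeric vector.
#' @param sigma Gaussian width (nm), > 0.
#' @param phi peak height.
#' @param center peak wavelength (nm).
#' @return numeric vector, the emission shape.
#' @examples
#' gaussianHf(740, sigma = 30)          # 1 at the peak
#' gaussianHf(770, sigma = 30)          # exp(-0.5)
#' @export
gaussianHf <- function(wavelengths, sigma, phi = 1, center = 740) {
  if (sigma <= 0) stop("sigma must be > 0")
  phi * exp(-(wavelengths - center)^2 / (2 * sigma^2))
}

#' Build the forward-model design matrix
#'
#' Restricts the basis to the retrieval window (half-open on channel centers)
#' and assembles the column blocks `[v1 * lhat^0 .. v1 * lhat^nP | v2 .. v_nv
#' | hF]`.  The polynomial is evaluated on the affine-normalized coordinate
#' `lhat = (lambda - mid(window)) / (max - min)` rather than raw nm: raw
#' wavelengths near 775 make the order-0 and order-1 columns nearly collinear,
#' and the affine reparametrization changes the polynomial coefficients but
#' not the fitted fluorescence amplitude.  `nv` counts singular vectors
#' inclusive of v_1, so nv = 1 yields no free singular-vector block.
#'
#' @param basis a [SingularBasis-class].
#' @param config a [RetrievalConfig-class].
#' @param nv number of singular vectors (inclusive of v_1),
#'   <= number of basis vectors.
#' @return a [DesignMatrix-class] with k = (nP + 1) + (nv - 1) + 1 columns.
#' @export
buildDesignMatrix <- function(basis, config, nv) {
  stopifnot(is(basis, "SingularBasis"), is(config, "RetrievalConfig"))
  nv <- as.integer(nv)
  if (nv < 1L) stop("nv must be >= 1")
  if (nv > ncol(basis@vectors)) {
    stop(sprintf("nv = %d exceeds the basis size (%d vectors)", nv,
                 ncol(basis@vectors)))
  }
  idx <- .windowChannels(basis@wavelengths, config@window)
  if (length(idx) == 0L) {
    stop(sprintf("window [%g, %g) contains no channels", config@window[1],
                 config@window[2]))
  }
  wl <- basis@wavelengths[idx]
  lhat <- (wl - mean(config@window)) / diff(config@window)
  v1 <- basis@vectors[idx, 1L]
  poly <- vapply(0:config@nP, function(i) v1 * lhat^i, numeric(length(idx)))
  cols <- list(poly)
  labels <- sprintf("v1.l%d", 0:config@nP)
  if (nv >= 2L) {
    cols <- c(cols, list(basis@vectors[idx, 2:nv, drop = FALSE]))
    labels <- c(labels, sprintf("sv%d", 2:nv))
  }
  hf <- gaussianHf(wl, config@sigma, config@phi, config@center)
  x <- cbind(do.call(cbind, cols), hf)
  colnames(x) <- c(labels, "Fs")
  new("DesignMatrix", matrix = x, wavelengths = wl, nP = config@nP, nv = nv)
}

#' Forward-evaluate the linear model
#'
#' @param dm a [DesignMatrix-class].
#' @param coefficients numeric vector of length k, ordered as the design
#'   columns (polynomial, singular-vector weights, Fs).
#' @return predicted radiance spectrum over the window channels.
#' @export
predictRadiance <- function(dm, coefficients) {
  stopifnot(is(dm, "DesignMatrix"))
  if (length(coefficients) != ncol(dm@matrix)) {
    stop(sprintf("expected %d coefficients, got %d", ncol(dm@matrix),
                 length(coefficients)))
  }
  drop(dm@matrix %*% coefficients)
}

#' Condition number of a design matrix
#'
#' 2-norm condition number of the column-scaled design; finite values confirm
#' the normalized wavelength coordinate avoids the near-collinearity of raw-nm
#' polynomial columns.
#'
#' @param dm a [DesignMatrix-class].
#' @return single numeric condition number.
#' @export
designCondition <- function(dm) {
  stopifnot(is(dm, "DesignMatrix"))
  d <- svd(dm@matrix, nu = 0, nv = 0)$d
  d[1] / d[length(d)]
}
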