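# Singular-vector basis from a matrix of non-fluorescent training spectra.

#' Compute singular vectors of a training set
#'
#' Singular value decomposition of the (scenes x channels) training matrix in
#' raw radiance units, without mean-centering: the first right-singular vector
#' itself carries the dominant spectrum shape and acts as the multiplicative
#' carrier in the forward model, so centering would destroy its role.  Sign
#' convention: each vector is flipped so its inner product with the mean
#' training spectrum is >= 0 (ties: largest-magnitude element positive), which
#' makes bases reproducible across linear-algebra backends.
#'
#' @param training a [SpectraSet-class] or a numeric matrix with scenes as
#'   rows and channels as columns.
#' @param nKeep number of singular vectors to retain,
#'   <= min(nScenes, nChannels).
#' @param wavelengths channel wavelengths; required when `training` is a bare
#'   matrix.
#' @return a [SingularBasis-class]; `explainedVariance` is computed against
#'   the total variance over all singular values, so it sums to 1 when all
#'   vectors are kept.
#' @examples
#' wl <- spectralGrid()
#' tr <- makeTrainingSet(wl, solarModel(), nScenes = 30, seed = 1)
#' basis <- computeSVs(tr, nKeep = 8)
#' @export
computeSVs <- function(training, nKeep, wavelengths = NULL) {
  if (is(training, "SpectraSet")) {
    wavelengths <- wavelengths(training)
    x <- t(radianceValues(training))
  } else {
    x <- as.matrix(training)
    if (is.null(wavelengths)) {
      stop("'wavelengths' is required when 'training' is a matrix")
    }
    if (ncol(x) != length(wavelengths)) {
      stop("training matrix must have one column per wavelength")
    }
  }
  .checkGrid(wavelengths)
  if (nrow(x) < 2L) stop("training set must contain at least 2 scenes")
  if (ncol(x) < 2L) stop("training set must contain at least 2 channels")
  if (all(x == 0)) stop("training matrix is all zero")
  nKeep <- as.integer(nKeep)
  if (nKeep < 1L || nKeep > min(dim(x))) {
    stop(sprintf("nKeep must be in [1, %d]", min(dim(x))))
  }
  sv <- svd(x, nu = 0, nv = min(dim(x)))
  p <- sv$d^2 / sum(sv$d^2)
  v <- sv$v[, seq_len(nKeep), drop = FALSE]
  # sign convention
  mn <- colMeans(x)
  for (j in seq_len(nKeep)) {
    ip <- sum(v[, j] * mn)
    if (ip < 0) {
      v[, j] <- -v[, j]
    } else if (ip == 0) {
      if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
    }
  }
  colnames(v) <- sprintf("sv%d", seq_len(nKeep))
  new("SingularBasis", wavelengths = as.numeric(wavelengths), vectors = v,
      singularValues = sv$d[seq_len(nKeep)],
      explainedVariance = p[seq_len(nKeep)])
}

#' Project a spectrum onto a singular basis
#'
#' Coefficients `omega_j = <v_j, spectrum>`; the reconstruction
#' `sum(omega_j v_j)` is the L2-optimal approximation within the span of the
#' kept vectors.
#'
#' @param basis a [SingularBasis-class].
#' @param spectrum numeric vector on the basis grid.
#' @param wavelengths optional wavelengths of `spectrum`, checked against the
#'   basis grid.
#' @return named numeric vector of coefficients.
#' @export
projectSpectrum <- function(basis, spectrum, wavelengths = NULL) {
  stopifnot(is(basis, "SingularBasis"))
  if (!is.null(wavelengths) &&
      !isTRUE(all.equal(wavelengths, basis@wavelengths, tolerance = 1e-9))) {
    stop("spectrum wavelengths do not match the basis grid")
  }
  if (length(spectrum) != nrow(basis@vectors)) {
    stop("spectrum length does not match the basis grid")
  }
  drop(crossprod(basis@vectors, spectrum))
}

#' Rank-limited reconstruction of a spectrum
#'
#' Projects onto the first `nUse` singular vectors and reconstructs, giving
#' the best rank-`nUse` approximation within the basis span.  Used to build
#' scenes with a known number of effective spectral patterns.
#'
#' @param basis a [SingularBasis-class].
#' @param spectrum numeric vector on the basis grid.
#' @param nUse number of leading vectors to use.
#' @return numeric vector, reconstructed spectrum.
#' @export
reconstructSpectrum <- function(basis, spectrum, nUse = ncol(basis@vectors)) {
  nUse <- as.integer(nUse)
  if (nUse < 1L || nUse > ncol(basis@vectors)) {
    stop("nUse must be in [1, number of basis vectors]")
  }
  v <- basis@vectors[, seq_len(nUse), drop = FALSE]
  drop(v %*% crossprod(v, spectrum))
}
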