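# Weighted least-squares fit of the forward model with BIC selection of the
# number of singular vectors.

#' Per-channel fit weights from the SNR model
#'
#' The weight is the reciprocal of the radiance uncertainty,
#' `w(lambda) = 1 / un(lambda) = SNR(lambda) / L(lambda)` (units 1/radiance).
#' Channels with non-positive radiance cannot carry a noise model; they get
#' weight 0 (masked, excluded from the fit and RSS) with a warning.  With
#' `snr = NULL` the fit is unweighted (all weights 1), for spectra lacking an
#' SNR specification.
#'
#' @param radiance measured radiance spectrum.
#' @param snr an [SnrModel-class], a positive numeric SNR vector, or NULL.
#' @return numeric weight vector of the same length; masked channels are 0.
#' @examples
#' computeWeights(rep(100, 4), snrModel(300))  # all 3.0
#' @export
computeWeights <- function(radiance, snr = NULL) {
  if (is.null(snr)) return(rep(1, length(radiance)))
  w <- numeric(length(radiance))
  ok <- is.finite(radiance) & radiance > 0
  if (!all(ok)) {
    warning(sprintf("%d channel(s) with non-positive radiance masked from the fit",
                    sum(!ok)))
  }
  if (any(ok)) w[ok] <- .evalSnr(snr, radiance[ok]) / radiance[ok]
  w
}

#' Weighted linear least-squares fit
#'
#' Minimizes `sum((w * (L - X b))^2)` by QR decomposition of the row-scaled
#' design.  The coefficient covariance is the standard weighted least-squares
#' estimate `(Xw' Xw)^-1 * s2` with residual-based variance rescaling
#' `s2 = RSS / (n - k)`, which keeps uncertainties calibrated even when the
#' weights are only proportional to the true inverse noise.
#'
#' @param dm a [DesignMatrix-class] or numeric design matrix.
#' @param radiance observed spectrum over the design rows.
#' @param weights per-channel weights (0 masks a channel).
#' @return list with `coefficients` (named), `covariance`, `residuals`
#'   (observed minus fitted, full length), `fitted`, `dof`.
#' @export
fitLinearModel <- function(dm, radiance, weights = NULL) {
  x <- if (is(dm, "DesignMatrix")) dm@matrix else as.matrix(dm)
  n <- nrow(x)
  k <- ncol(x)
  if (length(radiance) != n) stop("radiance length does not match the design")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length does not match the design")
  use <- is.finite(weights) & weights > 0
  if (sum(use) <= k) {
    stop(sprintf("need more than %d unmasked channels to fit %d coefficients",
                 k, k))
  }
  xw <- x[use, , drop = FALSE] * weights[use]
  yw <- radiance[use] * weights[use]
  qx <- qr(xw)
  if (qx$rank < k) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):k]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, yw)
  fitted <- drop(x %*% beta)
  resid <- radiance - fitted
  rssw <- sum((weights[use] * resid[use])^2)
  dof <- sum(use) - k
  r <- qr.R(qx)
  piv <- qx$pivot
  xtxinv <- chol2inv(r)[order(piv), order(piv), drop = FALSE]
  covb <- xtxinv * (rssw / dof)
  dimnames(covb) <- list(colnames(x), colnames(x))
  list(coefficients = beta, covariance = covb, residuals = resid,
       fitted = fitted, dof = dof)
}

#' Weighted residual sum of squares
#'
#' Default (`form = "quadratic"`): `RSS = sum((w * (L - Lhat))^2)` over
#' unmasked channels — the dimensionless chi-square when `w` is the reciprocal
#' radiance uncertainty.  `form = "linear"` computes `sum(w * (L - Lhat)^2)`
#' instead, exposing the alternative reading of the weighting convention.
#'
#' @param observed,predicted aligned numeric spectra.
#' @param weights per-channel weights; 0 masks a channel.
#' @param form `"quadratic"` (default) or `"linear"`.
#' @return single numeric RSS.
#' @export
computeRss <- function(observed, predicted, weights = NULL,
                       form = c("quadratic", "linear")) {
  form <- match.arg(form)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ")
  }
  if (is.null(weights)) weights <- rep(1, length(observed))
  use <- is.finite(weights) & weights > 0
  r <- observed[use] - predicted[use]
  w <- weights[use]
  if (form == "quadratic") sum((w * r)^2) else sum(w * r^2)
}

#' Bayesian Information Criterion for a spectral fit
#'
#' `BIC = n_lambda * ln(RSS / n_lambda) + k * ln(n_lambda)` with `n_lambda`
#' the number of spectral channels and `k` the number of fitted coefficients,
#' `k = (nP + 1) + (nv - 1) + 1`.
#'
#' @param rss residual sum of squares, > 0.
#' @param nChannels number of channels, > 0.
#' @param k number of coefficients, >= 1.
#' @return single numeric BIC value.
#' @examples
#' computeBic(160, 160, 7)  # 7 * log(160)
#' @export
computeBic <- function(rss, nChannels, k) {
  if (nChannels <= 0) stop("nChannels must be > 0")
  if (k < 1) stop("k must be >= 1")
  if (rss <= 0) {
    stop("rss must be > 0: a numerically perfect fit has no defined BIC")
  }
  nChannels * log(rss / nChannels) + k * log(nChannels)
}

#' Select the number of singular vectors by BIC
#'
#' Fits the forward model for every candidate `nv`, computes the BIC of each,
#' and returns the minimizer (ties broken toward the smallest `nv`; a
#' numerically perfect fit, whose BIC is undefined, is treated as -Inf and
#' wins).  The selected candidate's fit is returned and reused as the final
#' fit — refitting would reproduce it exactly, the solver being deterministic.
#'
#' @param basis a [SingularBasis-class].
#' @param config a [RetrievalConfig-class]; `config@nvCandidates` is the
#'   candidate set.
#' @param radiance measured spectrum over the window channels (already
#'   windowed, matching `buildDesignMatrix` rows).
#' @param weights per-channel weights over the window.
#' @return list with `nvSelected`, `bicByNv` (named over evaluated
#'   candidates), `fit` (the selected [fitLinearModel()] output), `dm`, `rss`.
#' @export
selectNumSvs <- function(basis, config, radiance, weights = NULL) {
  cand <- config@nvCandidates
  if (length(cand) == 0L) stop("no nv candidates supplied")
  bic <- setNames(rep(NA_real_, length(cand)), as.character(cand))
  fits <- vector("list", length(cand))
  errs <- character(length(cand))
  rsss <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    res <- tryCatch({
      dm <- buildDesignMatrix(basis, config, cand[i])
      fit <- fitLinearModel(dm, radiance, weights)
      rss <- computeRss(radiance, fit$fitted, weights, form = config@rssForm)
      b <- if (rss <= 0) -Inf else computeBic(rss, nrow(dm@matrix),
                                              ncol(dm@matrix))
      list(dm = dm, fit = fit, rss = rss, bic = b)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[i] <- conditionMessage(res)
    } else {
      bic[i] <- res$bic
      fits[[i]] <- res
      rsss[i] <- res$rss
    }
  }
  if (all(is.na(bic))) {
    stop(paste0("no nv candidate could be fitted:\n",
                paste(sprintf("  nv = %d: %s", cand, errs), collapse = "\n")))
  }
  best <- which.min(bic)  # candidates ascending: first minimum = smallest nv
  list(nvSelected = cand[best], bicByNv = bic[!is.na(bic)],
       fit = fits[[best]]$fit, dm = fits[[best]]$dm, rss = rsss[best])
}

#' Retrieve sun-induced fluorescence from one spectrum
#'
#' End-to-end single-sounding retrieval: windows the spectrum (half-open on
#' channel centers), computes SNR weights, selects the number of singular
#' vectors by BIC, and extracts the fluorescence amplitude `Fs` (coefficient
#' of the emission-shape column) with its 1-sigma uncertainty from the fit
#' covariance.  `sifAtRef = Fs * hF(lambdaRef)` re-expresses the amplitude at
#' the reporting wavelength.  Failures never yield silent NaN: an invalid
#' [RetrievalResult-class] carries the diagnostic message.
#'
#' @param radiance full-grid radiance spectrum on the basis wavelength axis.
#' @param basis a [SingularBasis-class].
#' @param config a [RetrievalConfig-class].
#' @param snr an [SnrModel-class], per-channel SNR vector on the full grid, or
#'   NULL for an unweighted fit.
#' @param wavelengths optional wavelengths of `radiance`, checked against the
#'   basis grid.
#' @return a [RetrievalResult-class].
#' @examples
#' wl <- spectralGrid()
#' sun <- solarModel()
#' tr <- makeTrainingSet(wl, sun, nScenes = 60, seed = 1)
#' basis <- computeSVs(tr, nKeep = 8)
#' sc <- simulateScenes(1, wl, sun, fsTrue = 0.8, seed = 2)
#' retrieveSif(radianceValues(sc)[, 1], basis, retrievalConfig(),
#'             snr = snrModel(300))
#' @export
retrieveSif <- function(radiance, basis, config = retrievalConfig(),
                        snr = NULL, wavelengths = NULL) {
  stopifnot(is(basis, "SingularBasis"), is(config, "RetrievalConfig"))
  if (!is.null(wavelengths) &&
      !isTRUE(all.equal(wavelengths, basis@wavelengths, tolerance = 1e-9))) {
    stop("spectrum wavelengths do not match the basis grid")
  }
  if (length(radiance) != length(basis@wavelengths)) {
    stop("spectrum length does not match the basis grid")
  }
  idx <- .windowChannels(basis@wavelengths, config@window)
  if (length(idx) == 0L) {
    stop("retrieval window contains no channels of the basis grid")
  }
  lwin <- radiance[idx]
  snrWin <- if (is.null(snr) || is(snr, "SnrModel")) {
    snr
  } else {
    s <- rep_len(as.numeric(snr), length(radiance))
    s[idx]
  }
  w <- if (config@weighting && !is.null(snrWin)) {
    computeWeights(lwin, snrWin)
  } else {
    rep(1, length(lwin))
  }
  sel <- selectNumSvs(basis, config, lwin, w)
  fs <- unname(sel$fit$coefficients["Fs"])
  fsVar <- sel$fit$covariance["Fs", "Fs"]
  hfRef <- gaussianHf(config@lambdaRef, config@sigma, config@phi,
                      config@center)
  new("RetrievalResult", fs = fs, sifAtRef = fs * hfRef,
      coefficients = sel$fit$coefficients, nvSelected = sel$nvSelected,
      bicByNv = sel$bicByNv, rss = sel$rss,
      residuals = sel$fit$residuals, wavelengths = basis@wavelengths[idx],
      fsUncertainty = sqrt(max(fsVar, 0)), valid = TRUE, message = "")
}

#' Retrieve fluorescence for a batch of soundings
#'
#' Runs [retrieveSif()] on every column of a [SpectraSet-class] (or a spectra
#' file readable by [readSpectra()]).  Per-sounding failures are recorded in
#' the `flag` column and the batch continues; ordering follows the input.
#'
#' @param x a [SpectraSet-class] or path to a spectra file.
#' @param basis a [SingularBasis-class].
#' @param config a [RetrievalConfig-class].
#' @param snr optional [SnrModel-class] applied to all soundings; by default
#'   the per-channel `snr` assay of `x` is used when present.
#' @return data.frame with columns sounding_id, fs, sif_at_ref,
#'   fs_uncertainty, nv_selected, rss, bic, flag.
#' @export
retrieveBatch <- function(x, basis, config = retrievalConfig(), snr = NULL) {
  if (is.character(x)) x <- readSpectra(x)
  stopifnot(is(x, "SpectraSet"))
  n <- ncol(x)
  out <- data.frame(
    sounding_id = if (n > 0) colnames(x) else character(0),
    fs = numeric(n), sif_at_ref = numeric(n), fs_uncertainty = numeric(n),
    nv_selected = integer(n), rss = numeric(n), bic = numeric(n),
    flag = character(n), stringsAsFactors = FALSE
  )
  if (n == 0L) {
    warning("empty input: no soundings to retrieve")
    return(out)
  }
  rad <- radianceValues(x)
  snrAssay <- snrValues(x)
  for (i in seq_len(n)) {
    res <- tryCatch({
      s <- if (!is.null(snr)) snr else if (!is.null(snrAssay)) {
        snrAssay[, i]
      } else NULL
      retrieveSif(rad[, i], basis, config, snr = s)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$fs[i] <- NA_real_
      out$sif_at_ref[i] <- NA_real_
      out$fs_uncertainty[i] <- NA_real_
      out$nv_selected[i] <- NA_integer_
      out$rss[i] <- NA_real_
      out$bic[i] <- NA_real_
      out$flag[i] <- paste0("error: ", conditionMessage(res))
    } else {
      out$fs[i] <- res@fs
      out$sif_at_ref[i] <- res@sifAtRef
      out$fs_uncertainty[i] <- res@fsUncertainty
      out$nv_selected[i] <- res@nvSelected
      out$rss[i] <- res@rss
      out$bic[i] <- min(res@bicByNv)
      out$flag[i] <- "ok"
    }
  }
  out
}
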