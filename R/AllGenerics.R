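#' @import methods
NULL

#' Wavelength axis of an object
#' @param x a SpectraSet, SingularBasis or DesignMatrix.
#' @return numeric vector of wavelengths (nm).
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Radiance matrix of a spectra container
#' @param x a SpectraSet.
#' @return numeric matrix, channels x soundings.
#' @export
setGeneric("radianceValues", function(x) standardGeneric("radianceValues"))

#' Per-channel SNR values, if stored
#' @param x a SpectraSet.
#' @return numeric matrix (channels x soundings) or NULL.
#' @export
setGeneric("snrValues", function(x) standardGeneric("snrValues"))

#' Singular vectors of a basis
#' @param x a SingularBasis.
#' @return numeric matrix, channels x vectors, unit-norm columns.
#' @export
setGeneric("basisVectors", function(x) standardGeneric("basisVectors"))

#' Singular values of a basis
#' @param x a SingularBasis.
#' @return non-increasing, non-negative numeric vector.
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' Explained-variance fractions of a basis
#'
#' Fraction p_j = s_j^2 / sum(s_k^2) of the total training-set variance
#' (sum over *all* singular values of the training matrix) carried by each
#' retained vector.
#'
#' @param x a SingularBasis.
#' @return numeric vector in [0, 1].
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
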