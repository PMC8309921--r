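# File formats: schema-versioned delimited text for spectra and bases, YAML
# configuration, JSON run manifests.
#
# Spectra formats
#   single sounding:  TSV/CSV with header columns wavelength_nm, radiance
#                     and optional snr.
#   batch container:  long-format TSV with a commented schema line
#                     "# sifsvd-spectra 1" and columns sounding_id,
#                     wavelength_nm, radiance[, snr]; all soundings share one
#                     wavelength axis.  Values are written at full (17
#                     significant digit) precision so write -> read
#                     round-trips bitwise.

.SPECTRA_SCHEMA <- "sifsvd-spectra 1"
.BASIS_SCHEMA <- "sifsvd-basis 1"

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write spectra to a delimited text file
#'
#' A single sounding is written as two/three-column delimited text
#' (wavelength_nm, radiance\[, snr\]); multiple soundings as the long-format
#' batch container with a `sounding_id` column.  Both carry a commented
#' schema line and round-trip bitwise through [readSpectra()].
#'
#' @param x a [SpectraSet-class].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path, sep = "\t") {
  stopifnot(is(x, "SpectraSet"))
  wl <- wavelengths(x)
  rad <- radianceValues(x)
  snr <- snrValues(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .SPECTRA_SCHEMA), con)
  single <- ncol(x) == 1L
  cols <- c(if (!single) "sounding_id", "wavelength_nm", "radiance",
            if (!is.null(snr)) "snr")
  writeLines(paste(cols, collapse = sep), con)
  for (j in seq_len(ncol(x))) {
    fields <- cbind(if (!single) colnames(x)[j], .fmtNum(wl), .fmtNum(rad[, j]),
                    if (!is.null(snr)) .fmtNum(snr[, j]))
    writeLines(apply(fields, 1L, paste, collapse = sep), con)
  }
  invisible(path)
}

#' Read spectra from a delimited text file
#'
#' Accepts both on-disk formats written by [writeSpectra()] (schema line
#' optional for plain single-sounding files).  Wavelength axes are validated
#' (strictly increasing) and, for batch files, checked to be shared across
#' soundings; violations raise errors naming the offending sounding.
#'
#' @param path input file path.
#' @return a [SpectraSet-class].
#' @export
readSpectra <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  for (col in intersect(c("wavelength_nm", "radiance", "snr"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  need <- c("wavelength_nm", "radiance")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed spectra file '%s': required columns %s, found %s",
                 path, paste(need, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  }
  hasSnr <- "snr" %in% names(df)
  if (nrow(df) == 0L) {
    return(SpectraSet(matrix(numeric(0), 0L, 0L), numeric(0)))
  }
  if ("sounding_id" %in% names(df)) {
    ids <- unique(df$sounding_id)
    wl <- df$wavelength_nm[df$sounding_id == ids[1]]
    tryCatch(.checkGrid(wl), error = function(e) {
      stop(sprintf("sounding '%s': %s", ids[1], conditionMessage(e)),
           call. = FALSE)
    })
    rad <- matrix(NA_real_, length(wl), length(ids),
                  dimnames = list(NULL, ids))
    snr <- if (hasSnr) rad else NULL
    for (id in ids) {
      sub <- df[df$sounding_id == id, ]
      if (nrow(sub) != length(wl) ||
          !isTRUE(all.equal(sub$wavelength_nm, wl))) {
        stop(sprintf("sounding '%s' is not aligned with the shared wavelength axis",
                     id))
      }
      rad[, id] <- sub$radiance
      if (hasSnr) snr[, id] <- sub$snr
    }
    SpectraSet(rad, wl, snr = snr)
  } else {
    tryCatch(.checkGrid(df$wavelength_nm, what = "wavelength_nm"),
             error = function(e) {
               stop(sprintf("malformed spectra file '%s': %s", path,
                            conditionMessage(e)), call. = FALSE)
             })
    SpectraSet(matrix(df$radiance, ncol = 1L), df$wavelength_nm,
               snr = if (hasSnr) matrix(df$snr, ncol = 1L) else NULL)
  }
}

#' Write a singular basis to a delimited text file
#'
#' TSV with a schema line, commented metadata rows carrying the singular
#' values and explained-variance fractions, then one row per channel:
#' wavelength_nm followed by the vector elements.  Full-precision output
#' round-trips bitwise through [readBasis()].
#'
#' @param basis a [SingularBasis-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBasis <- function(basis, path) {
  stopifnot(is(basis, "SingularBasis"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .BASIS_SCHEMA), con)
  writeLines(paste0("# singular_values\t",
                    paste(.fmtNum(basis@singularValues), collapse = "\t")), con)
  writeLines(paste0("# explained_variance\t",
                    paste(.fmtNum(basis@explainedVariance), collapse = "\t")),
             con)
  writeLines(paste(c("wavelength_nm", colnames(basis@vectors)),
                   collapse = "\t"), con)
  rows <- cbind(.fmtNum(basis@wavelengths),
                apply(basis@vectors, 2L, .fmtNum))
  writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a singular basis written by [writeBasis()]
#'
#' @param path input file path.
#' @return a [SingularBasis-class].
#' @export
readBasis <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (!startsWith(lines[1], paste0("# ", .BASIS_SCHEMA))) {
    stop(sprintf("'%s' is not a %s file", path, .BASIS_SCHEMA))
  }
  meta <- lines[startsWith(lines, "# ")][-1]
  getMeta <- function(key) {
    row <- meta[startsWith(meta, paste0("# ", key))]
    if (length(row) != 1L) stop(sprintf("missing '%s' metadata in %s", key, path))
    as.numeric(strsplit(row, "\t")[[1]][-1])
  }
  d <- getMeta("singular_values")
  p <- getMeta("explained_variance")
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          comment.char = "#")
  v <- as.matrix(df[, -1, drop = FALSE])
  new("SingularBasis", wavelengths = df$wavelength_nm, vectors = v,
      singularValues = d, explainedVariance = p)
}

# ---------------------------------------------------------------------------
# Configuration --------------------------------------------------------------

.RETRIEVAL_KEYS <- c("window", "n_p", "nv_candidates", "sigma", "phi",
                     "center", "lambda_ref", "weighting", "rss_form")
.SCENE_KEYS <- c("reflectance_coeffs", "mu0", "fs_true", "sigma_f", "phi",
                 "center", "o2_depth", "snr", "n_scenes", "mu0_range",
                 "line_jitter_sd")
.SOLAR_KEYS <- c("continuum_coeffs", "lines")

.checkKeys <- function(given, valid, section) {
  unknown <- setdiff(names(given), valid)
  if (length(unknown) > 0) {
    stop(sprintf("unknown key(s) in '%s' config: %s. Valid keys: %s",
                 section, paste(unknown, collapse = ", "),
                 paste(valid, collapse = ", ")))
  }
}

#' Load a retrieval/scene/solar configuration from YAML
#'
#' Recognized sections: `retrieval` (keys window, n_p, nv_candidates, sigma,
#' phi, center, lambda_ref, weighting, rss_form), `scene` (simulator truth
#' keys) and `solar` (continuum_coeffs, lines).  Missing keys take the
#' documented defaults; unknown keys are rejected with the list of valid
#' keys; invalid values raise the violated invariant (via class validity).
#' An empty file yields all defaults.
#'
#' @param path YAML file path.
#' @return list with elements `retrieval` ([RetrievalConfig-class]), `scene`
#'   (named list of simulator arguments) and `solar` ([SolarModel-class]).
#' @export
loadConfig <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else {
    stop(sprintf("config file not found: %s", path))
  }
  if (is.null(raw)) raw <- list()
  .checkKeys(raw, c("retrieval", "scene", "solar"), "top-level")
  rt <- raw$retrieval
  if (is.null(rt)) rt <- list()
  .checkKeys(rt, .RETRIEVAL_KEYS, "retrieval")
  cfg <- retrievalConfig(
    window = if (!is.null(rt$window)) unlist(rt$window) else c(771, 778),
    nP = if (!is.null(rt$n_p)) rt$n_p else 1L,
    nvCandidates = if (!is.null(rt$nv_candidates)) unlist(rt$nv_candidates) else 2:8,
    sigma = if (!is.null(rt$sigma)) rt$sigma else 30,
    phi = if (!is.null(rt$phi)) rt$phi else 1,
    center = if (!is.null(rt$center)) rt$center else 740,
    lambdaRef = if (!is.null(rt$lambda_ref)) rt$lambda_ref else 775,
    weighting = if (!is.null(rt$weighting)) rt$weighting else TRUE,
    rssForm = if (!is.null(rt$rss_form)) rt$rss_form else "quadratic"
  )
  sc <- raw$scene
  if (is.null(sc)) sc <- list()
  .checkKeys(sc, .SCENE_KEYS, "scene")
  so <- raw$solar
  if (is.null(so)) so <- list()
  .checkKeys(so, .SOLAR_KEYS, "solar")
  solar <- solarModel(
    continuumCoeffs = if (!is.null(so$continuum_coeffs)) {
      unlist(so$continuum_coeffs)
    } else c(1200, -60),
    lines = if (!is.null(so$lines)) {
      do.call(rbind.data.frame, so$lines)
    } else defaultFraunhoferLines()
  )
  list(retrieval = cfg, scene = sc, solar = solar)
}

#' Write a run manifest
#'
#' JSON record emitted alongside CLI outputs: tool version, configuration
#' snapshot, md5 checksums of input files, seeds and a timestamp.
#'
#' @param path manifest path.
#' @param config named list snapshot of the configuration in effect.
#' @param inputs character vector of input file paths (checksummed).
#' @param seed integer seed(s) used.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(path, config = list(), inputs = character(0),
                          seed = NA_integer_) {
  sums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(
    tool = "sifsvd",
    version = as.character(utils::packageVersion("sifsvd")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_checksums = sums
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
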