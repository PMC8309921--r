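# Shared fixtures, built once per test run and memoized.  All synthetic:
# nothing is read from disk.

suppressPackageStartupMessages(library(SummarizedExperiment))

.fx <- new.env(parent = emptyenv())

fxGrid <- function() spectralGrid()

fxSolar <- function() solarModel()

# Non-fluorescent training set on the default grid.
fxTraining <- function(nScenes = 400, seed = 11) {
  key <- sprintf("training_%d_%d", nScenes, seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- makeTrainingSet(fxGrid(), fxSolar(), nScenes = nScenes,
                                  seed = seed)
  }
  .fx[[key]]
}

# Singular basis from the shared training set.
fxBasis <- function(nKeep = 8, nScenes = 400, seed = 11) {
  key <- sprintf("basis_%d_%d_%d", nKeep, nScenes, seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- computeSVs(fxTraining(nScenes, seed), nKeep = nKeep)
  }
  .fx[[key]]
}

# Independent weighted least-squares oracle: explicit normal equations,
# column-equilibrated with one iterative-refinement step so the oracle's own
# round-off stays below the comparison tolerance on ill-conditioned designs.
normalEquationsFit <- function(x, y, w) {
  xw <- x * w
  yw <- y * w
  d <- sqrt(colSums(xw^2))
  xs <- sweep(xw, 2, d, "/")
  a <- crossprod(xs)
  rhs <- crossprod(xs, yw)
  b <- solve(a, rhs)
  b <- b + solve(a, rhs - a %*% b)
  b[, 1] / d
}
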