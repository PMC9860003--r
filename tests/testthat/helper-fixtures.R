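## Shared fixtures. Expensive end-to-end runs are memoised so several test
## files can reuse the same simulation.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

tstSpectrum <- function(fl = 1e5) memo(paste0("spec", fl), sourceSpectrum(fluenceScale = fl))
idealResp <- function() memo("ideal", detectorResponse("ideal"))
realResp <- function() memo("real", detectorResponse("realistic"))

## reduced-scale geometry for fast pipeline tests: 128 px at 2 mm,
## 216 cells, 180 views (fan coverage preserved)
reducedConfig <- function(mode = "2md", response = "ideal", seed = 5,
                          experiment = "noise_correlation", ...) {
  runConfig(experiment, mode = mode, response = response, nPixels = 128,
            pixelSizeMm = 2, nCells = 216, nViews = 180, seed = seed, ...)
}

reducedRun <- function(mode, response = "ideal", seed = 5) {
  memo(paste("red", mode, response, seed, sep = "_"),
       runNoiseCorrelation(reducedConfig(mode, response, seed)))
}

## full desk-scale runs (256 px / 432 cells / 360 views), used by the
## acceptance suite
deskRun <- function(mode, seed = 1) {
  memo(paste("desk", mode, seed, sep = "_"),
       runNoiseCorrelation(runConfig("noise_correlation", mode = mode,
                                     response = "ideal", seed = seed)))
}

headSweep <- function(seed = 5) {
  memo(paste0("sweep", seed),
       sweepHeadVMI(reducedConfig(experiment = "head_vmi", seed = seed)))
}

## tiny two-material disc phantom fully inside the basis span (no water
## background), for exact inverse-consistency checks
discPhantom <- function(n = 96, px = 2.5, mats = c("soft_tissue", "cortical_bone"),
                        coefs = c(0.6, 0.4), radiusMm = 50) {
  coeffs <- array(0, c(n, n, length(mats)))
  ax <- ((seq_len(n) - 0.5) - n / 2) * px
  m <- outer(ax, ax, function(x, y) x^2 + y^2 <= radiusMm^2)
  for (p in seq_along(mats)) coeffs[, , p][m] <- coefs[p]
  new("PhantomImage", coeffs = coeffs, materials = mats, pixelSizeMm = px)
}

tinyGeometry <- function(nCells = 108L, nViews = 90L)
  geometry(nCells = nCells, nViews = nViews)
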