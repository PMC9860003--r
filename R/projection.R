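## Fan-beam forward model: exact line integrals, polychromatic expected
## counts, and Poisson / charge-sharing count sampling.

#' Equiangular fan-beam geometry
#'
#' Defaults follow a clinical-geometry single-row acquisition: 541.0 mm
#' source-to-iso, 949.0 mm source-to-detector, 864 cells of 1.024 mm pitch,
#' 720 views per full rotation. Desk-scale runs use 432 cells / 360 views
#' (see [deskGeometry()]).
#'
#' @param nCells detector cells (single row).
#' @param nViews views per 360 degree rotation.
#' @param sourceToIsoMm,sourceToDetectorMm distances in mm.
#' @param cellPitchMm detector pitch in mm. When `nCells` is reduced below
#'   864 the pitch is scaled up to preserve the fan coverage.
#' @return A [Geometry-class].
#' @export
#' @examples
#' geometry()
geometry <- function(nCells = 864L, nViews = 720L, sourceToIsoMm = 541.0,
                     sourceToDetectorMm = 949.0,
                     cellPitchMm = 1.024 * 864 / nCells) {
  new("Geometry", sourceToIsoMm = sourceToIsoMm,
      sourceToDetectorMm = sourceToDetectorMm, nCells = as.integer(nCells),
      cellPitchMm = cellPitchMm, nViews = as.integer(nViews))
}

#' Desk-scale geometry profile
#'
#' Half resolution in cells and views (432 cells, 360 views) with the fan
#' coverage preserved; intended for laptop-scale runs and the test suite.
#'
#' @param nCells,nViews overrides.
#' @return A [Geometry-class].
#' @export
deskGeometry <- function(nCells = 432L, nViews = 360L)
  geometry(nCells = nCells, nViews = nViews)

## per-cell fan angles (rad) and per-view source angles (rad)
.fanAngles <- function(geom) {
  dg <- geom@cellPitchMm / geom@sourceToDetectorMm
  (seq_len(geom@nCells) - (geom@nCells + 1) / 2) * dg
}
.viewAngles <- function(geom)
  (seq_len(geom@nViews) - 1) * 2 * pi / geom@nViews

#' Exact per-material line integrals
#'
#' Siddon ray tracing of every coefficient map of the phantom through the
#' fan-beam geometry. Units: cm (coefficients are dimensionless).
#'
#' @param phantom a [PhantomImage-class].
#' @param geom a [Geometry-class].
#' @return A [LineIntegralSinogram-class] with one material slab per phantom
#'   material.
#' @export
lineIntegrals <- function(phantom, geom) {
  vals <- cpp_forward_project(phantom@coeffs, dim(phantom@coeffs)[1],
                              phantom@pixelSizeMm, .viewAngles(geom),
                              .fanAngles(geom), geom@sourceToIsoMm) / 10
  dim(vals) <- c(geom@nViews, geom@nCells, length(phantom@materials))
  new("LineIntegralSinogram", values = vals, materials = phantom@materials,
      geometry = geom,
      converged = matrix(TRUE, geom@nViews, geom@nCells))
}

## ---- polychromatic forward core (shared with decomposition/analytics) ----

## Expected channel counts for a matrix of line integrals.
## Amat: rays x P (cm); muMat: 140 x P (per cm); returns list with
## I (rays x K) and, for sharing responses, the independent-component means
## ns (rays x K) and pair (rays x K^2).
.forwardMeans <- function(Amat, muMat, spectrum, cw, withMu = FALSE) {
  expo <- -Amat %*% t(muMat)
  ## guard: trial iterates with negative paths can drive the low-energy
  ## exponent past double range (mu at a few keV is ~1e4/cm); the clip keeps
  ## the forward map finite there without touching any physical regime
  expo[expo > 500] <- 500
  Tmat <- exp(expo)                          # rays x 140 transmission
  fl <- spectrum@fluence
  I <- Tmat %*% (fl * cw$W)
  out <- list(I = I)
  if (any(cw$Wpair != 0)) {
    out$ns <- Tmat %*% (fl * cw$Wns)
    out$pair <- Tmat %*% (fl * cw$Wpair)
  }
  if (withMu) {
    K <- ncol(cw$W); P <- ncol(muMat)
    mu <- array(0, c(nrow(Amat), K, P))
    for (k in seq_len(K)) {
      wk <- fl * cw$W[, k]
      for (p in seq_len(P))
        mu[, k, p] <- (Tmat %*% (wk * muMat[, p])) / I[, k]
    }
    out$mu <- mu
  }
  out
}

#' Expected per-channel counts of a line-integral sinogram
#'
#' Beer-Lambert attenuation of the source spectrum by the per-material line
#' integrals, weighted by the effective channel response and summed over the
#' 1-keV grid (left Riemann sum at the table resolution).
#'
#' @param A a [LineIntegralSinogram-class] (materials resolvable by
#'   [getMaterial()]).
#' @param spectrum a [Spectrum-class].
#' @param channels a [ChannelSet-class].
#' @param response a [DetectorResponse-class].
#' @return A [CountsSinogram-class] with `expected = TRUE` (real-valued).
#' @export
expectedCounts <- function(A, spectrum, channels, response) {
  if (any(A@values < 0)) stop("negative line integrals")
  geom <- A@geometry
  nRays <- geom@nViews * geom@nCells
  Amat <- matrix(A@values, nRays, dim(A@values)[3])
  muMat <- .muMatrix(as.list(A@materials))
  cw <- .channelWeights(channels, response)
  fm <- .forwardMeans(Amat, muMat, spectrum, cw)
  K <- nChannels(channels)
  counts <- array(fm$I, c(geom@nViews, geom@nCells, K))
  comp <- if (!is.null(fm$ns))
    list(ns = fm$ns, pair = fm$pair, K = K) else list()
  new("CountsSinogram", counts = counts,
      airCounts = airScanCounts(spectrum, channels, response),
      channels = channels, geometry = geom, expected = TRUE,
      components = comp)
}

## Sample channel counts given component means (matrix interface).
## Ideal response: independent Poisson per channel. Sharing response: the
## count vector decomposes exactly into independent Poisson components --
## non-shared counts per channel plus one Poisson per ordered fragment
## channel pair, each pair contributing one count to both its channels.
.sampleCountsMatrix <- function(fm, response, K) {
  if (response@sharingFraction == 0 || is.null(fm$ns)) {
    cnt <- matrix(rpois(length(fm$I), fm$I), nrow(fm$I), K)
  } else {
    cnt <- matrix(rpois(length(fm$ns), fm$ns), nrow(fm$ns), K)
    npair <- matrix(rpois(length(fm$pair), fm$pair), nrow(fm$pair), K * K)
    k1 <- rep(seq_len(K), times = K)
    k2 <- rep(seq_len(K), each = K)
    for (j in seq_len(K * K)) {
      cnt[, k1[j]] <- cnt[, k1[j]] + npair[, j]
      cnt[, k2[j]] <- cnt[, k2[j]] + npair[, j]
    }
  }
  cnt
}

#' Sample noisy channel counts
#'
#' Draws Poisson-distributed counts from an expected-counts sinogram. With an
#' ideal response the channels are independent; with a realistic response the
#' charge-sharing component makes two channels receive a count from the same
#' photon, inducing positive interchannel correlation. A fixed seed makes the
#' draw bit-reproducible.
#'
#' @param expected a [CountsSinogram-class] with `expected = TRUE`.
#' @param response the [DetectorResponse-class] used to build `expected`.
#' @param seed integer RNG seed.
#' @return A [CountsSinogram-class] with `expected = FALSE`.
#' @export
sampleCounts <- function(expected, response, seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  stopifnot(expected@expected)
  set.seed(as.integer(seed))
  geom <- expected@geometry
  K <- nChannels(expected)
  nRays <- geom@nViews * geom@nCells
  fm <- list(I = matrix(expected@counts, nRays, K))
  if (length(expected@components)) {
    fm$ns <- expected@components$ns
    fm$pair <- expected@components$pair
  }
  cnt <- .sampleCountsMatrix(fm, response, K)
  new("CountsSinogram", counts = array(cnt, c(geom@nViews, geom@nCells, K)),
      airCounts = expected@airCounts, channels = expected@channels,
      geometry = geom, expected = FALSE, components = list())
}
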