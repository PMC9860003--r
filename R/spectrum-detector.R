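## Source spectrum, spectral channelization and detector response models.

#' Filtered 140 kVp bremsstrahlung source spectrum
#'
#' Kramers-shaped tube spectrum, `(kVp - E)/E`, hardened by an aluminum
#' filtration layer, normalized to a total expected fluence per detector cell
#' per view. The default 6 mm aluminum-equivalent filtration is calibrated so
#' that the packaged two-channel preset ([1-58 | 59-140] keV) splits the
#' air-scan counts essentially evenly, which is the stated channelization
#' goal of the acquisition model.
#'
#' @param kVp tube potential in keV (endpoint energy), <= 140.
#' @param fluenceScale total expected photons per cell per view (air scan).
#' @param filtrationMmAl aluminum filtration thickness in mm.
#' @return A [Spectrum-class].
#' @export
#' @examples
#' s <- sourceSpectrum()
#' sum(s@fluence)
sourceSpectrum <- function(kVp = 140, fluenceScale = 1e5,
                           filtrationMmAl = 6) {
  if (fluenceScale <= 0) stop("fluenceScale must be positive")
  if (kVp > .NE) stop("kVp exceeds the 140 keV grid")
  E <- energyGrid()
  muAl <- getMaterial("aluminum")@mu
  ## Kramers averaged over each 1-keV bin (keeps the endpoint bin populated)
  raw <- pmax(kVp - E + 0.5, 0) / E * exp(-muAl * filtrationMmAl / 10)
  new("Spectrum", fluence = raw / sum(raw) * fluenceScale, kVp = kVp)
}

#' Construct a spectral channel set
#'
#' @param bounds K x 2 matrix (or vector of K+1 breakpoints via `breaks`) of
#'   inclusive integer keV bounds; channels must tile [1, 140].
#' @return A [ChannelSet-class].
#' @export
#' @examples
#' channelSet(rbind(c(1, 58), c(59, 140)))
channelSet <- function(bounds) {
  b <- matrix(as.integer(bounds), ncol = 2)
  new("ChannelSet", bounds = b)
}

#' Packaged spectral channel presets
#'
#' The equal-count channel boundaries used throughout the simulation study:
#' [1-58, 59-140] keV for two channels, [1-51, 52-68, 69-140] keV for three,
#' and [1-43, 44-58, 59-72, 73-140] keV for four.
#'
#' @param K number of channels (2, 3 or 4).
#' @return A [ChannelSet-class].
#' @export
channelPreset <- function(K) {
  b <- switch(as.character(K),
    "2" = rbind(c(1, 58), c(59, 140)),
    "3" = rbind(c(1, 51), c(52, 68), c(69, 140)),
    "4" = rbind(c(1, 43), c(44, 58), c(59, 72), c(73, 140)),
    stop("no packaged preset for K = ", K))
  channelSet(b)
}

#' Detector response model
#'
#' `mode = "ideal"` records every detected photon at its incident energy.
#' `mode = "realistic"` applies a parameterized CZT-like recorded-energy
#' kernel: a Gaussian photopeak with sigma(E) = `sigmaA + sigmaB * sqrt(E)`,
#' a K-escape satellite at E - 27 keV (Cd/Te fluorescence), and a flat
#' low-energy tail; in addition a photon is split by charge sharing into two
#' recorded counts of energies uE and (1-u)E, u ~ Uniform(`uRange`), with
#' probability `sharingFraction`. Charge sharing is what makes counts in two
#' different channels positively correlated.
#'
#' @param mode "ideal" or "realistic".
#' @param efficiency detection efficiency; scalar or per-bin vector in [0,1].
#' @param sigmaA,sigmaB photopeak width parameters (keV, keV/sqrt(keV)).
#' @param escapeWeight weight of the K-escape satellite.
#' @param tailWeight weight of the flat low-energy tail.
#' @param escapeShift fluorescence escape energy deficit in keV.
#' @param sharingFraction probability a photon yields two recorded counts.
#' @param uRange support of the charge-sharing split fraction.
#' @return A [DetectorResponse-class].
#' @export
#' @examples
#' detectorResponse("ideal")
#' detectorResponse("realistic")
detectorResponse <- function(mode = c("ideal", "realistic"), efficiency = 1,
                             sigmaA = 1.5, sigmaB = 0.3,
                             escapeWeight = 0.08, tailWeight = 0.12,
                             escapeShift = 27,
                             sharingFraction = if (mode == "realistic") 0.1 else 0,
                             uRange = c(0.1, 0.5)) {
  mode <- match.arg(mode)
  eff <- rep_len(efficiency, .NE)
  E <- energyGrid()
  if (mode == "ideal") {
    kern <- diag(.NE)
    sharingFraction <- 0
  } else {
    kern <- matrix(0, .NE, .NE)
    peakW <- 1 - escapeWeight - tailWeight
    for (j in seq_len(.NE)) {
      sig <- sigmaA + sigmaB * sqrt(E[j])
      peak <- exp(-0.5 * ((E - E[j]) / sig)^2)
      peak <- peak / sum(peak)
      col <- peakW * peak
      if (E[j] - escapeShift >= 1) {
        esc <- exp(-0.5 * ((E - (E[j] - escapeShift)) / sig)^2)
        col <- col + escapeWeight * esc / sum(esc)
      } else {
        col <- col + escapeWeight * peak
      }
      tail <- as.numeric(E <= E[j])
      col <- col + tailWeight * tail / sum(tail)
      kern[, j] <- col
    }
  }
  new("DetectorResponse", mode = mode, efficiency = eff, kernel = kern,
      sharingFraction = sharingFraction, uRange = uRange)
}

#' Channel weighting function D_k(E)
#'
#' The effective weight with which a photon of incident energy E contributes
#' to the recorded counts of channel k: detection efficiency times the
#' probability that its recorded energy falls inside the channel (for a
#' realistic response this includes charge-sharing fragments, so the weight
#' is positive well outside the channel's nominal interval -- the
#' interchannel overlap).
#'
#' @param channels a [ChannelSet-class].
#' @param response a [DetectorResponse-class].
#' @param k channel index in 1..K.
#' @return Numeric(140) weights on [energyGrid()].
#' @export
channelWeighting <- function(channels, response, k) {
  K <- nChannels(channels)
  if (k < 1 || k > K) stop("channel index out of range")
  .channelWeights(channels, response)$W[, k]
}

## Effective per-channel weights W (140 x K) for expected counts, the
## non-shared weights Wns, and the ordered-pair weights Wpair (140 x K^2)
## of the charge-sharing fragments. Columns of Wpair are indexed (k1, k2)
## with k1 varying fastest. Cached per (channels, response).
.channelWeights <- function(channels, response) {
  key <- paste0("cw_", paste(c(channels@bounds), collapse = "_"), "_",
                response@mode, "_", response@sharingFraction, "_",
                signif(sum(response@kernel), 10), "_",
                signif(sum(response@efficiency), 10))
  if (!is.null(.pkgEnv[[key]])) return(.pkgEnv[[key]])
  E <- energyGrid()
  K <- nChannels(channels)
  b <- channels@bounds
  chOf <- integer(.NE)          # channel of each recorded-energy bin
  for (k in seq_len(K)) chOf[E >= b[k, 1] & E <= b[k, 2]] <- k
  ## kernel channel probabilities q_k(E) per incident bin
  q <- t(rowsum(response@kernel, chOf))            # 140 x K
  s <- response@sharingFraction
  eff <- response@efficiency
  Wns <- (1 - s) * q * eff
  if (s > 0) {
    u <- seq(response@uRange[1], response@uRange[2], length.out = 201)
    Wpair <- matrix(0, .NE, K * K)
    for (j in seq_len(.NE)) {
      k1 <- chOf[pmin(pmax(as.integer(round(u * E[j])), 1L), .NE)]
      k2 <- chOf[pmin(pmax(as.integer(round((1 - u) * E[j])), 1L), .NE)]
      tab <- tabulate((k2 - 1L) * K + k1, nbins = K * K)
      Wpair[j, ] <- s * eff[j] * tab / length(u)
    }
    ## marginal count contribution of each fragment
    M1 <- t(rowsum(t(Wpair), rep(seq_len(K), times = K)))   # first fragment
    M2 <- t(rowsum(t(Wpair), rep(seq_len(K), each = K)))    # second fragment
    W <- Wns + M1 + M2
  } else {
    Wpair <- matrix(0, .NE, K * K)
    W <- Wns
  }
  out <- list(W = W, Wns = Wns, Wpair = Wpair, K = K)
  .pkgEnv[[key]] <- out
  out
}

#' Equal-count spectral channelization
#'
#' Deterministic greedy split of the cumulative detected air-scan counts into
#' K channels with as-equal-as-possible totals: channel j ends at the first
#' bin where the cumulative sum reaches j/K of the total.
#'
#' @param spectrum a [Spectrum-class].
#' @param response a [DetectorResponse-class] (its efficiency weights the
#'   incident fluence).
#' @param K number of channels, >= 2.
#' @return A [ChannelSet-class].
#' @export
#' @examples
#' channelizeEqualCounts(sourceSpectrum(), detectorResponse("ideal"), 2)
channelizeEqualCounts <- function(spectrum, response, K) {
  if (K < 2) stop("K must be >= 2")
  w <- spectrum@fluence * response@efficiency
  if (K > sum(w > 0)) stop("K exceeds the number of populated bins")
  cs <- cumsum(w) / sum(w)
  ends <- vapply(seq_len(K - 1), function(j) {
    tgt <- j / K
    b <- which(cs >= tgt)[1]
    ## step back one bin when that leaves the cumulative sum closer to the
    ## target; keeps the per-channel imbalance below one bin's fluence
    if (b > 1L && tgt - cs[b - 1L] < cs[b] - tgt) b - 1L else b
  }, integer(1))
  ends <- unique(pmin(ends, .NE - (K - seq_len(K - 1))))
  if (length(ends) != K - 1) stop("degenerate channelization")
  lo <- c(1L, ends + 1L)
  hi <- c(ends, .NE)
  channelSet(cbind(lo, hi))
}

#' Expected air-scan channel counts
#'
#' @param spectrum a [Spectrum-class].
#' @param channels a [ChannelSet-class].
#' @param response a [DetectorResponse-class].
#' @return Numeric(K) expected counts per channel with no object in the beam.
#' @export
airScanCounts <- function(spectrum, channels, response) {
  cw <- .channelWeights(channels, response)
  as.numeric(crossprod(cw$W, spectrum@fluence))
}
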