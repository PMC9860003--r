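## Image-domain spectral metrics: virtual monochromatic synthesis, Pearson
## noise correlation, ROI statistics and CNR.

#' Synthesize a virtual monochromatic image
#'
#' Pixel-wise linear combination of the basis images with the basis
#' attenuation coefficients at a single energy:
#' `mu(x; E) = sum_p a_p(x) mu_p(E)`.
#'
#' @param basisImages a [BasisImageSet-class].
#' @param eMono monochromatic energy in keV, within [1, 140].
#' @param basisMaterials optional material override (defaults to the image
#'   set's own materials).
#' @param hounsfield if TRUE, convert to HU relative to water at `eMono`.
#' @return Matrix of linear attenuation (per cm) or HU.
#' @export
synthesizeVMI <- function(basisImages, eMono, basisMaterials = NULL,
                          hounsfield = FALSE) {
  if (eMono < 1 || eMono > 140) stop("eMono must lie in [1, 140] keV")
  mats <- if (is.null(basisMaterials)) as.list(basisImages@materials)
          else basisMaterials
  if (length(mats) != dim(basisImages@images)[3])
    stop("basis/image count mismatch")
  mu <- vapply(mats, function(m) attenuation(m, eMono), numeric(1))
  n <- dim(basisImages@images)[1]
  vmi <- matrix(0, n, n)
  for (p in seq_along(mats)) vmi <- vmi + basisImages@images[, , p] * mu[p]
  if (hounsfield) {
    muW <- attenuation("water", eMono)
    vmi <- 1000 * (vmi - muW) / muW
  }
  vmi
}

#' Pearson correlation coefficient of paired pixel values
#'
#' The plain sample Pearson R between two equal-length pixel vectors,
#' `sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`.
#'
#' @param x,y numeric vectors of equal length N >= 2 with nonzero variance.
#' @return List with `R`, `N`.
#' @export
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(2, 1, 4, 3))  # R = 0.6
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two pixels")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) stop("zero variance: Pearson R undefined")
  list(R = sum(dx * dy) / sqrt(sxx * syy), N = length(x))
}

#' Contrast-to-noise ratio between two ROIs
#'
#' `CNR = (m_sig - m_bkg) / (0.5 (sd_sig + sd_bkg))`, with means and
#' standard deviations gauged in the signal and background ROIs.
#'
#' @param signal,background numeric vectors of ROI pixel values.
#' @return List with `mSig`, `sdSig`, `mBkg`, `sdBkg`, `contrast`, `cnr`.
#' @export
#' @examples
#' cnr(rnorm(100, 10, 2), rnorm(100, 6, 2))
cnr <- function(signal, background) {
  mS <- mean(signal); mB <- mean(background)
  sS <- sd(signal); sB <- sd(background)
  den <- (sS + sB) / 2
  if (den == 0) stop("zero denominator: both ROIs are constant")
  list(mSig = mS, sdSig = sS, mBkg = mB, sdBkg = sB,
       contrast = mS - mB, cnr = (mS - mB) / den)
}

#' Pairwise noise-correlation table over basis images
#'
#' Forms noise-only images by subtracting a matched noiseless reconstruction
#' from the noisy one (so deterministic reconstruction texture does not bias
#' the correlation), then computes the Pearson R between every unordered
#' material pair within each ROI.
#'
#' @param noisy,noiseless matched [BasisImageSet-class] objects (same
#'   materials, same grid).
#' @param rois list of [ROI-class].
#' @return data.frame with columns roi, material1, material2, R, N.
#' @export
noiseCorrelationReport <- function(noisy, noiseless, rois) {
  if (!identical(noisy@materials, noiseless@materials))
    stop("noisy and noiseless image sets must share materials")
  P <- length(noisy@materials)
  if (P < 2) stop("need at least two basis images")
  noise <- noisy@images - noiseless@images
  if (is(rois, "ROI")) rois <- list(rois)
  rows <- list()
  for (r in seq_along(rois)) {
    px <- lapply(seq_len(P), function(p)
      roiPixels(noise[, , p], rois[[r]], noisy@pixelSizeMm))
    for (i in seq_len(P - 1)) for (j in (i + 1):P) {
      pr <- pearsonR(px[[i]], px[[j]])
      lab <- rois[[r]]@label
      rows[[length(rows) + 1L]] <- data.frame(
        roi = if (nzchar(lab)) lab else paste0("roi", r),
        material1 = noisy@materials[i], material2 = noisy@materials[j],
        R = pr$R, N = pr$N)
    }
  }
  do.call(rbind, rows)
}
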