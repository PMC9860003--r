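## Digital phantoms with ground-truth basis-coefficient maps, plus circular
## ROI plumbing. Coordinate convention: isocenter origin, mm units, pixel
## centers at (i + 0.5 - N/2) * pixelSize for 0-based index i.

#' Construct a circular ROI
#'
#' @param centerMm (x, y) center in isocenter coordinates, mm.
#' @param diameterMm diameter in mm.
#' @param label optional label.
#' @return An [ROI-class].
#' @export
roi <- function(centerMm, diameterMm, label = "") {
  new("ROI", centerMm = as.numeric(centerMm),
      diameterMm = as.numeric(diameterMm), label = label)
}

## pixel-center coordinate axis (mm) for an N-pixel grid
.pixelAxis <- function(n, pixelSizeMm)
  ((seq_len(n) - 0.5) - n / 2) * pixelSizeMm

## logical mask of pixels whose centers fall inside an ellipse
.ellipseMask <- function(n, pixelSizeMm, cx, cy, a, b, phiDeg = 0) {
  ax <- .pixelAxis(n, pixelSizeMm)
  X <- matrix(ax, n, n) - cx
  Y <- matrix(ax, n, n, byrow = TRUE) - cy
  phi <- phiDeg * pi / 180
  Xr <- X * cos(phi) + Y * sin(phi)
  Yr <- -X * sin(phi) + Y * cos(phi)
  (Xr / a)^2 + (Yr / b)^2 <= 1
}

## Table of rod compositions (coefficient fractions) per decomposition mode.
## Basis order: 2-MD (tissue, bone); 3-MD (tissue, iodine 10 mg/ml, bone);
## 4-MD (tissue, iodine 10 mg/ml, gadolinium 10 mg/ml, bone).
.rodTable <- function(mode) {
  switch(mode,
    "2md" = list(
      materials = c("soft_tissue", "cortical_bone"),
      rods = rbind(c(1 / 3, 2 / 3),
                   c(1 / 2, 1 / 2),
                   c(2 / 3, 1 / 3))),
    "3md" = list(
      materials = c("soft_tissue", "iodine_10mgml", "cortical_bone"),
      rods = rbind(c(2 / 7, 4 / 7, 1 / 7),
                   c(3 / 7, 3 / 7, 1 / 7),
                   c(4 / 7, 2 / 7, 1 / 7))),
    "4md" = list(
      materials = c("soft_tissue", "iodine_10mgml", "gadolinium_10mgml",
                    "cortical_bone"),
      rods = rbind(c(2 / 7, 2.5 / 7, 2 / 7, 0.5 / 7),
                   c(3 / 7, 2 / 7, 1.5 / 7, 0.5 / 7),
                   c(3 / 7, 2.5 / 7, 1 / 7, 0.5 / 7))),
    stop("mode must be one of '2md', '3md', '4md'"))
}

#' Three-rod noise-correlation phantom
#'
#' A 20 cm water cylinder holding three 7 cm rods at 120 degree spacing on a
#' 5.5 cm radius. Rod compositions are coefficient fractions of the basis
#' materials of the requested decomposition mode (see [.rodTable] source for
#' the exact fractions). The water background is carried as an extra material
#' channel in the returned [PhantomImage-class]; decomposition later operates
#' on the basis materials only. One 6 cm diameter ROI is returned concentric
#' with each rod.
#'
#' @param mode "2md", "3md" or "4md".
#' @param nPixels grid size (default 256).
#' @param pixelSizeMm pixel size in mm (default 1.0; FOV must cover 20 cm).
#' @return List with `phantom` ([PhantomImage-class]) and `rois` (list of 3
#'   [ROI-class], one per rod).
#' @export
#' @examples
#' p <- buildNoisePhantom("2md", nPixels = 64, pixelSizeMm = 4)
#' p$phantom
buildNoisePhantom <- function(mode = c("2md", "3md", "4md"), nPixels = 256,
                              pixelSizeMm = 1.0) {
  mode <- match.arg(mode)
  if (nPixels * pixelSizeMm < 200)
    stop("field of view must cover the 20 cm phantom")
  tab <- .rodTable(mode)
  P <- length(tab$materials)
  mats <- c(tab$materials, "water")
  coeffs <- array(0, dim = c(nPixels, nPixels, P + 1L),
                  dimnames = list(NULL, NULL, mats))
  waterMask <- .ellipseMask(nPixels, pixelSizeMm, 0, 0, 100, 100)
  coeffs[, , P + 1L][waterMask] <- 1
  rodR <- 55; ang <- (c(90, 210, 330)) * pi / 180
  rois <- vector("list", 3L)
  for (r in 1:3) {
    cx <- rodR * cos(ang[r]); cy <- rodR * sin(ang[r])
    m <- .ellipseMask(nPixels, pixelSizeMm, cx, cy, 35, 35)
    coeffs[, , P + 1L][m] <- 0
    for (p in seq_len(P)) coeffs[, , p][m] <- tab$rods[r, p]
    rois[[r]] <- roi(c(cx, cy), 60, sprintf("rod%d", r))
  }
  list(phantom = new("PhantomImage", coeffs = coeffs, materials = mats,
                     pixelSizeMm = pixelSizeMm),
       rois = rois)
}

## Modified Shepp-Logan ellipse table (cm-scaled by 10): the classic head
## geometry with materials reassigned. Later rows overwrite earlier ones.
.headEllipses <- function() {
  ## cx, cy, a, b (mm), phi (deg), material
  list(
    list(  0,    0, 69.0, 92.0,   0, "cortical_bone"),  # skull
    list(  0, -1.84, 66.2, 87.4,  0, "soft_tissue"),    # brain interior
    list( 22,    0, 11.0, 31.0, -18, "adipose"),        # right ventricle
    list(-22,    0, 16.0, 41.0,  18, "adipose"),        # left ventricle
    list(  0,  35.0, 21.0, 25.0,  0, "soft_tissue"),    # superior mass
    list(-12, -50.0, 10.0, 10.0,  0, "iodine_20mgml"),  # lesion 1 (signal)
    list( 14, -48.0,  8.0,  8.0,  0, "iodine_20mgml")   # lesion 2
  )
}

#' Modified Shepp-Logan head phantom
#'
#' The classic head-phantom ellipse geometry with materials reassigned:
#' cortical-bone shell, soft-tissue interior, two adipose ventricles, and two
#' small 20 mg/ml iodine lesions near the base. Returns a signal ROI inside
#' the larger lesion and a background ROI in adjacent soft tissue.
#'
#' @param nPixels grid size (default 256).
#' @param pixelSizeMm pixel size in mm (default 1.0).
#' @param signalRoi,backgroundRoi optional [ROI-class] overrides.
#' @return List with `phantom` ([PhantomImage-class]), `signalRoi` and
#'   `backgroundRoi`.
#' @export
buildHeadPhantom <- function(nPixels = 256, pixelSizeMm = 1.0,
                             signalRoi = NULL, backgroundRoi = NULL) {
  ells <- .headEllipses()
  mats <- unique(vapply(ells, `[[`, character(1), 6))
  coeffs <- array(0, dim = c(nPixels, nPixels, length(mats)),
                  dimnames = list(NULL, NULL, mats))
  for (e in ells) {
    m <- .ellipseMask(nPixels, pixelSizeMm, e[[1]], e[[2]], e[[3]], e[[4]],
                      e[[5]])
    for (p in seq_along(mats)) coeffs[, , p][m] <- 0   # later ellipses overwrite
    coeffs[, , match(e[[6]], mats)][m] <- 1
  }
  if (is.null(signalRoi)) signalRoi <- roi(c(-12, -50), 14, "signal")
  if (is.null(backgroundRoi)) backgroundRoi <- roi(c(2, -20), 14, "background")
  list(phantom = new("PhantomImage", coeffs = coeffs, materials = mats,
                     pixelSizeMm = pixelSizeMm),
       signalRoi = signalRoi, backgroundRoi = backgroundRoi)
}

#' Extract pixel values inside a circular ROI
#'
#' Returns the values of all pixels whose centers fall inside the circle.
#'
#' @param image 2-D numeric matrix on the package pixel convention.
#' @param roi an [ROI-class].
#' @param pixelSizeMm pixel size of `image` in mm.
#' @return Numeric vector of pixel values (error if the ROI is empty).
#' @export
roiPixels <- function(image, roi, pixelSizeMm) {
  n <- nrow(image)
  mask <- .ellipseMask(n, pixelSizeMm, roi@centerMm[1], roi@centerMm[2],
                       roi@diameterMm / 2, roi@diameterMm / 2)
  if (!any(mask)) stop("ROI contains no pixel centers")
  image[mask]
}
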