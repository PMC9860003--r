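setMethod("show", "Material", function(object) {
  ke <- if (length(object@kEdges))
    paste0("; K-edge at ", paste(object@kEdges, collapse = ", "), " keV")
  else ""
  cat(sprintf("Material '%s': mu(60 keV) = %.4f /cm%s\n",
              object@name, object@mu[60], ke))
})

setMethod("show", "Spectrum", function(object) {
  fl <- object@fluence
  cat(sprintf(
    "Spectrum: %g kVp, total fluence %.4g photons/cell/view, mean %.1f keV\n",
    object@kVp, sum(fl), sum(fl * energyGrid()) / sum(fl)))
})

setMethod("show", "ChannelSet", function(object) {
  b <- object@bounds
  cat(sprintf("ChannelSet with %d channels: %s keV\n", nrow(b),
              paste(sprintf("[%d-%d]", b[, 1], b[, 2]), collapse = " ")))
})

setMethod("show", "DetectorResponse", function(object) {
  cat(sprintf("DetectorResponse: %s mode, sharing fraction %.3g\n",
              object@mode, object@sharingFraction))
})

setMethod("show", "Geometry", function(object) {
  cat(sprintf(
    "Geometry: SID %.1f mm, SDD %.1f mm, %d cells @ %.3f mm, %d views/360deg\n",
    object@sourceToIsoMm, object@sourceToDetectorMm, object@nCells,
    object@cellPitchMm, object@nViews))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI '%s': center (%.1f, %.1f) mm, diameter %.1f mm\n",
              if (length(object@label)) object@label else "",
              object@centerMm[1], object@centerMm[2], object@diameterMm))
})

setMethod("show", "PhantomImage", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf("PhantomImage: %d x %d @ %.2f mm, materials: %s\n",
              d[1], d[2], object@pixelSizeMm,
              paste(object@materials, collapse = ", ")))
})

setMethod("show", "LineIntegralSinogram", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "LineIntegralSinogram: %d views x %d cells, materials: %s (%.2f%% flagged)\n",
    d[1], d[2], paste(object@materials, collapse = ", "),
    100 * mean(!object@converged)))
})

setMethod("show", "CountsSinogram", function(object) {
  d <- dim(object@counts)
  cat(sprintf("CountsSinogram (%s): %d views x %d cells x %d channels\n",
              if (object@expected) "expected" else "sampled",
              d[1], d[2], d[3]))
})

setMethod("show", "BasisImageSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("BasisImageSet: %d x %d @ %.2f mm, materials: %s\n",
              d[1], d[2], object@pixelSizeMm,
              paste(object@materials, collapse = ", ")))
})

setMethod("show", "OperatingPoint", function(object) {
  cat(sprintf("OperatingPoint: A = (%s) cm, Ibar = (%s)\n",
              paste(sprintf("%.3f", object@A), collapse = ", "),
              paste(sprintf("%.1f", object@Ibar), collapse = ", ")))
})

setMethod("show", "CovarianceEstimate", function(object) {
  cat(sprintf("CovarianceEstimate (%s%s) for %s\n", object@source,
              if (object@nReps > 0) sprintf(", %d reps", object@nReps) else "",
              paste(object@materials, collapse = ", ")))
  cat("  sigma_A:", sprintf("%.4g", sqrt(diag(object@VA))), "\n")
  P <- nrow(object@rhoA)
  for (i in seq_len(P - 1)) for (j in (i + 1):P)
    cat(sprintf("  rho(%s, %s) = %+.3f\n", object@materials[i],
                object@materials[j], object@rhoA[i, j]))
})
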