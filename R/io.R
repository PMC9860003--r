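## Artifact export: TIFF stacks with JSON sidecars, CSV tables, figures.

.writeTiffStack <- function(arr, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    warning("package 'tiff' not available; skipping ", path)
    return(invisible(NULL))
  }
  pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  ## 32-bit float pages; values pass through unscaled (the [0,1]-range
  ## warning only concerns integer storage)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  invisible(path)
}

#' Export a basis image set
#'
#' Writes a multi-page 32-bit float TIFF (one page per material) plus a JSON
#' sidecar with materials, pixel size and provenance.
#'
#' @param images a [BasisImageSet-class].
#' @param prefix output path prefix (writes `<prefix>.tif`, `<prefix>.json`).
#' @return The prefix, invisibly.
#' @export
writeBasisImages <- function(images, prefix) {
  .writeTiffStack(images@images, paste0(prefix, ".tif"))
  jsonlite::write_json(list(materials = images@materials,
                            pixelSizeMm = images@pixelSizeMm,
                            provenance = images@provenance),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(prefix)
}

#' Export a sinogram
#'
#' Multi-page float TIFF (page = material or channel slab) with a JSON
#' geometry sidecar.
#'
#' @param sino a [LineIntegralSinogram-class] or [CountsSinogram-class].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
writeSinogram <- function(sino, prefix) {
  arr <- if (is(sino, "LineIntegralSinogram")) sino@values else sino@counts
  .writeTiffStack(arr, paste0(prefix, ".tif"))
  g <- if (is(sino, "LineIntegralSinogram")) sino@geometry else sino@geometry
  meta <- list(kind = class(sino),
               labels = if (is(sino, "LineIntegralSinogram")) sino@materials
                        else apply(sino@channels@bounds, 1, paste,
                                   collapse = "-"),
               geometry = list(sourceToIsoMm = g@sourceToIsoMm,
                               sourceToDetectorMm = g@sourceToDetectorMm,
                               nCells = g@nCells, cellPitchMm = g@cellPitchMm,
                               nViews = g@nViews))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(prefix)
}

#' Write report tables to a directory
#'
#' Persists every quantitative table of a report (Pearson pairs, ROI noise,
#' analytic covariance entries, CNR) as CSV/JSON so each reported number is
#' traceable to a file.
#'
#' @param report a `pcctReport`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$pearson))
    write.csv(report$pearson, file.path(dir, "pearson.csv"),
              row.names = FALSE)
  if (!is.null(report$roiNoise))
    write.csv(report$roiNoise, file.path(dir, "roi_noise.csv"),
              row.names = FALSE)
  if (!is.null(report$analytic)) {
    tab <- do.call(rbind, lapply(names(report$analytic), function(nm) {
      ce <- report$analytic[[nm]]
      P <- nrow(ce@rhoA)
      do.call(rbind, lapply(seq_len(P - 1), function(i)
        do.call(rbind, lapply((i + 1):P, function(j)
          data.frame(roi = nm, material1 = ce@materials[i],
                     material2 = ce@materials[j],
                     sigma2A1 = ce@VA[i, i], sigma2A2 = ce@VA[j, j],
                     covariance = ce@VA[i, j], rho = ce@rhoA[i, j],
                     delta = ce@delta)))))
    }))
    write.csv(tab, file.path(dir, "analytic_covariance.csv"),
              row.names = FALSE)
  }
  summary <- list(experiment = report$config$experiment,
                  seed = report$config$seed,
                  response = report$config$response,
                  convergenceRate = report$convergenceRate,
                  version = report$version)
  if (!is.null(report$basisNoise)) {
    summary$basisNoise <- as.list(report$basisNoise)
    summary$vmiNoise <- report$vmiNoise
    summary$cnr <- report$cnr
  }
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Render figures for a report
#'
#' Writes the scatterplot data (paired noise pixels per material pair) as
#' CSV and renders PNG scatterplots and noise/CNR bar charts with base
#' graphics. Deterministic: identical reports produce byte-identical CSVs.
#'
#' @param report a `pcctReport` (noise-correlation or head study).
#' @param dir output directory.
#' @return Character vector of files written.
#' @export
makeFigures <- function(report, dir) {
  if (is.null(report$images)) stop("report carries no images")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  px <- report$images@pixelSizeMm
  if (!is.null(report$pearson)) {
    noise <- report$images@images - report$noiselessImages@images
    mats <- report$images@materials
    roiList <- report$rois
    lastRoi <- roiList[[length(roiList)]]
    P <- length(mats)
    for (i in seq_len(P - 1)) for (j in (i + 1):P) {
      x <- roiPixels(noise[, , i], lastRoi, px)
      y <- roiPixels(noise[, , j], lastRoi, px)
      base <- file.path(dir, sprintf("scatter_%s_vs_%s", mats[i], mats[j]))
      write.csv(data.frame(x = x, y = y), paste0(base, ".csv"),
                row.names = FALSE)
      grDevices::png(paste0(base, ".png"), 600, 600)
      plot(x, y, pch = ".", xlab = mats[i], ylab = mats[j],
           main = sprintf("noise correlation R = %.3f",
                          pearsonR(x, y)$R))
      grDevices::dev.off()
      files <- c(files, paste0(base, c(".csv", ".png")))
    }
  }
  if (!is.null(report$basisNoise)) {
    base <- file.path(dir, "noise_bars")
    df <- data.frame(material = names(report$basisNoise),
                     sd = as.numeric(report$basisNoise))
    write.csv(df, paste0(base, ".csv"), row.names = FALSE)
    grDevices::png(paste0(base, ".png"), 600, 400)
    graphics::barplot(df$sd, names.arg = df$material,
                      ylab = "background ROI noise (SD)")
    grDevices::dev.off()
    files <- c(files, paste0(base, c(".csv", ".png")))
  }
  files
}
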