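## Central S4 containers. The energy axis is fixed package-wide: a 1-keV grid
## from 1 to 140 keV (the integration domain of the polychromatic forward
## model), so every per-energy vector below has length 140.

#' The packaged energy grid
#'
#' All spectra, detector responses and attenuation tables in the package live
#' on a common 1-keV energy grid from 1 to 140 keV.
#'
#' @return Integer vector `1:140` (keV).
#' @export
#' @examples
#' range(energyGrid())
energyGrid <- function() 1:140

.NE <- 140L

#' Material with tabulated linear attenuation
#'
#' A named material whose linear attenuation coefficient (per cm) is tabulated
#' on [energyGrid()]. `kEdges` lists the energies (keV, possibly non-integer)
#' of K-shell absorption edges; the lookup in [attenuation()] is edge-aware so
#' the discontinuity sits at the tabulated edge energy, not at a bin boundary.
#'
#' @slot name character identifier.
#' @slot mu numeric(140), linear attenuation per cm on the energy grid.
#' @slot kEdges numeric, K-edge energies in keV (may be empty).
#' @export
setClass("Material",
  representation(name = "character", mu = "numeric", kEdges = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mu) != .NE) msg <- c(msg, "mu must have 140 entries")
    if (any(!is.finite(object@mu)) || any(object@mu <= 0))
      msg <- c(msg, "mu must be finite and positive everywhere")
    ## monotone non-increasing between consecutive K-edges
    if (length(object@mu) == .NE) {
      brk <- sort(unique(c(0, object@kEdges, .NE + 1)))
      E <- energyGrid()
      for (i in seq_len(length(brk) - 1L)) {
        idx <- which(E > brk[i] & E < brk[i + 1L])
        if (length(idx) > 1L && any(diff(object@mu[idx]) > 1e-9))
          msg <- c(msg, "mu must be non-increasing between K-edges")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Mixture of materials by coefficient fraction
#'
#' @slot materials list of [Material-class] objects.
#' @slot fractions numeric weights summing to 1 (within 1e-9).
#' @export
setClass("MixtureSpec",
  representation(materials = "list", fractions = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@materials) != length(object@fractions))
      msg <- c(msg, "materials and fractions must have equal length")
    if (!all(vapply(object@materials, is, logical(1), "Material")))
      msg <- c(msg, "materials must all be Material objects")
    if (any(object@fractions < 0) || any(object@fractions > 1))
      msg <- c(msg, "fractions must lie in [0, 1]")
    if (abs(sum(object@fractions) - 1) > 1e-9)
      msg <- c(msg, "fractions must sum to 1 (within 1e-9)")
    if (length(msg)) msg else TRUE
  })

#' X-ray source spectrum
#'
#' Expected photon fluence per 1-keV energy bin, per detector cell, per view
#' (air scan, no object).
#'
#' @slot fluence numeric(140), photons per bin; zero above the tube endpoint.
#' @slot kVp numeric, tube potential (keV endpoint).
#' @export
setClass("Spectrum",
  representation(fluence = "numeric", kVp = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@fluence) != .NE) msg <- c(msg, "fluence needs 140 bins")
    if (any(object@fluence < 0)) msg <- c(msg, "fluence must be nonnegative")
    if (any(object@fluence[energyGrid() > object@kVp] > 0))
      msg <- c(msg, "fluence must vanish above the kVp endpoint")
    if (length(msg)) msg else TRUE
  })

#' Spectral channel set
#'
#' K contiguous, disjoint energy intervals covering the full grid.
#'
#' @slot bounds integer K x 2 matrix of inclusive [lo, hi] bin bounds in keV.
#' @export
setClass("ChannelSet",
  representation(bounds = "matrix"),
  validity = function(object) {
    b <- object@bounds
    msg <- character()
    if (ncol(b) != 2L) msg <- c(msg, "bounds must be a K x 2 matrix")
    else {
      if (b[1, 1] != 1L || b[nrow(b), 2] != .NE)
        msg <- c(msg, "channels must cover [1, 140] keV")
      if (nrow(b) > 1L && any(b[-1L, 1] != b[-nrow(b), 2] + 1L))
        msg <- c(msg, "channels must be contiguous and ordered")
      if (any(b[, 2] < b[, 1])) msg <- c(msg, "each channel needs lo <= hi")
    }
    if (length(msg)) msg else TRUE
  })

#' Photon-counting detector response model
#'
#' Ideal mode records each photon at its incident energy. Realistic mode
#' distorts the recorded energy with a parameterized CZT-like kernel
#' (Gaussian photopeak, K-escape satellite, flat low-energy tail) and lets a
#' photon split into two recorded counts (charge sharing) with probability
#' `sharingFraction` -- the mechanism that induces positive interchannel
#' count correlation.
#'
#' @slot mode "ideal" or "realistic".
#' @slot efficiency numeric(140) detection efficiency in [0, 1].
#' @slot kernel 140 x 140 matrix; column j is the recorded-energy distribution
#'   for incident energy j keV (columns sum to <= 1).
#' @slot sharingFraction probability a photon yields two recorded counts.
#' @slot uRange support of the charge-sharing energy split fraction.
#' @export
setClass("DetectorResponse",
  representation(mode = "character", efficiency = "numeric",
                 kernel = "matrix", sharingFraction = "numeric",
                 uRange = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("ideal", "realistic"))
      msg <- c(msg, "mode must be 'ideal' or 'realistic'")
    if (length(object@efficiency) != .NE ||
        any(object@efficiency < 0) || any(object@efficiency > 1))
      msg <- c(msg, "efficiency must be 140 values in [0, 1]")
    if (!all(dim(object@kernel) == c(.NE, .NE)))
      msg <- c(msg, "kernel must be 140 x 140")
    else if (any(colSums(object@kernel) > 1 + 1e-8))
      msg <- c(msg, "kernel columns must sum to <= 1")
    if (object@mode == "ideal") {
      if (object@sharingFraction != 0)
        msg <- c(msg, "ideal mode requires sharingFraction = 0")
      if (any(abs(object@kernel - diag(.NE)) > 1e-12))
        msg <- c(msg, "ideal mode requires an identity kernel")
    }
    if (object@sharingFraction < 0 || object@sharingFraction > 1)
      msg <- c(msg, "sharingFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Equiangular fan-beam acquisition geometry
#'
#' Single-row curved detector, full 360 degree scan. Distances in mm.
#'
#' @slot sourceToIsoMm source-to-isocenter distance.
#' @slot sourceToDetectorMm source-to-detector distance.
#' @slot nCells number of detector cells (single row).
#' @slot cellPitchMm detector cell pitch (arc length at the detector).
#' @slot nViews views per 360 degree rotation.
#' @export
setClass("Geometry",
  representation(sourceToIsoMm = "numeric", sourceToDetectorMm = "numeric",
                 nCells = "integer", cellPitchMm = "numeric",
                 nViews = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@sourceToDetectorMm <= object@sourceToIsoMm)
      msg <- c(msg, "sourceToDetector must exceed sourceToIso")
    if (object@nCells < 2L || object@nViews < 2L)
      msg <- c(msg, "need at least 2 cells and 2 views")
    if (object@cellPitchMm <= 0) msg <- c(msg, "cellPitchMm must be positive")
    if (length(msg)) msg else TRUE
  })

#' Circular region of interest
#'
#' @slot centerMm (x, y) center in isocenter coordinates, mm.
#' @slot diameterMm diameter, mm.
#' @slot label optional label.
#' @export
setClass("ROI",
  representation(centerMm = "numeric", diameterMm = "numeric",
                 label = "character"),
  validity = function(object) {
    if (length(object@centerMm) != 2L) return("centerMm must be length 2")
    if (object@diameterMm <= 0) return("diameterMm must be positive")
    TRUE
  })

#' Digital phantom as per-material coefficient maps
#'
#' An N x N x M array of basis-coefficient maps: voxel attenuation is
#' `sum_m coeffs[,,m] * mu_m(E)` over the listed materials. The material list
#' may include non-basis materials (e.g. the water background of the
#' noise-correlation phantom); decomposition later uses only its own basis.
#'
#' @slot coeffs numeric array N x N x M, dimensionless coefficients >= 0.
#' @slot materials character(M) material names matching `dim(coeffs)[3]`.
#' @slot pixelSizeMm pixel size in mm.
#' @export
setClass("PhantomImage",
  representation(coeffs = "array", materials = "character",
                 pixelSizeMm = "numeric"),
  validity = function(object) {
    d <- dim(object@coeffs)
    msg <- character()
    if (length(d) != 3L || d[1] != d[2])
      msg <- c(msg, "coeffs must be a square N x N x M array")
    else if (d[3] != length(object@materials))
      msg <- c(msg, "materials must match the third array dimension")
    if (any(object@coeffs < 0)) msg <- c(msg, "coefficients must be >= 0")
    if (object@pixelSizeMm <= 0) msg <- c(msg, "pixelSizeMm must be positive")
    if (length(msg)) msg else TRUE
  })

#' Per-material line-integral sinogram
#'
#' `values[v, c, p]` is the line integral A_p (in cm) of basis-coefficient map
#' p along the ray of view v and detector cell c.
#'
#' @slot values numeric array nViews x nCells x P (cm).
#' @slot materials character(P).
#' @slot geometry the [Geometry-class] used.
#' @slot converged logical nViews x nCells matrix (TRUE everywhere for exact
#'   forward projections; solver flags for decomposed sinograms).
#' @export
setClass("LineIntegralSinogram",
  representation(values = "array", materials = "character",
                 geometry = "Geometry", converged = "matrix"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be nViews x nCells x P")
    if (d[3] != length(object@materials))
      return("materials must match third dimension")
    if (d[1] != object@geometry@nViews || d[2] != object@geometry@nCells)
      return("values must match geometry (nViews x nCells)")
    TRUE
  })

#' Per-channel counts sinogram
#'
#' Either expected (real-valued) or sampled (integer-valued Poisson) counts
#' per view, cell and spectral channel, together with the air-scan channel
#' counts. For a realistic detector response the independent-component means
#' used by the exact sharing sampler are carried along in `components`.
#'
#' @slot counts numeric array nViews x nCells x K.
#' @slot airCounts numeric(K) expected air-scan counts per channel.
#' @slot channels the [ChannelSet-class].
#' @slot geometry the [Geometry-class].
#' @slot expected TRUE for noiseless expected counts, FALSE for samples.
#' @slot components list of component means for the sharing sampler (internal).
#' @export
setClass("CountsSinogram",
  representation(counts = "array", airCounts = "numeric",
                 channels = "ChannelSet", geometry = "Geometry",
                 expected = "logical", components = "list"),
  validity = function(object) {
    d <- dim(object@counts)
    if (length(d) != 3L) return("counts must be nViews x nCells x K")
    if (d[3] != nrow(object@channels@bounds))
      return("counts must match the channel count")
    if (any(object@counts < 0)) return("counts must be nonnegative")
    TRUE
  })

#' Reconstructed basis-image set
#'
#' One 2-D image per basis material on a common grid, with provenance.
#'
#' @slot images numeric array N x N x P.
#' @slot materials character(P).
#' @slot pixelSizeMm pixel size in mm.
#' @slot provenance named list (mode, response, seed, ...).
#' @export
setClass("BasisImageSet",
  representation(images = "array", materials = "character",
                 pixelSizeMm = "numeric", provenance = "list"),
  validity = function(object) {
    d <- dim(object@images)
    if (length(d) != 3L || d[1] != d[2])
      return("images must be a square N x N x P array")
    if (d[3] != length(object@materials))
      return("materials must match third dimension")
    TRUE
  })

#' Polynomial calibration model for decomposition initial values
#'
#' Maps the per-channel log attenuation vector l_k = -ln(I_k / air_k) to an
#' initial estimate of each basis line integral A_p through a full polynomial
#' (all cross terms) of the given total degree, least-squares fitted on
#' noiseless forward projections of a tensor grid in A-space.
#'
#' @slot coefs numeric terms x P coefficient matrix.
#' @slot powers integer terms x K exponent matrix (rows are monomials).
#' @slot degree polynomial total degree.
#' @slot rangeA P x 2 matrix of the calibration span per material (cm).
#' @slot maxResidual worst absolute fit residual on the grid (cm).
#' @export
setClass("CalibrationModel",
  representation(coefs = "matrix", powers = "matrix", degree = "integer",
                 rangeA = "matrix", maxResidual = "numeric"))

#' Operating point for noise propagation
#'
#' The local first- and second-moment description of the channel counts at a
#' given basis line-integral vector A: expected counts, their covariance,
#' per-channel SNR and interchannel correlation.
#'
#' @slot A numeric(P) line integrals (cm).
#' @slot Ibar numeric(K) expected channel counts.
#' @slot VI K x K count covariance.
#' @slot snr numeric(K) Ibar / sd.
#' @slot rhoI K x K count correlation matrix.
#' @export
setClass("OperatingPoint",
  representation(A = "numeric", Ibar = "numeric", VI = "matrix",
                 snr = "numeric", rhoI = "matrix"),
  validity = function(object) {
    K <- length(object@Ibar)
    if (!all(dim(object@VI) == K)) return("VI must be K x K")
    if (max(abs(object@VI - t(object@VI))) > 1e-8 * max(abs(object@VI), 1))
      return("VI must be symmetric")
    TRUE
  })

#' Covariance of basis line integrals
#'
#' The A-space covariance produced either by analytic propagation through the
#' inverse Jacobian of the spectral forward map, or by Monte Carlo repetition
#' of the full sample-and-decompose chain for a single ray.
#'
#' @slot VA P x P covariance matrix of the A estimates (cm^2).
#' @slot rhoA P x P correlation matrix.
#' @slot delta determinant of the effective attenuation coefficient matrix
#'   (per cm^P); NA for Monte Carlo estimates.
#' @slot materials character(P).
#' @slot source "analytic" or "monte-carlo".
#' @slot nReps repetitions used (0 for analytic).
#' @export
setClass("CovarianceEstimate",
  representation(VA = "matrix", rhoA = "matrix", delta = "numeric",
                 materials = "character", source = "character",
                 nReps = "integer"),
  validity = function(object) {
    P <- nrow(object@VA)
    msg <- character()
    if (!all(dim(object@rhoA) == P)) msg <- c(msg, "rhoA must be P x P")
    if (max(abs(object@VA - t(object@VA))) > 1e-6 * max(abs(object@VA)))
      msg <- c(msg, "VA must be symmetric")
    if (any(abs(object@rhoA) > 1 + 1e-8))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })
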