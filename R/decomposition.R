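## Projection-domain material decomposition: polynomial calibration for
## initial values and a damped, vectorized Newton-Raphson inversion of the
## polychromatic forward map (square systems, K channels = P materials).

.polyPowers <- function(K, degree) {
  g <- do.call(expand.grid, rep(list(0:degree), K))
  g <- as.matrix(g[rowSums(g) <= degree, , drop = FALSE])
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g[order(rowSums(g)), , drop = FALSE]
}

.designMatrix <- function(L, powers) {
  X <- matrix(1, nrow(L), nrow(powers))
  for (j in seq_len(nrow(powers)))
    for (k in seq_len(ncol(powers)))
      if (powers[j, k] > 0) X[, j] <- X[, j] * L[, k]^powers[j, k]
  X
}

#' Calibrate the polynomial initializer
#'
#' Least-squares fit of a full polynomial (all cross terms, total degree
#' `degree`) mapping the per-channel log attenuation vector
#' l_k = -ln(I_k / air_k) to each basis line integral A_p, on noiseless
#' forward projections of a tensor grid in A-space.
#'
#' @param spectrum a [Spectrum-class].
#' @param channels a [ChannelSet-class]; `nChannels` must equal the basis size.
#' @param response a [DetectorResponse-class].
#' @param basis list of basis materials (or names).
#' @param rangeA P x 2 matrix of per-material calibration spans in cm
#'   (default `[0, 24]` cm each).
#' @param nPoints grid points per material (default 6).
#' @param degree polynomial total degree (default 3).
#' @return A [CalibrationModel-class]; its `maxResidual` slot reports the
#'   worst absolute grid residual in cm.
#' @export
calibrate <- function(spectrum, channels, response, basis, rangeA = NULL,
                      nPoints = 6, degree = 3) {
  basis <- lapply(basis, getMaterial)
  P <- length(basis); K <- nChannels(channels)
  if (K != P) stop("square system required: channels (", K,
                   ") must equal basis materials (", P, ")")
  if (is.null(rangeA)) rangeA <- cbind(rep(0, P), rep(24, P))
  rangeA <- matrix(rangeA, P, 2)
  muMat <- .muMatrix(basis)
  grid <- do.call(expand.grid, lapply(seq_len(P), function(p)
    seq(rangeA[p, 1], rangeA[p, 2], length.out = nPoints)))
  Agrid <- as.matrix(grid); dimnames(Agrid) <- NULL
  cw <- .channelWeights(channels, response)
  I <- .forwardMeans(Agrid, muMat, spectrum, cw)$I
  air <- airScanCounts(spectrum, channels, response)
  L <- -log(sweep(I, 2, air, "/"))
  powers <- .polyPowers(K, as.integer(degree))
  X <- .designMatrix(L, powers)
  fit <- lm.fit(X, Agrid)
  coefs <- matrix(fit$coefficients, ncol = P)
  coefs[is.na(coefs)] <- 0
  if (fit$rank < ncol(X) / 2)
    stop("rank-deficient calibration design; basis materials ",
         paste(vapply(basis, materialName, character(1)), collapse = "/"),
         " may be spectrally degenerate")
  resid <- X %*% coefs - Agrid
  new("CalibrationModel", coefs = coefs, powers = powers,
      degree = as.integer(degree), rangeA = rangeA,
      maxResidual = max(abs(resid)))
}

#' Evaluate the calibration model
#'
#' @param model a [CalibrationModel-class].
#' @param counts rays x K count matrix (or vector for one ray).
#' @param airCounts numeric(K) air-scan counts.
#' @return rays x P matrix of initial A estimates (cm).
#' @export
predictCalibration <- function(model, counts, airCounts) {
  counts <- rbind(counts)[, , drop = FALSE]
  L <- -log(sweep(pmax(counts, 0.5), 2, airCounts, "/"))
  .designMatrix(L, model@powers) %*% model@coefs
}

## Batched linear solve M x = r for rays of K x K systems (K <= 4), Cramer.
.batchSolve <- function(M, r) {
  K <- dim(M)[2]
  if (K == 1L) return(r / M[, 1, 1, drop = FALSE])
  if (K == 2L) {
    det <- M[, 1, 1] * M[, 2, 2] - M[, 1, 2] * M[, 2, 1]
    return(cbind((r[, 1] * M[, 2, 2] - r[, 2] * M[, 1, 2]) / det,
                 (M[, 1, 1] * r[, 2] - M[, 2, 1] * r[, 1]) / det))
  }
  det3 <- function(a11, a12, a13, a21, a22, a23, a31, a32, a33)
    a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
      a13 * (a21 * a32 - a22 * a31)
  if (K == 3L) {
    d <- det3(M[, 1, 1], M[, 1, 2], M[, 1, 3], M[, 2, 1], M[, 2, 2],
              M[, 2, 3], M[, 3, 1], M[, 3, 2], M[, 3, 3])
    x1 <- det3(r[, 1], M[, 1, 2], M[, 1, 3], r[, 2], M[, 2, 2], M[, 2, 3],
               r[, 3], M[, 3, 2], M[, 3, 3]) / d
    x2 <- det3(M[, 1, 1], r[, 1], M[, 1, 3], M[, 2, 1], r[, 2], M[, 2, 3],
               M[, 3, 1], r[, 3], M[, 3, 3]) / d
    x3 <- det3(M[, 1, 1], M[, 1, 2], r[, 1], M[, 2, 1], M[, 2, 2], r[, 2],
               M[, 3, 1], M[, 3, 2], r[, 3]) / d
    return(cbind(x1, x2, x3))
  }
  if (K == 4L) {
    det4 <- function(A) {    # A: list of 16 column vectors, row-major
      m <- function(i, j) A[[(i - 1) * 4 + j]]
      m(1, 1) * det3(m(2, 2), m(2, 3), m(2, 4), m(3, 2), m(3, 3), m(3, 4),
                     m(4, 2), m(4, 3), m(4, 4)) -
      m(1, 2) * det3(m(2, 1), m(2, 3), m(2, 4), m(3, 1), m(3, 3), m(3, 4),
                     m(4, 1), m(4, 3), m(4, 4)) +
      m(1, 3) * det3(m(2, 1), m(2, 2), m(2, 4), m(3, 1), m(3, 2), m(3, 4),
                     m(4, 1), m(4, 2), m(4, 4)) -
      m(1, 4) * det3(m(2, 1), m(2, 2), m(2, 3), m(3, 1), m(3, 2), m(3, 3),
                     m(4, 1), m(4, 2), m(4, 3))
    }
    cols <- function(repl = 0L) {
      A <- vector("list", 16L)
      for (i in 1:4) for (j in 1:4)
        A[[(i - 1) * 4 + j]] <- if (j == repl) r[, i] else M[, i, j]
      A
    }
    d <- det4(cols(0L))
    return(do.call(cbind, lapply(1:4, function(j) det4(cols(j)) / d)))
  }
  stop("batched solve supports up to 4 channels")
}

## Vectorized damped Newton-Raphson on r = ln(Ibar) - ln(counts).
##
## The step is the Newton step of the square system (equivalently the
## Gauss-Newton step of min ||r||^2), backtracked until the residual norm
## decreases, so the iteration converges to the exact root when one exists
## and to the least-squares best fit otherwise. Rays are flagged converged
## only when the root criterion max |r| < tol is met; rays that stall at a
## nonzero residual floor (no root: heavy noise can push the counts outside
## the range of the forward map in ill-conditioned bases) keep their
## best-fit iterate and stay flagged.
.newtonSolve <- function(counts, muMat, spectrum, cw, A0,
                         tol = 1e-6, maxIter = 50L, clampA = -1) {
  K <- ncol(counts)
  A <- A0
  n <- nrow(A)
  converged <- rep(FALSE, n)
  stalled <- rep(FALSE, n)
  lc <- log(counts)
  r <- log(.forwardMeans(A, muMat, spectrum, cw)$I) - lc
  for (it in seq_len(maxIter)) {
    rmax <- apply(abs(r), 1, max)
    converged <- converged | rmax <= tol
    active <- which(!converged & !stalled)
    if (!length(active)) break
    sub <- .forwardMeans(A[active, , drop = FALSE], muMat, spectrum, cw,
                         withMu = TRUE)
    delta <- .batchSolve(sub$mu, r[active, , drop = FALSE])
    delta[!is.finite(delta)] <- 0
    rOld2 <- rowSums(r[active, , drop = FALSE]^2)
    lam <- rep(1, length(active))
    ok <- rep(FALSE, length(active))
    Anew <- A[active, , drop = FALSE]
    rNew <- r[active, , drop = FALSE]
    for (half in 0:10) {
      todo <- which(!ok)
      if (!length(todo)) break
      Atry <- A[active[todo], , drop = FALSE] +
        lam[todo] * delta[todo, , drop = FALSE]
      Atry[Atry < clampA] <- clampA
      rTry <- log(.forwardMeans(Atry, muMat, spectrum, cw)$I) -
        lc[active[todo], , drop = FALSE]
      better <- rowSums(rTry^2) <= rOld2[todo] * (1 - 1e-10)
      acc <- todo[better]
      Anew[acc, ] <- Atry[better, , drop = FALSE]
      rNew[acc, ] <- rTry[better, , drop = FALSE]
      ok[acc] <- TRUE
      lam[todo[!better]] <- lam[todo[!better]] / 2
    }
    ## rays where no backtracked step decreases ||r|| sit at a local
    ## least-squares minimum: freeze them at the best iterate
    stalled[active[!ok]] <- TRUE
    ## rays whose accepted step is negligible have also stalled
    stepSz <- sqrt(rowSums((Anew - A[active, , drop = FALSE])^2))
    tiny <- ok & stepSz < 1e-9 * (1 + sqrt(rowSums(Anew^2)))
    stalled[active[tiny]] <- TRUE
    A[active, ] <- Anew
    r[active, ] <- rNew
  }
  converged <- converged | apply(abs(r), 1, max) <= tol
  list(A = A, converged = converged)
}

#' Newton-Raphson decomposition of channel counts
#'
#' Solves the polychromatic system Ibar_k(A) = counts_k for the basis line
#' integrals A by damped Newton iteration on the log-count residual
#' r_k = ln Ibar_k - ln counts_k, whose Jacobian is minus the effective
#' attenuation coefficient matrix (computed analytically from the spectral
#' integral). Converged when max |r| < `tol` or after `maxIter` iterations;
#' non-converged rays are flagged and return their last iterate. Zero counts
#' are clamped to 0.5 before taking logs.
#'
#' @param counts numeric vector (one ray) or rays x K matrix of channel
#'   counts, > 0 after clamping.
#' @param spectrum,channels,response the forward model
#'   ([Spectrum-class], [ChannelSet-class], [DetectorResponse-class]).
#' @param basis list of P = K basis materials.
#' @param init optional [CalibrationModel-class] (fit on the fly if NULL) or
#'   a rays x P matrix of starting values.
#' @param tol convergence tolerance on max |r| (default 1e-6).
#' @param maxIter iteration cap (default 50).
#' @return List with `A` (rays x P, cm) and logical `converged` per ray.
#' @export
newtonRaphsonMD <- function(counts, spectrum, channels, response, basis,
                            init = NULL, tol = 1e-6, maxIter = 50L) {
  basis <- lapply(basis, getMaterial)
  counts <- rbind(counts)[, , drop = FALSE]
  K <- nChannels(channels)
  if (ncol(counts) != K) stop("counts must have K columns")
  if (length(basis) != K) stop("square system required (K = P)")
  counts <- pmax(counts, 0.5)
  muMat <- .muMatrix(basis)
  cw <- .channelWeights(channels, response)
  air <- airScanCounts(spectrum, channels, response)
  if (is.null(init))
    init <- calibrate(spectrum, channels, response, basis)
  A0 <- if (is(init, "CalibrationModel"))
    predictCalibration(init, counts, air)
  else matrix(init, nrow(counts), K)
  .newtonSolve(counts, muMat, spectrum, cw, A0, tol = tol,
               maxIter = as.integer(maxIter))
}

#' Decompose a counts sinogram into basis line integrals
#'
#' Applies [newtonRaphsonMD()] to every (view, cell) ray of a counts
#' sinogram, initialized by the polynomial calibration model.
#'
#' @param counts a [CountsSinogram-class].
#' @param spectrum,response forward-model components (channels are taken from
#'   the sinogram).
#' @param basis list of P = K basis materials.
#' @param calibration optional [CalibrationModel-class]; fit on the fly with
#'   default spans if missing.
#' @param tol,maxIter passed to the solver.
#' @return A [LineIntegralSinogram-class] of estimated A values; rays that
#'   did not converge are flagged in its `converged` slot.
#' @export
decomposeSinogram <- function(counts, spectrum, response, basis,
                              calibration = NULL, tol = 1e-6, maxIter = 50L) {
  basis <- lapply(basis, getMaterial)
  channels <- counts@channels
  K <- nChannels(channels)
  if (length(basis) != K)
    stop("square system required: ", K, " channels vs ", length(basis),
         " basis materials")
  geom <- counts@geometry
  nRays <- geom@nViews * geom@nCells
  cmat <- matrix(counts@counts, nRays, K)
  if (is.null(calibration))
    calibration <- calibrate(spectrum, channels, response, basis)
  res <- newtonRaphsonMD(cmat, spectrum, channels, response, basis,
                         init = calibration, tol = tol, maxIter = maxIter)
  vals <- array(res$A, c(geom@nViews, geom@nCells, K))
  dimnames(vals) <- list(NULL, NULL,
                         vapply(basis, materialName, character(1)))
  new("LineIntegralSinogram", values = vals,
      materials = vapply(basis, materialName, character(1)),
      geometry = geom,
      converged = matrix(res$converged, geom@nViews, geom@nCells))
}
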