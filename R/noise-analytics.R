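## Analytic propagation of count-domain noise into A-space via the inverse
## Jacobian of the spectral forward map, closed two-material forms, the
## correlation-vanishing degenerate case, and a Monte Carlo oracle.

#' Analytic count covariance at a line-integral operating point
#'
#' For an ideal response the channels are independent Poisson, so V_I is
#' diagonal with the expected counts. For a sharing response the recorded
#' counts decompose into independent Poisson components (non-shared counts
#' per channel plus one component per ordered fragment channel pair that
#' feeds both its channels), giving the exact covariance
#' `V[k1, k2] = delta * Ins_k + sum_pairs m_pair c_k1 c_k2` with c_k the
#' number of fragments the pair sends into channel k.
#'
#' @param A numeric(P) basis line integrals (cm).
#' @param spectrum,channels,response the forward model.
#' @param basis list of P basis materials.
#' @return An [OperatingPoint-class] (expected counts, V_I, SNR, rho_I).
#' @export
operatingPoint <- function(A, spectrum, channels, response, basis) {
  basis <- lapply(basis, getMaterial)
  muMat <- .muMatrix(basis)
  cw <- .channelWeights(channels, response)
  K <- nChannels(channels)
  fm <- .forwardMeans(rbind(A), muMat, spectrum, cw)
  Ibar <- as.numeric(fm$I)
  if (any(Ibar <= 0)) stop("zero expected count at this operating point")
  if (is.null(fm$ns)) {
    VI <- diag(Ibar, K)
  } else {
    VI <- diag(as.numeric(fm$ns), K)
    k1 <- rep(seq_len(K), times = K)
    k2 <- rep(seq_len(K), each = K)
    for (j in seq_len(K * K)) {
      cvec <- tabulate(c(k1[j], k2[j]), nbins = K)
      VI <- VI + fm$pair[1, j] * tcrossprod(cvec)
    }
  }
  sdI <- sqrt(diag(VI))
  new("OperatingPoint", A = as.numeric(A), Ibar = Ibar, VI = VI,
      snr = Ibar / sdI, rhoI = VI / tcrossprod(sdI))
}

#' Effective attenuation coefficient matrix
#'
#' The polychromatic analog of the basis attenuation coefficients for each
#' spectral channel: `mu_kp = -(1 / Ibar_k) dIbar_k / dA_p`, evaluated
#' analytically as the fluence-weighted mean of `mu_p(E)` over the channel's
#' detected spectrum at the operating point. Beam hardening makes every
#' entry shrink as the paths A grow.
#'
#' @param A numeric(P) basis line integrals (cm).
#' @param spectrum,channels,response the forward model.
#' @param basis list of P basis materials.
#' @return K x P matrix (per cm), rows = channels, columns = materials.
#' @export
effectiveMu <- function(A, spectrum, channels, response, basis) {
  basis <- lapply(basis, getMaterial)
  muMat <- .muMatrix(basis)
  cw <- .channelWeights(channels, response)
  fm <- .forwardMeans(rbind(A), muMat, spectrum, cw, withMu = TRUE)
  if (any(fm$I <= 0)) stop("zero expected count at this operating point")
  mu <- matrix(fm$mu[1, , ], nChannels(channels), length(basis))
  colnames(mu) <- vapply(basis, materialName, character(1))
  mu
}

#' Propagate count covariance into A-space
#'
#' First-order (Jacobian) propagation through the inverse of the forward
#' map: `V[A] = F^-1 V[I] F^-T` with `F_kp = dIbar_k / dA_p = -Ibar_k
#' mu_kp`. Returns the covariance, the correlation matrix, and the
#' determinant of the effective attenuation matrix (whose square divides
#' every covariance entry in the closed forms).
#'
#' @param mu K x P effective attenuation matrix (see [effectiveMu()]).
#' @param op an [OperatingPoint-class].
#' @param materials optional material names for labeling.
#' @return A [CovarianceEstimate-class] with `source = "analytic"`.
#' @export
propagateCovariance <- function(mu, op, materials = colnames(mu)) {
  K <- length(op@Ibar); P <- ncol(mu)
  if (K != P) stop("square system required (K = P)")
  Fmat <- -op@Ibar * mu                       # row-scaled: F_kp = -Ibar_k mu_kp
  delta <- det(mu)
  if (abs(det(Fmat)) < .Machine$double.eps * max(abs(Fmat))^K) {
    cn <- colnames(mu)
    stop("singular Jacobian: basis materials ",
         paste(cn, collapse = "/"), " have proportional attenuation")
  }
  Finv <- solve(Fmat)
  VA <- Finv %*% op@VI %*% t(Finv)
  VA <- (VA + t(VA)) / 2
  sdA <- sqrt(diag(VA))
  rhoA <- VA / tcrossprod(sdA)
  if (is.null(materials)) materials <- paste0("m", seq_len(P))
  new("CovarianceEstimate", VA = VA, rhoA = rhoA, delta = delta,
      materials = materials, source = "analytic", nReps = 0L)
}

#' Closed-form two-material noise propagation
#'
#' The literal closed forms for the variances, covariance and correlation of
#' the two basis line integrals in terms of the four effective attenuation
#' coefficients, the per-channel SNRs and the interchannel count correlation
#' rho_I12; with `rhoI12 = 0` they reduce to the classic
#' correlation-vanishing (Alvarez-Macovski) expressions.
#'
#' @param mu11,mu12,mu21,mu22 effective attenuation coefficients (channel,
#'   material), per cm.
#' @param snr1,snr2 per-channel count SNRs, > 0.
#' @param rhoI12 interchannel count correlation in [-1, 1].
#' @return List with `sigma2A1`, `sigma2A2`, `sigmaA1A2`, `rhoA1A2`, `delta`
#'   (the 2 x 2 determinant mu11 mu22 - mu21 mu12).
#' @export
#' @examples
#' closedForm2MD(0.3, 0.25, 0.2, 0.18, 100, 120, 0)
closedForm2MD <- function(mu11, mu12, mu21, mu22, snr1, snr2, rhoI12 = 0) {
  if (any(snr1 <= 0) || any(snr2 <= 0)) stop("SNRs must be positive")
  if (any(abs(rhoI12) > 1)) stop("|rhoI12| must be <= 1")
  delta <- mu11 * mu22 - mu21 * mu12
  if (any(delta == 0)) stop("degenerate basis: zero determinant")
  s2A1 <- (mu22^2 / snr1^2 + mu12^2 / snr2^2 -
             2 * rhoI12 * (mu22 / snr1) * (mu12 / snr2)) / delta^2
  s2A2 <- (mu21^2 / snr1^2 + mu11^2 / snr2^2 -
             2 * rhoI12 * (mu11 / snr2) * (mu21 / snr1)) / delta^2
  sA12 <- -(mu21 * mu22 / snr1^2 + mu12 * mu11 / snr2^2 -
              rhoI12 * ((mu11 / snr2) * (mu22 / snr1) +
                        (mu12 / snr2) * (mu21 / snr1))) / delta^2
  rho <- sA12 / sqrt(s2A1 * s2A2)
  list(sigma2A1 = s2A1, sigma2A2 = s2A2, sigmaA1A2 = sA12,
       rhoA1A2 = rho, delta = delta)
}

#' Determinant of a 3 x 3 effective attenuation matrix
#'
#' Explicit six-term expansion of the three-material Jacobian determinant.
#'
#' @param mu 3 x 3 matrix.
#' @return The determinant.
#' @export
jacobian3MD <- function(mu) {
  if (!all(dim(mu) == c(3L, 3L))) stop("mu must be 3 x 3")
  mu[1, 1] * mu[2, 2] * mu[3, 3] + mu[1, 2] * mu[2, 3] * mu[3, 1] +
    mu[1, 3] * mu[2, 1] * mu[3, 2] - mu[3, 1] * mu[2, 2] * mu[1, 3] -
    mu[3, 2] * mu[2, 3] * mu[1, 1] - mu[1, 2] * mu[2, 1] * mu[3, 3]
}

#' Monte Carlo covariance of decomposed line integrals
#'
#' Repeats the sample-and-decompose chain for a single ray: draws channel
#' counts at the operating point `nReps` times, runs the Newton-Raphson
#' decomposition on every draw, and returns the sample covariance and
#' correlation of the estimates. Errors if more than 5 percent of the
#' repetitions fail to converge.
#'
#' @param A numeric(P) true basis line integrals (cm).
#' @param spectrum,channels,response the forward model.
#' @param basis list of P basis materials.
#' @param nReps repetitions, >= 100.
#' @param seed RNG seed.
#' @param calibration optional [CalibrationModel-class] reused across draws.
#' @return A [CovarianceEstimate-class] with `source = "monte-carlo"`.
#' @export
monteCarloCovariance <- function(A, spectrum, channels, response, basis,
                                 nReps = 5000, seed = 1,
                                 calibration = NULL) {
  if (nReps < 100) stop("nReps must be >= 100")
  basis <- lapply(basis, getMaterial)
  muMat <- .muMatrix(basis)
  cw <- .channelWeights(channels, response)
  K <- nChannels(channels)
  fm1 <- .forwardMeans(rbind(A), muMat, spectrum, cw)
  fm <- list(I = matrix(fm1$I, nReps, K, byrow = TRUE))
  if (!is.null(fm1$ns)) {
    fm$ns <- matrix(fm1$ns, nReps, K, byrow = TRUE)
    fm$pair <- matrix(fm1$pair, nReps, K * K, byrow = TRUE)
  }
  set.seed(as.integer(seed))
  cnt <- .sampleCountsMatrix(fm, response, K)
  if (is.null(calibration))
    calibration <- calibrate(spectrum, channels, response, basis)
  res <- newtonRaphsonMD(cnt, spectrum, channels, response, basis,
                         init = calibration)
  if (mean(!res$converged) > 0.05)
    stop("more than 5% of Monte Carlo repetitions failed to converge")
  Ahat <- res$A[res$converged, , drop = FALSE]
  VA <- stats::cov(Ahat)
  sdA <- sqrt(diag(VA))
  new("CovarianceEstimate", VA = VA, rhoA = VA / tcrossprod(sdA),
      delta = NA_real_,
      materials = vapply(basis, materialName, character(1)),
      source = "monte-carlo", nReps = as.integer(nReps))
}
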