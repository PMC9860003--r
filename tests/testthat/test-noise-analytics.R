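test_that("effective attenuation matches the monochromatic and FD oracles", {
  mono <- new("Spectrum", fluence = c(rep(0, 59), 1e5, rep(0, 80)), kVp = 140)
  ch1 <- channelSet(cbind(1, 140)); resp <- idealResp()
  em <- effectiveMu(2, mono, ch1, resp, list("water"))
  expect_equal(em[1, 1], attenuation("water", 60), ignore_attr = TRUE)
  ## central finite difference of ln Ibar vs the analytic entries
  s <- tstSpectrum(); ch <- channelPreset(2)
  basis <- list("soft_tissue", "cortical_bone")
  A0 <- c(9, 1.5)
  em2 <- effectiveMu(A0, s, ch, resp, basis)
  cw <- pcctmd:::.channelWeights(ch, resp)
  mm <- pcctmd:::.muMatrix(basis)
  h <- 1e-5
  for (p in 1:2) {
    Ap <- A0; Am <- A0
    Ap[p] <- Ap[p] + h; Am[p] <- Am[p] - h
    fd <- -(log(pcctmd:::.forwardMeans(rbind(Ap), mm, s, cw)$I) -
              log(pcctmd:::.forwardMeans(rbind(Am), mm, s, cw)$I)) / (2 * h)
    expect_equal(as.vector(fd), em2[, p], tolerance = 1e-6)
  }
  ## beam hardening: entries shrink along a longer path
  emLong <- effectiveMu(c(18, 3), s, ch, resp, basis)
  expect_true(all(emLong < em2))
})

test_that("covariance propagation matches identity and closed-form oracles", {
  opId <- new("OperatingPoint", A = c(0, 0), Ibar = c(1, 1),
              VI = diag(2), snr = c(1, 1), rhoI = diag(2))
  ce <- propagateCovariance(-diag(2), opId, materials = c("a", "b"))
  expect_equal(ce@VA, diag(2))
  ## closed 2-material forms == matrix route, term by term
  set.seed(1)
  for (i in 1:50) {
    mu <- matrix(runif(4, 0.05, 1.5), 2, 2)
    mu <- mu + diag(2)                      # keep it well away from singular
    snr <- runif(2, 5, 300)
    rho <- runif(1, -0.8, 0.8)
    Ibar <- runif(2, 1e3, 1e5)
    sdI <- Ibar / snr
    VI <- diag(sdI^2); VI[1, 2] <- VI[2, 1] <- rho * sdI[1] * sdI[2]
    op <- new("OperatingPoint", A = c(1, 1), Ibar = Ibar, VI = VI,
              snr = snr, rhoI = matrix(c(1, rho, rho, 1), 2))
    cf <- closedForm2MD(mu[1, 1], mu[1, 2], mu[2, 1], mu[2, 2],
                        snr[1], snr[2], rho)
    ce <- propagateCovariance(mu, op, materials = c("a", "b"))
    expect_equal(cf$sigma2A1, ce@VA[1, 1], tolerance = 1e-10)
    expect_equal(cf$sigma2A2, ce@VA[2, 2], tolerance = 1e-10)
    expect_equal(cf$sigmaA1A2, ce@VA[1, 2], tolerance = 1e-10)
    expect_equal(cf$rhoA1A2, ce@rhoA[1, 2], tolerance = 1e-10)
    expect_equal(cf$delta, ce@delta, tolerance = 1e-12)
  }
})

test_that("symmetric two-channel systems give equal variances", {
  cf <- closedForm2MD(0.8, 0.3, 0.3, 0.8, 120, 120, 0)
  expect_equal(cf$sigma2A1, cf$sigma2A2)
  expect_lt(cf$rhoA1A2, 0)
})

test_that("correlation-vanishing case is always negative for positive mu", {
  set.seed(2)
  for (i in 1:200) {
    mu <- matrix(runif(4, 0.05, 2), 2, 2)
    if (abs(mu[1, 1] * mu[2, 2] - mu[1, 2] * mu[2, 1]) < 1e-3) next
    cf <- closedForm2MD(mu[1, 1], mu[1, 2], mu[2, 1], mu[2, 2],
                        runif(1, 2, 500), runif(1, 2, 500), 0)
    expect_lt(cf$rhoA1A2, 0)
  }
  expect_error(closedForm2MD(1, 1, 1, 1, 10, 10, 0), "degenerate")
  expect_error(closedForm2MD(1, 0.5, 0.5, 1, -1, 10, 0), "positive")
})

test_that("three-material Jacobian expansion equals the determinant", {
  expect_equal(jacobian3MD(diag(3)), 1)
  m <- matrix(runif(9), 3, 3); m[2, ] <- m[1, ]
  expect_equal(jacobian3MD(m), 0)
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rnorm(9), 3, 3)
    expect_equal(jacobian3MD(m), det(m), tolerance = 1e-12)
  }
  expect_error(jacobian3MD(diag(2)), "3 x 3")
})

test_that("propagated covariance is symmetric PSD for any PSD count noise", {
  s <- tstSpectrum(); ch <- channelPreset(3); resp <- idealResp()
  basis <- list("soft_tissue", "iodine_10mgml", "cortical_bone")
  em <- effectiveMu(c(5, 1, 0.5), s, ch, resp, basis)
  Ibar <- as.vector(pcctmd:::.forwardMeans(rbind(c(5, 1, 0.5)),
                                           pcctmd:::.muMatrix(basis), s,
                                           pcctmd:::.channelWeights(ch, resp))$I)
  set.seed(4)
  for (i in 1:20) {
    M <- matrix(rnorm(9), 3, 3)
    VI <- M %*% t(M) * mean(Ibar)
    sdI <- sqrt(diag(VI))
    op <- new("OperatingPoint", A = c(5, 1, 0.5), Ibar = Ibar, VI = VI,
              snr = Ibar / sdI, rhoI = VI / tcrossprod(sdI))
    ce <- propagateCovariance(em, op)
    expect_equal(ce@VA, t(ce@VA))
    expect_gte(min(eigen(ce@VA, symmetric = TRUE)$values), -1e-10 * max(ce@VA))
  }
})

test_that("analytic count covariance matches sampling moments when sharing", {
  s <- tstSpectrum(); ch <- channelPreset(2); resp <- realResp()
  op <- operatingPoint(c(6, 1), s, ch, resp,
                       list("soft_tissue", "cortical_bone"))
  expect_gt(op@rhoI[1, 2], 0)
  cw <- pcctmd:::.channelWeights(ch, resp)
  mm <- pcctmd:::.muMatrix(list("soft_tissue", "cortical_bone"))
  fm1 <- pcctmd:::.forwardMeans(rbind(c(6, 1)), mm, s, cw)
  n <- 200000
  fm <- list(I = matrix(fm1$I, n, 2, byrow = TRUE),
             ns = matrix(fm1$ns, n, 2, byrow = TRUE),
             pair = matrix(fm1$pair, n, 4, byrow = TRUE))
  set.seed(5)
  cnt <- pcctmd:::.sampleCountsMatrix(fm, resp, 2L)
  expect_equal(colMeans(cnt), op@Ibar, tolerance = 0.01)
  expect_equal(cov(cnt)[1, 2], op@VI[1, 2], tolerance = 0.1)
  expect_equal(diag(cov(cnt)), diag(op@VI), tolerance = 0.05,
               ignore_attr = TRUE)
})
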