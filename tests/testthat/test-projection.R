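test_that("line integrals reproduce chord lengths and are linear", {
  g <- tinyGeometry()
  empty <- new("PhantomImage", coeffs = array(0, c(64, 64, 1)),
               materials = "water", pixelSizeMm = 4)
  expect_true(all(lineIntegrals(empty, g)@values == 0))
  ph <- discPhantom(96, 2.5, "water", 1, radiusMm = 50)
  A <- lineIntegrals(ph, g)
  central <- A@values[1, (g@nCells + 1) %/% 2, 1]
  expect_equal(central, 10, tolerance = 0.25 / 10)   # one pixel length
  ph2 <- ph; ph2@coeffs <- ph@coeffs * 3
  expect_equal(lineIntegrals(ph2, g)@values, 3 * A@values, tolerance = 1e-12)
})

test_that("expected counts obey Beer-Lambert limits", {
  g <- geometry(nCells = 4L, nViews = 2L)
  s <- tstSpectrum(); ch <- channelPreset(2); resp <- idealResp()
  zeroA <- new("LineIntegralSinogram",
               values = array(0, c(2, 4, 1)), materials = "water",
               geometry = g, converged = matrix(TRUE, 2, 4))
  ec <- expectedCounts(zeroA, s, ch, resp)
  air <- airScanCounts(s, ch, resp)
  for (k in 1:2) expect_equal(unique(as.vector(ec@counts[, , k])), air[k])
  ## monochromatic single channel: closed form N0 exp(-A mu(E0))
  mono <- new("Spectrum", fluence = c(rep(0, 59), 1e4, rep(0, 80)), kVp = 140)
  ch1 <- channelSet(cbind(1, 140))
  oneA <- zeroA; oneA@values[] <- 2.5
  ec1 <- expectedCounts(oneA, mono, ch1, resp)
  expect_equal(as.vector(ec1@counts),
               rep(1e4 * exp(-2.5 * attenuation("water", 60)), 8))
  ## monotone decreasing in every A
  twoA <- oneA; twoA@values[] <- 5
  ec2 <- expectedCounts(twoA, s, ch, resp)
  ecHalf <- expectedCounts(oneA, s, ch, resp)
  expect_true(all(ec2@counts < ecHalf@counts))
  badA <- oneA; badA@values[1, 1, 1] <- -0.1
  expect_error(expectedCounts(badA, s, ch, resp), "negative")
})

test_that("Poisson sampling is seeded, unbiased and uncorrelated when ideal", {
  g <- geometry(nCells = 100L, nViews = 100L)   # 1e4 identical rays
  s <- tstSpectrum(); ch <- channelPreset(2); resp <- idealResp()
  A <- new("LineIntegralSinogram", values = array(4, c(100, 100, 1)),
           materials = "water", geometry = g,
           converged = matrix(TRUE, 100, 100))
  ec <- expectedCounts(A, s, ch, resp)
  s1 <- sampleCounts(ec, resp, 42)
  s2 <- sampleCounts(ec, resp, 42)
  expect_identical(s1@counts, s2@counts)
  expect_false(identical(s1@counts, sampleCounts(ec, resp, 43)@counts))
  m <- ec@counts[1, 1, ]
  for (k in 1:2) {
    xk <- as.vector(s1@counts[, , k])
    expect_lt(abs(mean(xk) - m[k]), 3 * sqrt(m[k] / 1e4))
  }
  r <- cor(as.vector(s1@counts[, , 1]), as.vector(s1@counts[, , 2]))
  expect_lt(abs(r), 0.03)
  ## all-opaque rays give zero counts
  Ab <- A; Ab@values[] <- 400
  expect_true(all(sampleCounts(expectedCounts(Ab, s, ch, resp),
                               resp, 1)@counts == 0))
  expect_error(sampleCounts(ec, resp, "a"), "seed")
})

test_that("charge sharing induces positive interchannel correlation", {
  g <- geometry(nCells = 100L, nViews = 100L)
  s <- tstSpectrum(); ch <- channelPreset(2); resp <- realResp()
  A <- new("LineIntegralSinogram", values = array(0, c(100, 100, 1)),
           materials = "water", geometry = g,
           converged = matrix(TRUE, 100, 100))
  sc <- sampleCounts(expectedCounts(A, s, ch, resp), resp, 7)
  r <- cor(as.vector(sc@counts[, , 1]), as.vector(sc@counts[, , 2]))
  expect_gt(r, 0)
})

test_that("air-scan dose is channel-count independent at fixed fluence", {
  s <- tstSpectrum(); resp <- idealResp()
  tot <- vapply(2:4, function(K)
    sum(airScanCounts(s, channelPreset(K), resp)), numeric(1))
  expect_equal(tot, rep(1e5, 3))
})
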