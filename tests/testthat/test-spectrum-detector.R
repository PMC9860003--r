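test_that("source spectrum obeys its normalization and endpoint contract", {
  s <- sourceSpectrum(140, 2e5)
  expect_equal(sum(s@fluence), 2e5)
  expect_gt(s@fluence[140], 0)
  expect_true(all(s@fluence >= 0))
  mode <- which.max(s@fluence)
  expect_gt(mode, 20); expect_lt(mode, 80)
  expect_error(sourceSpectrum(140, -1), "positive")
  s120 <- sourceSpectrum(120, 1e5)
  expect_true(all(s120@fluence[energyGrid() > 120] == 0))
})

test_that("equal-count channelization splits uniform fluence at quantiles", {
  uni <- new("Spectrum", fluence = rep(1000, 140), kVp = 140)
  resp <- idealResp()
  expect_equal(channelizeEqualCounts(uni, resp, 2)@bounds,
               matrix(c(1L, 71L, 70L, 140L), 2, 2), ignore_attr = TRUE)
  expect_equal(channelizeEqualCounts(uni, resp, 4)@bounds[, 2],
               c(35L, 70L, 105L, 140L), ignore_attr = TRUE)
})

test_that("channelization of the packaged spectrum balances counts", {
  s <- tstSpectrum()
  resp <- idealResp()
  cs <- channelizeEqualCounts(s, resp, 2)
  ac <- airScanCounts(s, cs, resp)
  expect_lt(abs(ac[1] - ac[2]), max(s@fluence))
  ## invariance to overall fluence scaling
  s2 <- sourceSpectrum(fluenceScale = 7e6)
  expect_equal(channelizeEqualCounts(s2, resp, 3)@bounds,
               channelizeEqualCounts(s, resp, 3)@bounds)
  expect_error(channelizeEqualCounts(s, resp, 141), "populated bins")
})

test_that("packaged channel presets are shipped and the 2-channel preset is balanced", {
  expect_equal(channelPreset(2)@bounds[, 1], c(1L, 59L), ignore_attr = TRUE)
  expect_equal(channelPreset(3)@bounds[, 2], c(51L, 68L, 140L),
               ignore_attr = TRUE)
  expect_equal(channelPreset(4)@bounds[, 1], c(1L, 44L, 59L, 73L),
               ignore_attr = TRUE)
  ac <- airScanCounts(tstSpectrum(), channelPreset(2), idealResp())
  expect_lt(abs(ac[1] / ac[2] - 1), 0.1)
  expect_error(channelPreset(5), "no packaged preset")
})

test_that("ideal channel weighting is an indicator, realistic overlaps", {
  ch <- channelPreset(2)
  w1 <- channelWeighting(ch, idealResp(), 1)
  expect_equal(w1[30], 1)
  expect_equal(w1[100], 0)
  wr <- channelWeighting(ch, realResp(), 1)
  expect_gt(wr[100], 0)                       # interchannel overlap
  expect_true(all(wr[100] >= w1[100]))
  expect_error(channelWeighting(ch, idealResp(), 3), "out of range")
})

test_that("summed channel weights respect the sharing bound", {
  for (resp in list(idealResp(), realResp())) {
    ch <- channelPreset(3)
    W <- vapply(1:3, function(k) channelWeighting(ch, resp, k), numeric(140))
    bound <- resp@efficiency * (1 + resp@sharingFraction)
    expect_true(all(rowSums(W) <= bound + 1e-9))
  }
})

test_that("detector response validity rules hold", {
  r <- realResp()
  expect_true(all(colSums(r@kernel) <= 1 + 1e-8))
  expect_equal(idealResp()@kernel, diag(140))
  expect_equal(idealResp()@sharingFraction, 0)
  expect_error(new("DetectorResponse", mode = "ideal",
                   efficiency = rep(1, 140), kernel = diag(140),
                   sharingFraction = 0.2, uRange = c(0.1, 0.5)),
               "sharingFraction")
})
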