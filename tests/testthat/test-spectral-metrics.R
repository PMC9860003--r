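test_that("Pearson R reproduces hand-computed and limiting cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonR(x, x)$R, 1)
  expect_equal(pearsonR(x, -2 * x + 7)$R, -1)
  expect_equal(pearsonR(x, c(2, 1, 4, 3))$R, 0.6)
  expect_equal(pearsonR(x, c(2, 1, 4, 3))$N, 4L)
  expect_error(pearsonR(x, rep(1, 4)), "zero variance")
  expect_error(pearsonR(x, 1:3), "equal length")
  ## affine invariance / sign flip
  set.seed(6)
  a <- rnorm(50); b <- rnorm(50)
  r0 <- pearsonR(a, b)$R
  expect_equal(pearsonR(3 * a + 2, b)$R, r0)
  expect_equal(pearsonR(-3 * a + 2, b)$R, -r0)
})

test_that("CNR implements the average-of-SD denominator", {
  sig <- c(8, 12); bkg <- c(4, 8)           # means 10/6, both sd = 2 sqrt(2)
  res <- cnr(sig, bkg)
  expect_equal(res$contrast, 4)
  expect_equal(res$cnr, 4 / (2 * sqrt(2)))
  expect_equal(cnr(sig, sig)$cnr, 0)
  expect_equal(cnr(5 * sig, 5 * bkg)$cnr, res$cnr)    # scale invariance
  expect_gt(res$cnr * res$contrast, 0)                # matching signs
  expect_error(cnr(c(1, 1), c(2, 2)), "zero denominator")
})

test_that("VMI synthesis is the coefficient-weighted attenuation sum", {
  n <- 16
  imgs <- array(0, c(n, n, 2), dimnames = list(NULL, NULL,
                                               c("soft_tissue",
                                                 "cortical_bone")))
  imgs[, , 1] <- 1
  bis <- new("BasisImageSet", images = imgs,
             materials = c("soft_tissue", "cortical_bone"),
             pixelSizeMm = 1, provenance = list())
  v <- synthesizeVMI(bis, 45)
  expect_equal(unique(as.vector(v)), attenuation("soft_tissue", 45))
  ## linearity in each basis image
  bis2 <- bis; bis2@images[, , 2] <- 0.5
  v2 <- synthesizeVMI(bis2, 45)
  expect_equal(v2, v + 0.5 * attenuation("cortical_bone", 45) *
                 matrix(1, n, n))
  ## Hounsfield conversion references water
  bisW <- new("BasisImageSet",
              images = array(1, c(n, n, 1), dimnames = list(NULL, NULL,
                                                            "water")),
              materials = "water", pixelSizeMm = 1, provenance = list())
  expect_equal(unique(as.vector(synthesizeVMI(bisW, 70, hounsfield = TRUE))),
               0)
  expect_error(synthesizeVMI(bis, 200), "eMono")
})

test_that("noise-correlation report covers all pairs with correct limits", {
  set.seed(7)
  n <- 64
  base <- array(rnorm(n * n * 4), c(n, n, 4))
  mats <- c("a", "b", "c", "d")
  noisy <- new("BasisImageSet", images = base + 1, materials = mats,
               pixelSizeMm = 1, provenance = list())
  clean <- new("BasisImageSet", images = array(1, c(n, n, 4)),
               materials = mats, pixelSizeMm = 1, provenance = list())
  tab <- noiseCorrelationReport(noisy, clean, list(roi(c(0, 0), 40)))
  expect_equal(nrow(tab), choose(4, 2))
  ## a pair of identical noise images has R = 1
  noisy2 <- noisy; noisy2@images[, , 2] <- noisy2@images[, , 1]
  tab2 <- noiseCorrelationReport(noisy2, clean, list(roi(c(0, 0), 40)))
  expect_equal(tab2$R[tab2$material1 == "a" & tab2$material2 == "b"], 1)
  cleanBad <- clean; cleanBad@materials <- c("a", "b", "c", "e")
  expect_error(noiseCorrelationReport(noisy, cleanBad, list(roi(c(0, 0), 40))),
               "share materials")
})
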