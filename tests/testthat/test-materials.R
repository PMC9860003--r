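test_that("water attenuation matches the authoritative value at 60 keV", {
  ## NIST mass attenuation of water at 60 keV is 0.2059 cm^2/g (unit density)
  expect_equal(attenuation("water", 60), 0.2059, tolerance = 0.01)
})

test_that("every packaged material resolves and is monotone between K-edges", {
  mats <- c("water", "soft_tissue", "cortical_bone", "adipose", "pmma",
            "teflon", "iodine_10mgml", "gadolinium_10mgml")
  E <- energyGrid()
  for (nm in mats) {
    m <- getMaterial(nm)
    expect_s4_class(m, "Material")
    expect_true(all(m@mu > 0))
    brk <- c(0, m@kEdges, 141)
    for (i in seq_len(length(brk) - 1)) {
      idx <- which(E > brk[i] & E < brk[i + 1])
      if (length(idx) > 1)
        expect_true(all(diff(m@mu[idx]) <= 1e-9), label = nm)
    }
  }
  expect_error(getMaterial("unobtainium"), "unknown material")
})

test_that("K-edges sit at their tabulated energies and jump upward", {
  expect_equal(findKEdge("gadolinium_10mgml"), 50.2, tolerance = 1e-3)
  expect_equal(findKEdge("iodine_10mgml"), 33.2, tolerance = 1e-3)
  for (nm in c("iodine_10mgml", "gadolinium_10mgml")) {
    e <- getMaterial(nm)@kEdges
    expect_gt(attenuation(nm, e + 0.05), attenuation(nm, e - 0.05))
  }
  ## bulk materials have no edge in the diagnostic range
  expect_length(findKEdge("water"), 0)
  expect_error(attenuation("water", 150), "out of the")
})

test_that("mixture attenuation is linear and permutation invariant", {
  E <- c(40, 70, 100)
  one <- mixtureSpec(list("cortical_bone"), 1)
  expect_equal(mixtureAttenuation(one, E), attenuation("cortical_bone", E))
  half <- mixtureSpec(list("soft_tissue", "cortical_bone"), c(0.5, 0.5))
  expect_equal(mixtureAttenuation(half, E),
               (attenuation("soft_tissue", E) +
                  attenuation("cortical_bone", E)) / 2)
  rod1 <- mixtureSpec(list("soft_tissue", "cortical_bone"), c(1, 2) / 3)
  expect_equal(mixtureAttenuation(rod1, 70),
               attenuation("soft_tissue", 70) / 3 +
                 2 * attenuation("cortical_bone", 70) / 3)
  perm <- mixtureSpec(list("cortical_bone", "soft_tissue"), c(2, 1) / 3)
  expect_equal(mixtureAttenuation(perm, E), mixtureAttenuation(rod1, E))
  expect_error(mixtureSpec(list("water", "pmma"), c(0.6, 0.5)), "sum to 1")
})

test_that("solution attenuation is water plus concentration-linear excess", {
  E <- energyGrid()
  expect_equal(solutionAttenuation("iodine", 0, E), attenuation("water", E))
  ex10 <- solutionAttenuation("iodine", 10, E) - attenuation("water", E)
  ex20 <- solutionAttenuation("iodine", 20, E) - attenuation("water", E)
  expect_equal(ex20, 2 * ex10, tolerance = 1e-12)
  expect_error(solutionMaterial("iodine", -1), ">= 0")
})
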