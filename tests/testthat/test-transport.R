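test_that("single-layer records keep one strictly positive pathlength", {
  med <- skinMedium(10, 7.1)
  p <- runWhiteMC(med, 2e3, seed = 1)
  expect_identical(ncol(p@pathlengths), 1L)
  expect_true(all(p@pathlengths[, 1] > 0))
  expect_true(all(p@weight > 0 & p@weight <= 1))
  expect_true(all(p@radius >= 0))
})

test_that("photons that reached the subcutis crossed the epidermis twice", {
  p <- paths735()
  deep <- p@pathlengths[, 2] > 0
  expect_gt(mean(deep), 0.5)  # most photons sample the deep layer
  expect_true(all(p@pathlengths[deep, 1] >= 2 * 0.011 - 1e-12))
})

test_that("identical seed and inputs give a bit-identical record stream", {
  a <- runWhiteMC(medium735(), 5e3, seed = 77)
  b <- runWhiteMC(medium735(), 5e3, seed = 77)
  expect_identical(a@pathlengths, b@pathlengths)
  expect_identical(a@radius, b@radius)
  c <- runWhiteMC(medium735(), 5e3, seed = 78)
  expect_false(identical(a@radius, c@radius))
})

test_that("non-physical media are rejected", {
  expect_error(skinMedium(10, 7.1, g = 1), "anisotropy")
  expect_error(skinMedium(10, 7.1, n = 0.9), "refractive")
  expect_error(skinMedium(10, -2), "musp")
  expect_error(runWhiteMC(medium735(), 100, seed = 1), "nPhotons")
})

test_that("white MC rescaling matches direct absorbing MC within 3 SE", {
  p <- paths735()
  for (mua in list(c(0.06, 0.06), c(2, 0.1), c(8, 0.3))) {
    w <- scoreSFD(p, mua)
    d <- runDirectMC(medium735(), mua, 5e4, seed = 900 + round(100 * mua[1]))
    expect_lt(abs(w@rd0 - d@rd0), 3 * sqrt(w@se0^2 + d@se0^2))
    expect_lt(abs(w@rd1 - d@rd1), 3 * sqrt(w@se1^2 + d@se1^2))
  }
})

test_that("scoring reduces to total diffuse reflectance at zero frequency", {
  p <- paths735()
  sc <- scoreSFD(p, c(0, 0))
  expect_equal(sc@rd0, sum(p@weight) / p@nPhotons, tolerance = 1e-12)
  expect_lte(sc@rd1, sc@rd0)
})

test_that("Beer weighting is monotone in absorption", {
  p <- paths735()
  r1 <- scoreSFD(p, c(0.5, 0.1))
  r2 <- scoreSFD(p, c(0.5, 0.2))
  r3 <- scoreSFD(p, c(1.0, 0.1))
  expect_lt(r2@rd0, r1@rd0)   # doubling mua_sub strictly decreases Rd(0)
  expect_lt(r3@rd0, r1@rd0)
  expect_error(scoreSFD(p, 0.1), "per layer")
  expect_error(scoreSFD(p, c(-0.1, 0.1)), ">= 0")
})

test_that("total reflectance agrees with diffusion theory at high albedo", {
  # reference phantom scattering carried to 735 nm, mean phantom absorption
  sf <- fitScatterPowerLaw(c(7.1, 5.3), c(690, 830))
  musp <- sf$A
  mua <- 0.0495
  p <- memo("pathsHom735", function()
    runWhiteMC(skinMedium(10, musp), 5e4, seed = 5))
  mc <- scoreSFD(p, mua)
  expect_lt(abs(mc@rd0 - diffusionRd(mua, musp)) / mc@rd0, 0.10)
})
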