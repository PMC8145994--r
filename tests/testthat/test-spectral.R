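test_that("melanin index maps to epidermal absorption through the melanin spectrum", {
  expect_equal(miToMuaEpi(0.16, 662), 0.16 / 0.011, tolerance = 1e-12)
  expect_equal(miToMuaEpi(0.176, 662), 16, tolerance = 1e-12)
  # spectral ratio is exp(-0.009 * (735 - 662))
  expect_equal(miToMuaEpi(0.1, 735) / miToMuaEpi(0.1, 662),
               exp(-0.009 * 73), tolerance = 1e-12)
  expect_equal(miToMuaEpi(0, c(662, 735, 859)), c(0, 0, 0))
  expect_error(miToMuaEpi(-0.1, 662), ">= 0")
})

test_that("hemoglobin unmixing is exact on consistent two-chromophore spectra", {
  wl <- c(662, 735, 859)
  mua <- hemoglobinMua(20, 0.75, wl)
  fit <- fitHemoglobin(mua, wl)
  expect_equal(fit$cHbO, 15, tolerance = 1e-9)
  expect_equal(fit$cHb, 5, tolerance = 1e-9)
  expect_equal(fit$tHb, 20, tolerance = 1e-9)
  expect_equal(fit$stO2, 0.75, tolerance = 1e-12)
  expect_lt(fit$mse, 1e-25)
  expect_true(fit$physiological)
})

test_that("the fit is exactly linear in the input spectrum", {
  wl <- c(662, 735, 859)
  set.seed(3)
  for (rep in 1:10) {
    mua <- hemoglobinMua(runif(1, 5, 40), runif(1, 0.2, 0.9), wl) +
      rnorm(3, 0, 0.002)
    f1 <- fitHemoglobin(mua, wl)
    k <- runif(1, 0.5, 3)
    f2 <- fitHemoglobin(k * mua, wl)
    expect_equal(f2$cHbO, k * f1$cHbO, tolerance = 1e-8)
    expect_equal(f2$cHb, k * f1$cHb, tolerance = 1e-8)
    expect_equal(f2$mse, k^2 * f1$mse, tolerance = 1e-8)
  }
})

test_that("a 735 nm excess raises the fit error", {
  wl <- c(662, 735, 859)
  mua <- hemoglobinMua(20, 0.75, wl)
  base <- fitHemoglobin(mua, wl)$mse
  bump <- fitHemoglobin(mua + c(0, 0.01, 0), wl)$mse
  expect_gt(bump, base)
})

test_that("adjusted MSE dominates MSE and is undefined beyond full saturation", {
  wl <- c(662, 735, 859)
  set.seed(8)
  for (rep in 1:10) {
    mua <- hemoglobinMua(20, runif(1, 0.1, 0.95), wl) + abs(rnorm(3, 0, 0.003))
    f <- fitHemoglobin(mua, wl)
    if (f$stO2 > 0 && f$stO2 < 1) expect_gte(f$adjMse, f$mse)
  }
  pureHbO <- log(10) * hbExtinction(wl)[, 1] * 20e-6
  f <- fitHemoglobin(pureHbO, wl)
  expect_equal(f$stO2, 1, tolerance = 1e-9)
  expect_identical(f$adjMse, Inf)
})

test_that("scatter power-law fitting is exact on power-law input", {
  wl <- c(662, 735, 859)
  musp <- 16.9 * (wl / 735)^-1.21
  sf <- fitScatterPowerLaw(musp, wl)
  expect_equal(sf$A, 16.9, tolerance = 1e-10)
  expect_equal(sf$b, 1.21, tolerance = 1e-10)
  # device epidermal scattering: amplitude anchored near the 735 nm value
  sfE <- fitScatterPowerLaw(c(22.16, 16.89, 11.62), wl)
  # independent normal-equation solution on the log-log scale
  x <- -log(wl / 735); y <- log(c(22.16, 16.89, 11.62))
  bHat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  aHat <- exp(mean(y) - bHat * mean(x))
  expect_equal(sfE$b, bHat, tolerance = 1e-10)
  expect_equal(sfE$A, aHat, tolerance = 1e-10)
  expect_equal(sfE$A, 16.9, tolerance = 0.02)
  expect_error(fitScatterPowerLaw(c(-1, 2), c(690, 830)), "> 0")
})

test_that("the MI grid has the prescribed spacing and tie-break", {
  grid <- seq(0, 0.176, length.out = 161)
  expect_equal(diff(grid)[1], 0.176 / 160, tolerance = 1e-15)
  expect_identical(length(grid), 161L)
})

test_that("MI optimization tracks the planted melanin level", {
  luts <- miniLUTs()$twoLayer
  for (miTrue in c(0.01, 0.1)) {
    rd <- makeForwardRd(phantomSpec(miTrue), nPhotons = 4e4,
                        seed = 300 + round(1000 * miTrue))
    fit <- optimizeMI(rd, luts)
    expect_lt(abs(fit@selectedMI - miTrue), 0.03)
    # adjusted and unadjusted criteria agree on two-chromophore input
    fitAdj <- optimizeMI(rd, luts, mode = "adjusted")
    expect_equal(fitAdj@selectedMI, fit@selectedMI)
    # raising assumed MI raises StO2 and lowers tHb (trend over the grid)
    ok <- is.finite(fit@stO2) & !apply(fit@oob, 1, any)
    expect_gt(cor(fit@miGrid[ok], fit@stO2[ok], method = "spearman"), 0.95)
    expect_lt(cor(fit@miGrid[ok], fit@tHb[ok], method = "spearman"), -0.95)
  }
})
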