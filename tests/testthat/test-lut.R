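test_that("device two-layer tables have the prescribed grid geometry", {
  lut <- miniLUTs()$twoLayer[["735"]]
  expect_identical(length(lut@muaEpiAxis), 21L)
  expect_identical(range(lut@muaEpiAxis), c(0, 20))
  expect_identical(length(lut@muaSubAxis), 75L)
  expect_equal(range(lut@muaSubAxis), c(0.01, 0.75))
  expect_equal(lut@musEpiPrime, 16.89)
  expect_equal(lut@depiModel, 0.011)
  expect_true(all(lut@rd1Grid <= lut@rd0Grid + 1e-12))
  expect_true(all(lut@rd0Grid >= 0 & lut@rd0Grid <= 1))
})

test_that("grids are monotone along every optical-property axis", {
  lut <- miniLUTs()$twoLayer[["662"]]
  # Beer factors from a shared record set: exactly monotone in both mua axes
  expect_true(all(apply(lut@rd0Grid, c(2, 3), function(v) all(diff(v) <= 0))))
  expect_true(all(apply(lut@rd0Grid, c(1, 3), function(v) all(diff(v) <= 0))))
  expect_true(all(apply(lut@rd1Grid, c(2, 3), function(v) all(diff(v) <= 0))))
  # independent runs along the scattering axis: monotone within MC noise
  tol <- 2 * sqrt(2) * mcSeBound(lut@provenance$nPhotons[1])
  expect_true(all(apply(lut@rd0Grid, c(1, 2), function(v) all(diff(v) >= -tol))))
})

test_that("raising epidermal absorption darkens the table", {
  lut <- miniLUTs()$twoLayer[["735"]]
  lo <- collapseLUT(lut, 0.66)
  hi <- collapseLUT(lut, 9.9)
  expect_true(all(hi@rd0Grid < lo@rd0Grid))
})

test_that("collapse is exact on nodes and linear between them", {
  lut <- miniLUTs()$twoLayer[["735"]]
  ax <- lut@muaEpiAxis
  onNode <- collapseLUT(lut, ax[4])
  expect_identical(onNode@rd0Grid, lut@rd0Grid[4, , ])
  mid <- collapseLUT(lut, (ax[4] + ax[5]) / 2)
  expect_equal(mid@rd0Grid, (lut@rd0Grid[4, , ] + lut@rd0Grid[5, , ]) / 2,
               tolerance = 1e-12)
  expect_error(collapseLUT(lut, 25), "outside")
})

test_that("inversion is node-exact and flags out-of-gamut queries", {
  tab <- collapseLUT(miniLUTs()$twoLayer[["735"]], 1.9)
  i <- 30L; j <- 5L
  inv <- invertRd(tab, tab@rd0Grid[i, j], tab@rd1Grid[i, j])
  expect_equal(inv$mua, tab@muaAxis[i], tolerance = 1e-9)
  expect_equal(inv$musp, tab@muspAxis[j], tolerance = 1e-9)
  expect_false(inv$oob)
  far <- invertRd(tab, 0.98, 0.97)
  expect_true(far$oob)
  expect_true(is.finite(far$mua) && is.finite(far$musp))  # hull clamp
  nan <- invertRd(tab, NaN, 0.1)
  expect_true(nan$oob)
})

test_that("inversion is a left inverse of the forward interpolation", {
  tab <- collapseLUT(miniLUTs()$twoLayer[["859"]], 0.8)
  set.seed(11)
  mua <- runif(25, 0.02, 0.7)
  musp <- runif(25, 4.5, 19.5)
  f <- forwardRd(tab, mua, musp)
  inv <- invertRd(tab, f$rd0, f$rd1)
  # piecewise-linear inverse of a piecewise-bilinear forward: small residual
  expect_lt(max(abs(inv$mua - mua) / mua), 0.05)
  expect_lt(max(abs(inv$musp - musp) / musp), 0.05)
  # absorption moves rd0 down, scattering moves both up (gamut orientation)
  g <- forwardRd(tab, c(0.1, 0.3, 0.1), c(10, 10, 14))
  expect_lt(g$rd0[2], g$rd0[1])
  expect_gt(g$rd0[3], g$rd0[1])
  expect_gt(g$rd1[3], g$rd1[1])
})

test_that("a degenerate layer split reduces to the homogeneous table", {
  # matched epidermal and subcutaneous scattering: a two-layer medium with
  # the same absorption in both layers is physically the homogeneous medium
  ms <- 8
  p2 <- memo("degenerate2L", function()
    runWhiteMC(skinMedium(c(0.011, 10), c(ms, ms)), 3e4, seed = 21))
  p1 <- memo("degenerate1L", function()
    runWhiteMC(skinMedium(10.011, ms), 3e4, seed = 22))
  for (mua in c(0.05, 0.2, 0.5)) {
    two <- scoreSFD(p2, c(mua, mua))
    one <- scoreSFD(p1, mua)
    expect_lt(abs(two@rd0 - one@rd0), 3 * sqrt(two@se0^2 + one@se0^2))
    expect_lt(abs(two@rd1 - one@rd1), 3 * sqrt(two@se1^2 + one@se1^2))
  }
  # with the epidermis fully transparent (mua_epi = 0) the medium is
  # slightly brighter than the homogeneous one — the top 110 um absorbs
  # nothing — by about exp(mua * <L_epi>); at low absorption this sits
  # below the Monte Carlo noise
  twoT <- scoreSFD(p2, c(0, 0.05))
  oneT <- scoreSFD(p1, 0.05)
  expect_gt(twoT@rd0 - oneT@rd0, -3 * sqrt(twoT@se0^2 + oneT@se0^2))
  expect_lt(twoT@rd0 - oneT@rd0, 0.01)
})

test_that("tables serialize and restore bit-exactly", {
  lut <- miniLUTs()$twoLayer[["662"]]
  f <- tempfile(fileext = ".rds")
  writeLUT(lut, f)
  back <- readLUT(f)
  expect_identical(back@rd0Grid, lut@rd0Grid)
  expect_identical(back@provenance, lut@provenance)
  unlink(f)
  bad <- tempfile(fileext = ".rds")
  saveRDS(1:3, bad)
  expect_error(readLUT(bad), "lookup table")
  unlink(bad)
})

test_that("the LUT builder rejects inconsistent record sets", {
  p <- list(runWhiteMC(skinMedium(c(0.011, 10), c(16.89, 8)), 2e3, seed = 1),
            runWhiteMC(skinMedium(c(0.011, 10), c(16.89, 6)), 2e3, seed = 2))
  expect_error(buildTwoLayerLUT(p, 735), "increasing")
})
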