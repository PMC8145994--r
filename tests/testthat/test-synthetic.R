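test_that("phantom specifications enforce their physical invariants", {
  expect_s4_class(phantomSpec(0.1), "PhantomSpec")
  expect_error(phantomSpec(-0.1), "mi")
  expect_error(phantomSpec(0.1, stO2 = 1.2), "stO2")
  expect_error(phantomSpec(0.1, muspSub = c(-1, 2, 3)), "scattering")
})

test_that("melanin-free phantoms are the brightest of the battery", {
  # one shared record set per wavelength; MI enters only through Beer factors
  sp0 <- phantomSpec(0)
  paths <- memo("batteryPaths", function() lapply(1:3, function(i)
    runWhiteMC(skinMedium(c(0.011, 10),
                          c(sp0@muspEpi[i], sp0@muspSub[i])),
               3e4, seed = 400 + i)))
  rdAll <- lapply(c(0, 0.005, 0.04, 0.16), function(mi)
    makeForwardRd(phantomSpec(mi), paths = paths))
  for (k in 2:4) {
    expect_true(all(rdAll[[k]]@rd0 < rdAll[[1]]@rd0))
    expect_true(all(rdAll[[k]]@rd1 < rdAll[[1]]@rd1))
  }
  # monotone decline with MI at every wavelength
  rd0s <- sapply(rdAll, function(r) r@rd0)
  expect_true(all(apply(rd0s, 1, function(v) all(diff(v) < 0))))
})

test_that("compression movies carry a U-shaped hemoglobin ground truth", {
  mov <- defaultMovie()
  comp <- mov@times >= 60 & mov@times < 120
  for (r in 1:8) {
    tr <- mov@truth$thbRoi[, r]
    expect_identical(comp[which.min(tr)], TRUE)
    expect_lt(min(tr), mov@truth$tHb - 0.5)
    # recovery returns to baseline
    expect_equal(tr[length(tr)], tr[1], tolerance = 0.05 * mov@truth$tHb)
  }
})

test_that("zero planted slope yields recovered slopes centred on zero", {
  mov0 <- makeCompressionMovie(miniLUTs()$twoLayer, mi = 0.05, nx = 32,
                               ny = 32, sto2Slope = 0,
                               slopeJitterSd = 0.002, seed = 31)
  res <- processCompression(mov0, miniLUTs()$twoLayer, mi = 0.05)
  kept <- !res$rois$rejected
  expect_lt(abs(mean(res$rois$compressionSlope[kept])), 0.006)
})

test_that("movie synthesis is reproducible and respects its contracts", {
  a <- makeCompressionMovie(miniLUTs()$twoLayer, mi = 0.02, nx = 24, ny = 24,
                            seed = 5)
  b <- makeCompressionMovie(miniLUTs()$twoLayer, mi = 0.02, nx = 24, ny = 24,
                            seed = 5)
  expect_identical(a@rd, b@rd)
  expect_identical(a@truth$roiSlopes, b@truth$roiSlopes)
  expect_error(makeCompressionMovie(miniLUTs()$twoLayer, thbDip = 25),
               "dip")
})

test_that("planted compression slopes are recovered across ROIs", {
  mov <- defaultMovie()
  res <- processCompression(mov, miniLUTs()$twoLayer, mi = mov@truth$mi)
  kept <- !res$rois$rejected
  err <- res$rois$compressionSlope[kept] - mov@truth$roiSlopes[kept]
  # recovered per-ROI slopes track the planted values to within a few
  # thousandths of a pp/s at the default noise
  expect_lt(max(abs(err)), 0.008)
  expect_lt(abs(mean(err)), 0.004)
})
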