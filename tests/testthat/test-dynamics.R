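test_that("specular rejection keeps uniform images and catches hot pixels", {
  m0 <- array(1, c(8, 8, 1, 4))
  expect_true(!any(rejectSpecularPixels(m0)))
  # one pixel at +10 SD in a single frame excludes it for the whole run
  set.seed(1)
  m0 <- array(rnorm(8 * 8 * 1 * 4, 100, 1), c(8, 8, 1, 4))
  v <- m0[, , 1, 2]; v[3, 5] <- 100 + 10 * sd(v); m0[, , 1, 2] <- v
  rej <- rejectSpecularPixels(m0)
  expect_true(rej[3, 5])
})

test_that("planted specular discs are recovered by the rejection mask", {
  mov <- defaultMovie()
  movSpec <- makeCompressionMovie(miniLUTs()$twoLayer, mi = 0.05, nx = 32,
                                  ny = 32, seed = 9,
                                  noise = noiseModel(specularN = 2,
                                                     specularRadius = 3))
  m0 <- movSpec@rd[, , , 1, ]
  rej <- rejectSpecularPixels(m0, movSpec@fovMask)
  planted <- movSpec@truth$specular & movSpec@fovMask
  expect_true(all(rej[planted]))
})

test_that("dynamic-absorption rejection is scale-covariant and targeted", {
  set.seed(2)
  a <- array(rnorm(16 * 16 * 2 * 6, 0.1, 0.002), c(16, 16, 2, 6))
  expect_true(!any(rejectDynamicPixels(a, pixelPitch = 2)))
  b <- a
  b[2, 2, 1, 3] <- 0.1 + 9 * sd(a[5:12, 5:12, 1, ])
  rej <- rejectDynamicPixels(b, pixelPitch = 2)
  expect_true(rej[2, 2])
  expect_identical(rejectDynamicPixels(b * 37, pixelPitch = 2), rej)
  expect_error(rejectDynamicPixels(a, pixelPitch = 50), "3 x 3")
})

test_that("the circular field partitions into eight equal disjoint sectors", {
  # sector areas equalize as O(1/R): boundary pixels along the diagonals are
  # assigned to one side, so use a generous radius
  n <- 520
  d2 <- outer((1:n - (n + 1) / 2)^2, (1:n - (n + 1) / 2)^2, `+`)
  fov <- d2 <= 250^2
  lab <- partitionROIs(fov)
  expect_identical(sort(unique(lab[fov])), 1:8)
  expect_true(all(lab[!fov] == 0L))
  areas <- tabulate(lab[fov], 8)
  expect_lt(diff(range(areas)) / mean(areas), 0.01)
  # rotating the image by 90 degrees shifts the sector labels by two
  rot90 <- function(m) t(m)[, nrow(m):1]
  labR <- partitionROIs(rot90(fov))
  expected <- ifelse(lab == 0L, 0L, (lab + 1L) %% 8L + 1L)
  expect_gt(mean(rot90(expected) == labR), 0.999)
  expect_error(partitionROIs(matrix(FALSE, 4, 4)), "empty")
})

test_that("baseline screening applies the slope and noise thresholds", {
  times <- seq(0, 178, by = 2)
  flat <- rep(0.7, length(times))
  s <- screenBaseline(flat, times)
  expect_equal(s$slope, 0); expect_equal(s$rms, 0); expect_true(s$keep)
  drift <- 0.7 + 0.0005 * times          # 0.05 pp/s > 0.045 pp/s
  expect_false(screenBaseline(drift, times)$keep)
  ok <- 0.7 + 0.0004 * times             # 0.04 pp/s
  expect_true(screenBaseline(ok, times)$keep)
  wob <- 0.7 + 0.005 * sqrt(2) * sin(2 * pi * times / 7)  # rms ~0.5 pp
  scr <- screenBaseline(wob, times)
  expect_gt(scr$rms, 0.4); expect_false(scr$keep)
})

test_that("compression slopes are recovered exactly for linear declines", {
  times <- seq(0, 178, by = 2)
  tr <- 0.7 - 0.00011 * pmax(times - 60, 0)   # -0.011 pp/s during compression
  expect_equal(compressionSlope(tr, times), -0.011, tolerance = 1e-9)
  expect_equal(compressionSlope(rep(0.6, length(times)), times), 0)
  expect_equal(compressionSlope(tr + 0.05, times),
               compressionSlope(tr, times), tolerance = 1e-12)
})

test_that("window endpoints are inclusive", {
  times <- seq(0, 175, by = 5)
  tr <- seq_along(times) * 0 + 0.7
  s <- screenBaseline(tr, times, window = c(10, 55))
  expect_true(s$keep)
  expect_identical(sum(times >= 10 & times <= 55), 10L)
})

test_that("ROI artifact screening uses a strict 60% threshold", {
  roi <- matrix(TRUE, 10, 10)
  rej <- matrix(FALSE, 10, 10)
  expect_true(roiArtifactScreen(roi, rej))
  rej[1:61] <- TRUE
  expect_false(roiArtifactScreen(roi, rej))
  rej[] <- FALSE; rej[1:60] <- TRUE
  expect_true(roiArtifactScreen(roi, rej))   # exactly 60% is kept
})

test_that("baseline averaging is exact for constant and drifting stacks", {
  mov <- defaultMovie()
  cons <- mov
  cons@rd[] <- 0.5
  cons@rd[, , , 2, ] <- 0.2
  avg <- baselineAverageRd(cons)
  expect_equal(avg@rd0, rep(0.5, 3)); expect_equal(avg@rd1, rep(0.2, 3))
  # linear drift r0 + c t averages to r0 + c * mean(retained times)
  drift <- cons
  for (it in seq_along(drift@times))
    drift@rd[, , , 1, it] <- 0.5 + 1e-3 * drift@times[it]
  keep <- drift@times >= 10 & drift@times <= 55
  avg2 <- baselineAverageRd(drift)
  expect_equal(avg2@rd0, rep(0.5 + 1e-3 * mean(drift@times[keep]), 3),
               tolerance = 1e-12)
})

test_that("the dynamic pipeline recovers planted compression hemodynamics", {
  mov <- defaultMovie()
  res <- processCompression(mov, miniLUTs()$twoLayer, mi = mov@truth$mi)
  kept <- !res$rois$rejected
  expect_gt(sum(kept), 0)
  # sign-correct compression slopes in >= 95% of retained ROIs
  signOK <- sign(res$rois$compressionSlope[kept]) ==
    sign(mov@truth$roiSlopes[kept])
  expect_gte(mean(signOK), 0.95)
  # tHb dips during compression and recovers: U-shape in the ROI means
  comp <- mov@times >= mov@timeline["compression"] &
    mov@times < mov@timeline["recovery"]
  for (r in which(kept)) {
    tr <- res$thb[, r]
    expect_lt(min(tr[comp]), mean(tr[mov@times < 60]) - 1)
    expect_identical(comp[which.min(tr)], TRUE)  # minimum inside compression
  }
  # rejection decisions are reproducible (idempotent rerun)
  res2 <- processCompression(mov, miniLUTs()$twoLayer, mi = mov@truth$mi)
  expect_identical(res$rois, res2$rois)
})

test_that("an ROI buried under a large artifact is rejected with a reason", {
  movSpec <- makeCompressionMovie(miniLUTs()$twoLayer, mi = 0.05, nx = 32,
                                  ny = 32, seed = 13,
                                  noise = noiseModel(specularN = 3,
                                                     specularRadius = 8))
  res <- processCompression(movSpec, miniLUTs()$twoLayer, mi = 0.05)
  expect_true(all(res$rois$reason[res$rois$rejected] %in%
                    c("artifact", "baseline-unstable")))
})
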