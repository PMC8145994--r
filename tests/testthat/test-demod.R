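test_that("demodulation recovers DC and AC of ideal sinusoids exactly", {
  ph <- 2 * pi * (0:2) / 3
  # constant illumination
  d <- demodulate(matrix(5, 3, 3), matrix(5, 3, 3), matrix(5, 3, 3))
  expect_equal(d$m0, matrix(5, 3, 3))
  expect_equal(d$m1, matrix(0, 3, 3))
  # property: random offset, amplitude and phase per pixel
  set.seed(4)
  for (rep in 1:20) {
    B <- matrix(runif(12, 5, 50), 3, 4)
    A <- matrix(runif(12, 0, 4), 3, 4)
    phi <- matrix(runif(12, 0, 2 * pi), 3, 4)
    fr <- lapply(ph, function(p) B + A * cos(phi + p))
    d <- demodulate(fr[[1]], fr[[2]], fr[[3]])
    expect_equal(d$m0, B, tolerance = 1e-12)
    expect_equal(d$m1, A, tolerance = 1e-10)
    # permutation symmetry
    d2 <- demodulate(fr[[3]], fr[[1]], fr[[2]])
    expect_equal(d2$m0, d$m0, tolerance = 1e-12)
    expect_equal(d2$m1, d$m1, tolerance = 1e-10)
  }
  expect_error(demodulate(matrix(1, 2, 2), matrix(1, 2, 3), matrix(1, 2, 2)),
               "identical shape")
  expect_error(demodulate(matrix(-1, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2)),
               "non-negative")
})

test_that("saturated pixels are masked before demodulation", {
  f <- matrix(10, 4, 4); f[2, 2] <- 4095
  m <- maskSaturated(list(f, matrix(10, 4, 4)), 4095)
  expect_true(m[2, 2]); expect_equal(sum(m), 1L)
  d <- demodulate(f, matrix(10, 4, 4), matrix(10, 4, 4), mask = m)
  expect_true(is.na(d$m0[2, 2]))
})

test_that("calibration is exact for identity and linear measurements", {
  ref <- demodulate(matrix(8, 5, 5), matrix(12, 5, 5), matrix(10, 5, 5))
  out <- calibrate(ref, ref, 0.6, 0.2)
  expect_equal(out$rd0, matrix(0.6, 5, 5))
  expect_equal(out$rd1, matrix(0.2, 5, 5))
  half <- list(m0 = ref$m0 / 2, m1 = ref$m1 / 2)
  out2 <- calibrate(half, ref, 0.6, 0.2)
  expect_equal(out2$rd0, matrix(0.3, 5, 5))
})

test_that("calibration is invariant to a common gain on all raw frames", {
  set.seed(9)
  ph <- 2 * pi * (0:2) / 3
  B <- matrix(runif(16, 20, 40), 4, 4); A <- 0.3 * B
  Br <- matrix(runif(16, 25, 35), 4, 4); Ar <- 0.4 * Br
  mk <- function(B, A, k) lapply(ph, function(p) k * (B + A * cos(p)))
  for (k in c(1, 0.2, 13)) {
    m <- do.call(demodulate, mk(B, A, k))
    r <- do.call(demodulate, mk(Br, Ar, k))
    out <- calibrate(m, r, 0.55, 0.18)
    if (k == 1) base <- out
    expect_equal(out$rd0, base$rd0, tolerance = 1e-10)
    expect_equal(out$rd1, base$rd1, tolerance = 1e-10)
  }
})

test_that("near-zero reference pixels are flagged invalid", {
  ref <- list(m0 = matrix(c(0, rep(10, 8)), 3, 3),
              m1 = matrix(c(0, rep(4, 8)), 3, 3))
  meas <- list(m0 = matrix(5, 3, 3), m1 = matrix(2, 3, 3))
  out <- calibrate(meas, ref, 0.5, 0.2)
  expect_true(is.na(out$rd0[1, 1]))
  expect_false(anyNA(out$rd0[-1]))
})

test_that("phantom reference reflectance follows the two-point power law", {
  sf <- fitScatterPowerLaw(c(7.1, 5.3), c(690, 830))
  # independent two-point solution: b = ln(7.1/5.3) / ln(830/690)
  expect_equal(sf$b, log(7.1 / 5.3) / log(830 / 690), tolerance = 1e-12)
  rdRef <- phantomReferenceRd(miniLUTs()$homogeneous)
  expect_identical(length(rdRef@rd0), 3L)
  expect_true(all(rdRef@rd0 > 0 & rdRef@rd0 < 1))
  expect_true(all(rdRef@rd1 > 0 & rdRef@rd1 < rdRef@rd0))
  # red wavelength sees the strongest scattering hence largest Rd
  expect_gt(rdRef@rd0[1], rdRef@rd0[3])
})

test_that("raw-stack synthesis closes the loop through demod + calibration", {
  rdRef <- phantomReferenceRd(miniLUTs()$homogeneous)
  truth <- new("SfdReflectance", wavelength = c(662, 735, 859),
               rd0 = c(0.41, 0.54, 0.60), rd1 = c(0.17, 0.18, 0.17),
               se0 = rep(0, 3), se1 = rep(0, 3), fx = c(0, 0.1))
  st <- makeRawStack(truth, rdRef, nx = 24, ny = 20, seed = 2)
  out <- calibrateStack(st)
  for (i in 1:3) {
    expect_lt(max(abs(out[[i]]$rd0 - truth@rd0[i]) / truth@rd0[i]), 1e-6)
    expect_lt(max(abs(out[[i]]$rd1 - truth@rd1[i]) / truth@rd1[i]), 1e-6)
  }
  # identical seeds give bit-identical stacks
  st2 <- makeRawStack(truth, rdRef, nx = 24, ny = 20, seed = 2)
  expect_identical(st$frames, st2$frames)
})

test_that("stacks round-trip through TIFF + YAML sidecar files", {
  rdRef <- phantomReferenceRd(miniLUTs()$homogeneous)
  truth <- new("SfdReflectance", wavelength = c(662, 735, 859),
               rd0 = c(0.4, 0.5, 0.6), rd1 = c(0.15, 0.17, 0.16),
               se0 = rep(0, 3), se1 = rep(0, 3), fx = c(0, 0.1))
  st <- makeRawStack(truth, rdRef, nx = 16, ny = 16, seed = 3)
  d <- file.path(tempdir(), "stackio")
  paths <- writeSfdiStack(st, d)
  back <- readSfdiStack(paths[["sidecar"]])
  expect_equal(back$frames, st$frames, tolerance = 1e-6)
  out <- calibrateStack(back)
  expect_lt(max(abs(out[[2]]$rd0 - truth@rd0[2])), 1e-5)
  unlink(d, recursive = TRUE)
})

test_that("blank marker frames locate the sequence start", {
  bright <- matrix(100, 6, 6)
  blank <- matrix(1, 6, 6)
  frames <- c(list(bright, bright), list(blank, blank, blank),
              replicate(9, bright, simplify = FALSE))
  det <- detectSequenceStart(frames)
  expect_identical(which(det$blank), 3:5)
  expect_identical(det$start, 6L)
})
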