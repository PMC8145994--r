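#' @include demod.R
NULL

# evaluate expr under a temporary R RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Construct a software-phantom specification
#'
#' @param mi melanin index.
#' @param depi epidermal thickness (cm), default the model value 0.011.
#' @param tHb total hemoglobin (micromolar), default 20 (healthy breast).
#' @param stO2 oxygen saturation (fraction), default 0.75.
#' @param muspEpi epidermal reduced scattering per wavelength (cm^-1).
#' @param muspSub subcutaneous reduced scattering per wavelength (cm^-1).
#' @param wavelength nm.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(mi, depi = 0.011, tHb = 20, stO2 = 0.75,
                        muspEpi = c(22.16, 16.89, 11.62),
                        muspSub = c(10.21, 8.94, 7.78),
                        wavelength = c(662, 735, 859)) {
  new("PhantomSpec", mi = mi, depi = depi, wavelength = wavelength,
      muspEpi = muspEpi, muspSub = muspSub, tHb = tHb, stO2 = stO2)
}

#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: MI = %.3f, d_epi = %g cm, tHb = %g uM, StO2 = %.0f%%\n",
    object@mi, object@depi, object@tHb, 100 * object@stO2))
})

#' Forward-simulate the diffuse reflectance of a software phantom
#'
#' Builds the subcutaneous absorption from the phantom's hemodynamic state,
#' the epidermal absorption from its melanin index, runs one white Monte
#' Carlo simulation per wavelength at the phantom's scattering values and
#' scores Rd at both spatial frequencies.
#'
#' @param spec a [PhantomSpec-class].
#' @param nPhotons photons per wavelength simulation.
#' @param seed base seed; per-wavelength streams are derived from it.
#' @param fx spatial frequencies (mm^-1).
#' @param paths optional pre-run list of [PhotonPaths-class] (one per
#'   wavelength, matching the spec's scattering) to rescale instead of
#'   running fresh simulations.
#' @return an [SfdReflectance-class] with one entry per wavelength.
#' @export
makeForwardRd <- function(spec, nPhotons = 2e5, seed = 1, fx = c(0, 0.1),
                          paths = NULL) {
  validObject(spec)
  wl <- spec@wavelength
  muaSub <- hemoglobinMua(spec@tHb, spec@stO2, wl)
  muaEpi <- miToMuaEpi(spec@mi, wl, spec@depi)
  rd0 <- se0 <- rd1 <- se1 <- numeric(length(wl))
  for (i in seq_along(wl)) {
    p <- if (is.null(paths)) {
      med <- skinMedium(c(spec@depi, 10), c(spec@muspEpi[i], spec@muspSub[i]))
      runWhiteMC(med, nPhotons, seed = seed * 100 + i)
    } else paths[[i]]
    sc <- scoreSFD(p, c(muaEpi[i], muaSub[i]), fx = fx, wavelength = wl[i])
    rd0[i] <- sc@rd0; rd1[i] <- sc@rd1; se0[i] <- sc@se0; se1[i] <- sc@se1
  }
  new("SfdReflectance", wavelength = wl, rd0 = rd0, rd1 = rd1, se0 = se0,
      se1 = se1, fx = fx)
}

#' Instrument-noise preset for synthetic acquisitions
#'
#' Declared noise defaults for the synthetic generator: signal-proportional
#' (shot-like) noise, additive read noise, optional specular-glint discs and
#' a slow multiplicative baseline drift. All zero-able; validation batteries
#' run noise-free.
#'
#' @param shot SD of multiplicative noise as a fraction of signal
#'   (default 0.005).
#' @param read SD of additive noise as a fraction of full scale
#'   (default 0.001).
#' @param specularN number of planted specular discs.
#' @param specularRadius disc radius in pixels.
#' @param specularLevel apparent reflectance inside a disc (far above
#'   tissue levels).
#' @param drift multiplicative drift rate per second.
#' @return named list of noise parameters.
#' @export
noiseModel <- function(shot = 0.005, read = 0.001, specularN = 0,
                       specularRadius = 4, specularLevel = 1.8,
                       drift = 0) {
  stopifnot(shot >= 0, read >= 0, specularN >= 0, drift >= 0)
  list(shot = shot, read = read, specularN = specularN,
       specularRadius = specularRadius, specularLevel = specularLevel,
       drift = drift)
}

# smooth static heterogeneity field: low-resolution Gaussian draw,
# bilinearly upsampled, zero mean, unit SD
smoothField <- function(ny, nx, coarse = 6) {
  z <- matrix(rnorm(coarse * coarse), coarse, coarse)
  ry <- seq(1, coarse, length.out = ny)
  rx <- seq(1, coarse, length.out = nx)
  iy <- pmin(floor(ry), coarse - 1L); ty <- ry - iy
  ix <- pmin(floor(rx), coarse - 1L); tx <- rx - ix
  f <- outer(seq_len(ny), seq_len(nx), function(a, b) {
    (1 - ty[a]) * (1 - tx[b]) * z[cbind(iy[a], ix[b])] +
      ty[a] * (1 - tx[b]) * z[cbind(iy[a] + 1L, ix[b])] +
      (1 - ty[a]) * tx[b] * z[cbind(iy[a], ix[b] + 1L)] +
      ty[a] * tx[b] * z[cbind(iy[a] + 1L, ix[b] + 1L)]
  })
  (f - mean(f)) / sd(f)
}

#' Synthesize a raw three-phase frame stack with matching reference
#'
#' Inverse of the demodulation/calibration chain: per wavelength, three
#' phase-shifted sinusoidal frames are built whose demodulation and
#' calibration against the emitted reference-phantom stack reproduce the
#' requested diffuse reflectance exactly in the noise-free limit. Noise,
#' specular discs and drift are then injected per the noise model, and every
#' planted artifact is recorded in the ground-truth sidecar.
#'
#' @param rdTruth an [SfdReflectance-class], target tissue reflectance per
#'   wavelength.
#' @param rdRef an [SfdReflectance-class], theoretical reflectance of the
#'   reference phantom (same wavelengths).
#' @param nx,ny image size in pixels.
#' @param pixelPitch mm per pixel.
#' @param gain illumination/camera scale (counts at full reflectance).
#' @param noise a [noiseModel()] list.
#' @param seed RNG seed.
#' @return list with \code{frames} and \code{reference} arrays
#'   [ny, nx, phase, wavelength] and a \code{sidecar} list (wavelengths, fx,
#'   phases, pixel pitch, gain, ground truth, planted artifacts).
#' @export
makeRawStack <- function(rdTruth, rdRef, nx = 64, ny = 64, pixelPitch = 0.78,
                         gain = 1000, noise = noiseModel(shot = 0, read = 0),
                         seed = 1) {
  if (any(rdTruth@rd0 <= 0 | rdTruth@rd0 >= 1))
    stop("rdTruth must lie strictly inside (0, 1)")
  if (is.null(pixelPitch) || !is.finite(pixelPitch))
    stop("pixel pitch must be set")
  wl <- rdTruth@wavelength
  fxMod <- rdTruth@fx[2L]                      # mm^-1
  phases <- 2 * pi * (0:2) / 3
  phaseMap <- outer(rep(1, ny), 2 * pi * fxMod * pixelPitch * (seq_len(nx) - 1))
  build <- function(rdObj) {
    a <- array(NA_real_, c(ny, nx, 3L, length(wl)))
    for (i in seq_along(wl))
      for (p in 1:3)
        a[, , p, i] <- 0.5 * gain *
          (rdObj@rd0[i] + rdObj@rd1[i] * cos(phaseMap + phases[p]))
    a
  }
  frames <- build(rdTruth)
  reference <- build(rdRef)
  artifacts <- list()
  withSeed(seed, {
    if (noise$specularN > 0) {
      for (s in seq_len(noise$specularN)) {
        cx <- sample(seq_len(nx), 1L); cy <- sample(seq_len(ny), 1L)
        d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`)
        disc <- d2 <= noise$specularRadius^2
        for (i in seq_along(wl)) for (p in 1:3)
          frames[, , p, i][disc] <- 0.5 * gain * noise$specularLevel
        artifacts[[s]] <- list(x = cx, y = cy, radius = noise$specularRadius)
      }
    }
    if (noise$shot > 0 || noise$read > 0) {
      nz <- function(a) a * (1 + noise$shot * array(rnorm(length(a)), dim(a))) +
        noise$read * gain * array(rnorm(length(a)), dim(a))
      frames <- pmax(nz(frames), 0)
      reference <- pmax(nz(reference), 0)
    }
  })
  list(frames = frames, reference = reference,
       sidecar = list(wavelengths = wl, fx = rdTruth@fx, phases = phases,
                      pixelPitch = pixelPitch, gain = gain, seed = seed,
                      truth = list(rd0 = rdTruth@rd0, rd1 = rdTruth@rd1),
                      reference = list(rd0 = rdRef@rd0, rd1 = rdRef@rd1),
                      artifacts = artifacts))
}

#' Synthesize a dynamic breast-compression measurement
#'
#' Generates a calibrated diffuse-reflectance movie over a circular field of
#' view for the 1-min baseline / 1-min compression / 1-min recovery
#' protocol: total hemoglobin follows a U-shaped blanching dip during
#' compression and recovers on release; oxygen saturation follows a linear
#' compression trend with per-ROI slope jitter; a smooth static
#' heterogeneity field modulates the hemoglobin map. Hemodynamics are mapped
#' to reflectance through the two-layer forward tables, and the ground truth
#' (per-ROI traces, slopes, planted artifacts) is emitted in the movie's
#' truth sidecar.
#'
#' @param luts list of [TwoLayerLUT-class], one per wavelength.
#' @param mi melanin index of the simulated skin.
#' @param tHb,stO2 baseline hemodynamics (micromolar, fraction).
#' @param thbDip depth of the compression blanching dip (micromolar).
#' @param sto2Slope mean StO2 compression slope (percentage points per
#'   second).
#' @param slopeJitterSd per-ROI SD of the compression slope (pp/s).
#' @param muspSub subcutaneous scattering per wavelength (cm^-1).
#' @param nx,ny frame size (pixels); pixel pitch is fovDiameter / nx.
#' @param fovDiameter circular field of view (mm).
#' @param cadence seconds between frames.
#' @param timeline durations (s) of baseline, compression, recovery.
#' @param heterogeneity fractional SD of the static tHb field.
#' @param rdStructure fractional SD of a smooth static multiplicative field
#'   applied to the reflectance maps, emulating the residual spatial
#'   structure (tissue texture, curvature, flat-field remnants) that
#'   calibrated in-vivo Rd images carry. Real frames are dominated by this
#'   static structure rather than by frame noise, which is what makes the
#'   per-frame SD-based specular rejection selective; a perfectly flat
#'   synthetic field would let temporal noise alone trip the threshold at
#'   some frame for almost every pixel.
#' @param noise a [noiseModel()] list applied to the reflectance stack.
#' @param seed RNG seed.
#' @return an [SfdiMovie-class].
#' @export
makeCompressionMovie <- function(luts, mi = 0.1, tHb = 20, stO2 = 0.75,
                                 thbDip = 4, sto2Slope = -0.011,
                                 slopeJitterSd = 0.004,
                                 muspSub = c(10.21, 8.94, 7.78),
                                 nx = 48, ny = 48, fovDiameter = 50,
                                 cadence = 2,
                                 timeline = c(baseline = 60,
                                              compression = 60,
                                              recovery = 60),
                                 heterogeneity = 0.02, rdStructure = 0.02,
                                 noise = noiseModel(), seed = 1) {
  if (thbDip >= tHb) stop("blanching dip must be smaller than baseline tHb")
  wl <- vapply(luts, function(l) l@wavelength, 1.0)
  depi <- luts[[1L]]@depiModel
  nt <- floor(sum(timeline) / cadence)
  times <- (seq_len(nt) - 1) * cadence
  tOn <- timeline[[1L]]; tOff <- timeline[[1L]] + timeline[[2L]]
  pixelPitch <- fovDiameter / nx
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`)
  fov <- d2 <= (fovDiameter / 2 / pixelPitch)^2
  rois <- partitionROIs(fov)

  collapsed <- lapply(seq_along(wl), function(i)
    refineLUT(collapseLUT(luts[[i]], miToMuaEpi(mi, wl[i], depi))))
  eps <- log(10) * hbExtinction(wl)

  rd <- array(NA_real_, c(ny, nx, length(wl), 2L, nt))
  truth <- NULL
  withSeed(seed, {
    het <- 1 + heterogeneity * smoothField(ny, nx)
    slopes <- sto2Slope + rnorm(8L, 0, slopeJitterSd)    # pp/s, per ROI
    slopePx <- matrix(0, ny, nx)
    for (r in 1:8) slopePx[rois == r] <- slopes[r]
    # temporal templates
    dipT <- ifelse(times >= tOn & times < tOff,
                   0.5 * (1 - cos(2 * pi * (times - tOn) / timeline[[2L]])),
                   0)
    dsto2T <- ifelse(times < tOn, 0,
                     ifelse(times < tOff, times - tOn,
                            pmax(0, (timeline[[2L]]) *
                                   (1 - (times - tOff) / 20))))
    thbRoi <- matrix(NA_real_, nt, 8L)
    sto2Roi <- matrix(NA_real_, nt, 8L)
    for (it in seq_len(nt)) {
      thbMap <- tHb * het - thbDip * dipT[it]
      sto2Map <- stO2 + (slopePx / 100) * dsto2T[it]
      c1 <- thbMap * sto2Map * 1e-6
      c2 <- thbMap * (1 - sto2Map) * 1e-6
      for (i in seq_along(wl)) {
        mua <- eps[i, 1L] * c1 + eps[i, 2L] * c2
        fwd <- forwardRd(collapsed[[i]], as.vector(mua),
                         rep(muspSub[i], length(mua)))
        rd[, , i, 1L, it] <- fwd$rd0
        rd[, , i, 2L, it] <- fwd$rd1
      }
      for (r in 1:8) {
        thbRoi[it, r] <- mean(thbMap[rois == r])
        sto2Roi[it, r] <- mean(sto2Map[rois == r])
      }
    }
    if (rdStructure > 0) {
      struct <- 1 + rdStructure * smoothField(ny, nx)
      rd <- rd * as.vector(struct)   # recycles over the trailing dims
    }
    specMask <- matrix(FALSE, ny, nx)
    if (noise$specularN > 0) {
      for (s in seq_len(noise$specularN)) {
        px <- sample(which(fov), 1L)
        sy <- (px - 1L) %% ny + 1L; sx <- (px - 1L) %/% ny + 1L
        disc <- outer((seq_len(ny) - sy)^2, (seq_len(nx) - sx)^2, `+`) <=
          noise$specularRadius^2
        specMask <- specMask | disc
      }
      for (i in seq_along(wl)) for (j in 1:2) for (it in seq_len(nt))
        rd[, , i, j, it][specMask] <- noise$specularLevel
    }
    if (noise$shot > 0 || noise$read > 0)
      rd <- pmax(rd * (1 + noise$shot * array(rnorm(length(rd)), dim(rd))) +
                   noise$read * array(rnorm(length(rd)), dim(rd)), 1e-6)
    if (noise$drift > 0) {
      dr <- 1 + noise$drift * times
      rd <- sweep(rd, 5L, dr, `*`)
    }
    truth <- list(mi = mi, tHb = tHb, stO2 = stO2, thbDip = thbDip,
                   muspSub = muspSub, roiSlopes = slopes,
                   thbRoi = thbRoi, sto2Roi = sto2Roi, rois = rois,
                   specular = specMask, seed = seed)
  })
  new("SfdiMovie", rd = rd, times = times, wavelength = wl, fx = c(0, 0.1),
      pixelPitch = pixelPitch, fovMask = fov, pressure = numeric(0),
      timeline = c(baseline = 0, compression = tOn, recovery = tOff,
                   end = sum(timeline)),
      truth = truth)
}

#' @export
setMethod("show", "SfdiMovie", function(object) {
  d <- dim(object@rd)
  cat(sprintf(
    "SfdiMovie: %d x %d px, %d wavelengths, %d frames every %gs (%gs total)\n",
    d[1L], d[2L], d[3L], d[5L], diff(object@times[1:2]),
    max(object@times)))
})
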