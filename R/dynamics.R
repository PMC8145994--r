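#' @include synthetic.R
NULL

#' Reject specular/artifact pixels from demodulated magnitude stacks
#'
#' A pixel is excluded for the whole measurement if its planar magnitude
#' M(0) deviates from the per-frame image mean by more than \code{nSD}
#' standard deviations at any timepoint or wavelength. Statistics are
#' computed per frame (one mean/SD per wavelength and timepoint) over the
#' field of view.
#'
#' @param m0 array [y, x, wavelength, time] of planar magnitudes (any common
#'   scale; the criterion is scale-invariant).
#' @param fovMask optional logical matrix restricting the statistics and the
#'   mask to the field of view.
#' @param nSD rejection threshold in standard deviations (default 2.5).
#' @return logical matrix [y, x]: TRUE = rejected.
#' @export
rejectSpecularPixels <- function(m0, fovMask = NULL, nSD = 2.5) {
  d <- dim(m0)
  if (length(d) == 2L) m0 <- array(m0, c(d, 1L, 1L))
  if (length(dim(m0)) == 3L) m0 <- array(m0, c(dim(m0), 1L))
  d <- dim(m0)
  if (is.null(fovMask)) fovMask <- matrix(TRUE, d[1L], d[2L])
  rejected <- matrix(FALSE, d[1L], d[2L])
  for (i in seq_len(d[3L])) {
    for (t in seq_len(d[4L])) {
      fr <- m0[, , i, t]
      v <- fr[fovMask]
      m <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      rejected <- rejected | (fovMask & (abs(fr - m) > nSD * s))
    }
  }
  rejected[!fovMask] <- FALSE
  if (all(rejected[fovMask]))
    stop("specular rejection removed every pixel in the field of view")
  rejected
}

#' Average baseline diffuse reflectance for the melanin-index fit
#'
#' Mean reflectance over retained pixels and the closed baseline window
#' (default t in [10, 55] s, skipping early repositioning), per wavelength
#' and spatial frequency.
#'
#' @param movie an [SfdiMovie-class].
#' @param rejected optional logical matrix of pixels to exclude.
#' @param window closed time window (s).
#' @return an [SfdReflectance-class] with one entry per wavelength.
#' @export
baselineAverageRd <- function(movie, rejected = NULL, window = c(10, 55)) {
  keepT <- which(movie@times >= window[1L] & movie@times <= window[2L])
  if (length(keepT) < 2L) stop("fewer than two frames in the baseline window")
  keepPx <- movie@fovMask
  if (!is.null(rejected)) keepPx <- keepPx & !rejected
  if (!any(keepPx)) stop("no retained pixels")
  nwl <- length(movie@wavelength)
  rd0 <- rd1 <- numeric(nwl)
  for (i in seq_len(nwl)) {
    sub0 <- movie@rd[, , i, 1L, keepT, drop = FALSE]
    sub1 <- movie@rd[, , i, 2L, keepT, drop = FALSE]
    sel <- array(keepPx, dim(sub0)[1:2])
    rd0[i] <- mean(apply(sub0, 5L, function(f) mean(f[sel], na.rm = TRUE)))
    rd1[i] <- mean(apply(sub1, 5L, function(f) mean(f[sel], na.rm = TRUE)))
  }
  new("SfdReflectance", wavelength = movie@wavelength, rd0 = rd0, rd1 = rd1,
      se0 = rep(0, nwl), se1 = rep(0, nwl), fx = movie@fx)
}

#' Reject pixels with aberrant dynamic absorption
#'
#' A pixel is excluded if its inverted subcutaneous absorption at any
#' wavelength or timepoint deviates by more than \code{nSD} standard
#' deviations from the central-region statistics (a ~20 mm square at the
#' image center, pooled over time per wavelength).
#'
#' @param muaSub array [y, x, wavelength, time] (cm^-1).
#' @param pixelPitch mm per pixel, defines the central square.
#' @param nSD threshold (default 8).
#' @param centralMm side of the central reference square (mm).
#' @param fovMask optional logical matrix.
#' @return logical matrix [y, x]: TRUE = rejected.
#' @export
rejectDynamicPixels <- function(muaSub, pixelPitch, nSD = 8,
                                centralMm = 20, fovMask = NULL) {
  d <- dim(muaSub)
  half <- round(centralMm / pixelPitch / 2)
  cy <- round(d[1L] / 2); cx <- round(d[2L] / 2)
  ys <- max(1L, cy - half):min(d[1L], cy + half)
  xs <- max(1L, cx - half):min(d[2L], cx + half)
  if (length(ys) < 3L || length(xs) < 3L)
    stop("central reference region smaller than 3 x 3 pixels")
  rejected <- matrix(FALSE, d[1L], d[2L])
  for (i in seq_len(d[3L])) {
    ref <- muaSub[ys, xs, i, ]
    m <- mean(ref, na.rm = TRUE)
    s <- sd(ref, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    dev <- apply(abs(muaSub[, , i, , drop = FALSE] - m) > nSD * s, c(1L, 2L),
                 any, na.rm = TRUE)
    rejected <- rejected | dev
  }
  if (!is.null(fovMask)) rejected[!fovMask] <- FALSE
  rejected
}

#' Partition a circular field of view into regions of interest
#'
#' Default scheme: eight equal-area 45-degree angular sectors, numbered
#' clockwise starting from image-up. A 2 x 4 rectangular grid is available
#' as an alternative.
#'
#' @param fovMask logical matrix, TRUE inside the circular field of view.
#' @param n number of regions (8 for sectors; any composite for grid).
#' @param scheme "sector" or "grid".
#' @return integer matrix of ROI labels (0 outside the field of view).
#' @export
partitionROIs <- function(fovMask, n = 8, scheme = c("sector", "grid")) {
  scheme <- match.arg(scheme)
  d <- dim(fovMask)
  idx <- which(fovMask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty field-of-view mask")
  cy <- mean(range(idx[, 1L])); cx <- mean(range(idx[, 2L]))
  lab <- matrix(0L, d[1L], d[2L])
  if (scheme == "sector") {
    dy <- idx[, 1L] - cy; dx <- idx[, 2L] - cx
    # angle measured clockwise from image-up (-y direction)
    ang <- atan2(dx, -dy) %% (2 * pi)
    lab[idx] <- as.integer(pmin(floor(ang / (2 * pi / n)), n - 1) + 1L)
  } else {
    nrow2 <- floor(sqrt(n))
    while (n %% nrow2 != 0) nrow2 <- nrow2 - 1L   # e.g. 8 -> 2 x 4
    ncol2 <- n %/% nrow2
    ry <- pmin(floor((idx[, 1L] - min(idx[, 1L])) /
                       (diff(range(idx[, 1L])) + 1e-9) * nrow2), nrow2 - 1)
    rx <- pmin(floor((idx[, 2L] - min(idx[, 2L])) /
                       (diff(range(idx[, 2L])) + 1e-9) * ncol2), ncol2 - 1)
    lab[idx] <- as.integer(ry * ncol2 + rx + 1L)
  }
  lab
}

#' Screen an ROI's baseline for stability
#'
#' Linear fit of the StO2 trace over the closed baseline window; the region
#' is kept only if the slope magnitude is at most \code{maxSlope}
#' (percentage points per second) and the root-mean-square deviation from
#' the fit is at most \code{maxRms} (percentage points).
#'
#' @param stO2 saturation trace (fraction).
#' @param times timestamps (s).
#' @param window closed window (s), default [10, 55].
#' @param maxSlope,maxRms rejection thresholds (pp/s, pp).
#' @return list with \code{slope} (pp/s), \code{rms} (pp) and \code{keep}.
#' @export
screenBaseline <- function(stO2, times, window = c(10, 55),
                           maxSlope = 0.045, maxRms = 0.4) {
  sel <- times >= window[1L] & times <= window[2L]
  if (sum(sel) < 3L) stop("fewer than three points in the baseline window")
  y <- 100 * stO2[sel]              # percentage points
  x <- times[sel]
  fit <- lm.fit(cbind(1, x), y)
  slope <- unname(coef(fit)[2L])
  rms <- sqrt(mean(fit$residuals^2))
  list(slope = slope, rms = rms,
       keep = abs(slope) <= maxSlope && rms <= maxRms)
}

#' Rate of change of StO2 during compression
#'
#' Least-squares slope of the saturation trace over the compression window
#' (default t in [65, 113] s), in percentage points per second.
#'
#' @inheritParams screenBaseline
#' @param window closed window (s), default [65, 113].
#' @return slope (pp/s).
#' @export
compressionSlope <- function(stO2, times, window = c(65, 113)) {
  sel <- times >= window[1L] & times <= window[2L]
  if (sum(sel) < 3L) stop("fewer than three points in the compression window")
  fit <- lm.fit(cbind(1, times[sel]), 100 * stO2[sel])
  unname(coef(fit)[2L])
}

#' Screen an ROI for optical artifacts
#'
#' @param roiMask logical matrix for one region.
#' @param rejectedMask logical matrix of rejected pixels.
#' @param maxFrac maximum tolerated rejected fraction (strict inequality;
#'   exactly 60% is kept).
#' @return TRUE to keep the region.
#' @export
roiArtifactScreen <- function(roiMask, rejectedMask, maxFrac = 0.6) {
  frac <- mean(rejectedMask[roiMask])
  !(frac > maxFrac)
}

#' Process a dynamic compression measurement into per-ROI hemodynamics
#'
#' Full dynamic pipeline: specular-pixel rejection on the planar magnitude
#' stack, per-pixel two-layer inversion at the supplied melanin index,
#' dynamic-absorption pixel rejection, per-pixel hemoglobin unmixing, ROI
#' partition, baseline-stability screening and compression-slope fits.
#' Every rejection is logged with its reason and the result is
#' deterministic for a given input.
#'
#' @param movie an [SfdiMovie-class].
#' @param luts list of [TwoLayerLUT-class], one per wavelength.
#' @param mi melanin index at which to collapse the tables.
#' @param nSDSpecular,nSDDynamic,maxSlope,maxRms,maxArtifactFrac thresholds
#'   (defaults 2.5 SD, 8 SD, 0.045 pp/s, 0.4 pp, 60%).
#' @param baselineWindow,slopeWindow time windows (s).
#' @return list with \code{rois} (data.frame: roi, baseline slope/rms,
#'   compression slope, rejected flag + reason), \code{thb}/\code{sto2}
#'   ROI trace matrices, the pixel masks, and the per-pixel hemodynamic
#'   arrays.
#' @export
processCompression <- function(movie, luts, mi,
                               nSDSpecular = 2.5, nSDDynamic = 8,
                               maxSlope = 0.045, maxRms = 0.4,
                               maxArtifactFrac = 0.6,
                               baselineWindow = c(10, 55),
                               slopeWindow = c(65, 113)) {
  wl <- movie@wavelength
  d <- dim(movie@rd)
  m0 <- movie@rd[, , , 1L, , drop = FALSE]
  dim(m0) <- d[c(1L, 2L, 3L, 5L)]
  specRej <- rejectSpecularPixels(m0, movie@fovMask, nSD = nSDSpecular)

  depi <- luts[[1L]]@depiModel
  collapsed <- lapply(seq_along(wl), function(i)
    refineLUT(collapseLUT(luts[[i]], miToMuaEpi(mi, wl[i], depi))))
  npx <- d[1L] * d[2L]; nt <- d[5L]
  muaSub <- array(NA_real_, c(d[1L], d[2L], length(wl), nt))
  oobFrac <- numeric(length(wl))
  for (i in seq_along(wl)) {
    q0 <- as.vector(movie@rd[, , i, 1L, ])
    q1 <- as.vector(movie@rd[, , i, 2L, ])
    inv <- invertRd(collapsed[[i]], q0, q1)
    muaSub[, , i, ] <- array(inv$mua, c(d[1L], d[2L], nt))
    oobFrac[i] <- mean(inv$oob)
  }
  dynRej <- rejectDynamicPixels(muaSub, movie@pixelPitch, nSD = nSDDynamic,
                                fovMask = movie@fovMask)
  rejected <- specRej | dynRej

  eps <- log(10) * hbExtinction(wl)
  P <- solve(crossprod(eps), t(eps))
  muaMat <- matrix(aperm(muaSub, c(1L, 2L, 4L, 3L)), ncol = length(wl))
  conc <- muaMat %*% t(P) * 1e6          # uM
  thbPx <- array(conc[, 1L] + conc[, 2L], c(d[1L], d[2L], nt))
  sto2Px <- array(conc[, 1L] / (conc[, 1L] + conc[, 2L]),
                  c(d[1L], d[2L], nt))

  rois <- partitionROIs(movie@fovMask)
  nroi <- max(rois)
  thbRoi <- matrix(NA_real_, nt, nroi)
  sto2Roi <- matrix(NA_real_, nt, nroi)
  tab <- data.frame(roi = seq_len(nroi), baselineSlope = NA_real_,
                    baselineRms = NA_real_, compressionSlope = NA_real_,
                    rejected = FALSE, reason = "", stringsAsFactors = FALSE)
  for (r in seq_len(nroi)) {
    rm <- rois == r
    keepPx <- rm & !rejected
    if (!roiArtifactScreen(rm, rejected, maxArtifactFrac)) {
      tab$rejected[r] <- TRUE
      tab$reason[r] <- "artifact"
      next
    }
    for (it in seq_len(nt)) {
      thbRoi[it, r] <- mean(thbPx[, , it][keepPx], na.rm = TRUE)
      sto2Roi[it, r] <- mean(sto2Px[, , it][keepPx], na.rm = TRUE)
    }
    scr <- screenBaseline(sto2Roi[, r], movie@times, baselineWindow,
                          maxSlope, maxRms)
    tab$baselineSlope[r] <- scr$slope
    tab$baselineRms[r] <- scr$rms
    if (!scr$keep) {
      tab$rejected[r] <- TRUE
      tab$reason[r] <- "baseline-unstable"
      next
    }
    tab$compressionSlope[r] <- compressionSlope(sto2Roi[, r], movie@times,
                                                slopeWindow)
  }
  list(rois = tab, thb = thbRoi, sto2 = sto2Roi, roiLabels = rois,
       rejectedMask = rejected, specularMask = specRej,
       dynamicMask = dynRej, muaSub = muaSub, thbPx = thbPx,
       sto2Px = sto2Px, oobFraction = oobFrac)
}
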