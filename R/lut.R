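#' @include transport.R
NULL

#' Device description for the handheld SFDI breast imager
#'
#' Default device constants: the three LED wavelengths, the two spatial
#' frequencies, the fixed epidermal scattering per wavelength, the model
#' epidermal thickness, typical healthy-breast subcutaneous scattering, and
#' the circular 50-mm field of view.
#'
#' @return a named list of device constants.
#' @export
sfdiDevice <- function() {
  list(wavelengths = c(662, 735, 859),
       fx = c(0, 0.1),                      # mm^-1
       musEpiPrime = c(22.16, 16.89, 11.62),  # cm^-1 at the three wavelengths
       depi = 0.011,                        # cm
       muspSubDefault = c(10.21, 8.94, 7.78),  # cm^-1
       g = 0.8, n = 1.4,
       fovDiameter = 50)                    # mm
}

# Beer-Lambert rescaling of white-MC records over a (mua1, mua2) grid.
# Returns rd0 and rd1 matrices of dim length(ax1) x length(ax2); relies on
# BLAS for the two cross products.
beerGrids <- function(paths, ax1, ax2, fxMod = 0.1) {
  L <- paths@pathlengths
  w <- paths@weight
  n <- paths@nPhotons
  E <- exp(-outer(L[, 1L], ax1))
  S <- exp(-outer(L[, 2L], ax2))
  j0 <- besselJ(2 * pi * (fxMod * 10) * paths@radius, 0)
  list(rd0 = crossprod(E, S * w) / n,
       rd1 = crossprod(E, S * (w * j0)) / n)
}

#' Assemble a two-layer lookup table from white Monte Carlo records
#'
#' Each element of \code{pathsList} holds the exit records of one two-layer
#' simulation (fixed epidermal scattering, one subcutaneous scattering value);
#' the (mua_epi, mua_sub) axes of the table are filled by Beer-Lambert
#' rescaling of the recorded per-layer pathlengths.
#'
#' @param pathsList list of [PhotonPaths-class], one per subcutaneous
#'   scattering value, in increasing musp_sub order.
#' @param wavelength nm tag of the table.
#' @param muaEpiAxis epidermal absorption axis (default 21 values, 0-20).
#' @param muaSubAxis subcutaneous absorption axis (default 75 values,
#'   0.01-0.75).
#' @param fx the two spatial frequencies (mm^-1).
#' @return a [TwoLayerLUT-class].
#' @export
buildTwoLayerLUT <- function(pathsList, wavelength,
                             muaEpiAxis = seq(0, 20, length.out = 21),
                             muaSubAxis = seq(0.01, 0.75, length.out = 75),
                             fx = c(0, 0.1)) {
  if (!length(pathsList)) stop("pathsList is empty")
  media <- lapply(pathsList, function(p) p@medium@layers)
  if (any(vapply(media, nrow, 1L) != 2L))
    stop("all record sets must come from two-layer media")
  muspSub <- vapply(media, function(m) m$musp[2L], 1.0)
  if (is.unsorted(muspSub, strictly = TRUE))
    stop("record sets must be ordered by increasing subcutaneous musp")
  musEpi <- unique(vapply(media, function(m) m$musp[1L], 1.0))
  depi <- unique(vapply(media, function(m) m$thickness[1L], 1.0))
  if (length(musEpi) != 1L || length(depi) != 1L)
    stop("epidermal layer must be identical across record sets")
  n1 <- length(muaEpiAxis); n2 <- length(muaSubAxis); n3 <- length(muspSub)
  rd0 <- array(NA_real_, c(n1, n2, n3))
  rd1 <- array(NA_real_, c(n1, n2, n3))
  for (k in seq_len(n3)) {
    g <- beerGrids(pathsList[[k]], muaEpiAxis, muaSubAxis, fx[2L])
    rd0[, , k] <- g$rd0
    rd1[, , k] <- pmin(g$rd1, g$rd0)
  }
  new("TwoLayerLUT", wavelength = wavelength, muaEpiAxis = muaEpiAxis,
      muaSubAxis = muaSubAxis, muspSubAxis = muspSub, musEpiPrime = musEpi,
      depiModel = depi, rd0Grid = rd0, rd1Grid = rd1,
      provenance = list(
        nPhotons = vapply(pathsList, function(p) p@nPhotons, 1.0),
        seeds = vapply(pathsList, function(p) p@seed, 1.0),
        maxPathlength = vapply(pathsList, function(p) p@maxPathlength, 1.0),
        fx = fx, package = as.character(packageVersion("twoLayerSFDI"))))
}

#' Assemble a homogeneous (single-layer) lookup table
#'
#' @param pathsList list of single-layer [PhotonPaths-class], one per
#'   reduced-scattering value, increasing.
#' @param muaAxis absorption axis (default 75 values, 0.01-0.75).
#' @param wavelength optional nm tag (a white-MC homogeneous table is
#'   wavelength-independent; the wavelength only selects which musp is used).
#' @param fx the two spatial frequencies (mm^-1).
#' @return a [HomogeneousLUT-class].
#' @export
buildHomogeneousLUT <- function(pathsList,
                                muaAxis = seq(0.01, 0.75, length.out = 75),
                                wavelength = NA_real_, fx = c(0, 0.1)) {
  musp <- vapply(pathsList, function(p) p@medium@layers$musp[1L], 1.0)
  if (is.unsorted(musp, strictly = TRUE))
    stop("record sets must be ordered by increasing musp")
  nmu <- length(muaAxis)
  rd0 <- matrix(NA_real_, nmu, length(musp))
  rd1 <- matrix(NA_real_, nmu, length(musp))
  for (k in seq_along(pathsList)) {
    p <- pathsList[[k]]
    L <- p@pathlengths[, 1L]
    S <- exp(-outer(L, muaAxis))
    j0 <- besselJ(2 * pi * (fx[2L] * 10) * p@radius, 0)
    rd0[, k] <- crossprod(S, p@weight) / p@nPhotons
    rd1[, k] <- pmin(crossprod(S, p@weight * j0) / p@nPhotons, rd0[, k])
  }
  new("HomogeneousLUT", wavelength = wavelength, muaAxis = muaAxis,
      muspAxis = musp, rd0Grid = rd0, rd1Grid = rd1,
      provenance = list(
        nPhotons = vapply(pathsList, function(p) p@nPhotons, 1.0),
        seeds = vapply(pathsList, function(p) p@seed, 1.0),
        fx = fx, package = as.character(packageVersion("twoLayerSFDI"))))
}

#' Build the full device lookup-table set
#'
#' Runs the white Monte Carlo battery for a device configuration: one
#' two-layer simulation per (wavelength, subcutaneous scattering) pair with
#' the wavelength's fixed epidermal scattering, plus (optionally) one
#' single-layer simulation per scattering value for the conventional
#' homogeneous table. Per-run seeds are derived deterministically from
#' \code{seed}.
#'
#' @param nPhotons photons per simulation; either a scalar or one value per
#'   subcutaneous scattering node, allowing denser sampling of the
#'   physiological scattering range (an importance allocation: inversion
#'   accuracy is driven by the nodes bracketing the measured tissue, while
#'   the outer nodes only shape the gamut).
#' @param seed base seed.
#' @param device device constants, see [sfdiDevice()].
#' @param muspSubAxis subcutaneous scattering axis (default 17 values, 4-20).
#' @param muaEpiAxis,muaSubAxis absorption axes of the two-layer table.
#' @param twoLayer build the two-layer tables?
#' @param homogeneous also build the homogeneous table?
#' @param maxPathlength termination cap (cm), see [runWhiteMC()].
#' @param verbose print progress?
#' @return list with elements \code{twoLayer} (one [TwoLayerLUT-class] per
#'   wavelength) and \code{homogeneous} (a [HomogeneousLUT-class] or NULL).
#' @export
buildDeviceLUTs <- function(nPhotons = 2e5, seed = 1, device = sfdiDevice(),
                            muspSubAxis = seq(4, 20, length.out = 17),
                            muaEpiAxis = seq(0, 20, length.out = 21),
                            muaSubAxis = seq(0.01, 0.75, length.out = 75),
                            twoLayer = TRUE, homogeneous = TRUE,
                            maxPathlength = 450, verbose = FALSE) {
  nPhotons <- rep_len(nPhotons, length(muspSubAxis))
  runIdx <- 0L
  twoLayerTabs <- if (twoLayer) vector("list", length(device$wavelengths))
                  else NULL
  if (twoLayer) names(twoLayerTabs) <- as.character(device$wavelengths)
  for (iw in if (twoLayer) seq_along(device$wavelengths) else integer(0)) {
    paths <- vector("list", length(muspSubAxis))
    for (k in seq_along(muspSubAxis)) {
      runIdx <- runIdx + 1L
      med <- skinMedium(c(device$depi, 10),
                        c(device$musEpiPrime[iw], muspSubAxis[k]),
                        g = device$g, n = device$n)
      if (verbose)
        message(sprintf("white MC %d: lambda=%g musp_sub=%.2f",
                        runIdx, device$wavelengths[iw], muspSubAxis[k]))
      paths[[k]] <- runWhiteMC(med, nPhotons[k], seed = seed * 1000 + runIdx,
                               maxPathlength = maxPathlength)
    }
    twoLayerTabs[[iw]] <- buildTwoLayerLUT(paths, device$wavelengths[iw],
                                           muaEpiAxis, muaSubAxis,
                                           device$fx)
  }
  hom <- NULL
  if (homogeneous) {
    paths <- vector("list", length(muspSubAxis))
    for (k in seq_along(muspSubAxis)) {
      runIdx <- runIdx + 1L
      med <- skinMedium(10, muspSubAxis[k], g = device$g, n = device$n)
      if (verbose)
        message(sprintf("white MC %d: homogeneous musp=%.2f", runIdx,
                        muspSubAxis[k]))
      paths[[k]] <- runWhiteMC(med, nPhotons[k], seed = seed * 1000 + runIdx,
                               maxPathlength = maxPathlength)
    }
    hom <- buildHomogeneousLUT(paths, muaSubAxis, fx = device$fx)
  }
  list(twoLayer = twoLayerTabs, homogeneous = hom)
}

#' @describeIn collapseLUT linear interpolation along the epidermal
#'   absorption axis only; an on-node value returns the exact slice.
#' @export
setMethod("collapseLUT", "TwoLayerLUT", function(lut, muaEpi) {
  ax <- lut@muaEpiAxis
  if (!is.finite(muaEpi) || muaEpi < ax[1L] || muaEpi > ax[length(ax)])
    stop(sprintf("muaEpi = %g outside the table axis [%g, %g]", muaEpi,
                 ax[1L], ax[length(ax)]))
  i <- findInterval(muaEpi, ax, rightmost.closed = TRUE)
  if (ax[i] == muaEpi) {
    rd0 <- lut@rd0Grid[i, , ]
    rd1 <- lut@rd1Grid[i, , ]
  } else {
    t <- (muaEpi - ax[i]) / (ax[i + 1L] - ax[i])
    rd0 <- (1 - t) * lut@rd0Grid[i, , ] + t * lut@rd0Grid[i + 1L, , ]
    rd1 <- (1 - t) * lut@rd1Grid[i, , ] + t * lut@rd1Grid[i + 1L, , ]
  }
  new("HomogeneousLUT", wavelength = lut@wavelength,
      muaAxis = lut@muaSubAxis, muspAxis = lut@muspSubAxis,
      rd0Grid = rd0, rd1Grid = rd1,
      provenance = c(lut@provenance,
                     list(collapsedAt = muaEpi,
                          musEpiPrime = lut@musEpiPrime,
                          depiModel = lut@depiModel)))
})

#' @describeIn invertRd piecewise-linear inversion over the two-triangle
#'   split of each forward-grid cell; exact at grid nodes. Queries outside
#'   the forward gamut are clamped to the nearest gamut-boundary point and
#'   flagged in the \code{oob} column.
#' @export
setMethod("invertRd", "HomogeneousLUT", function(table, rd0, rd1) {
  if (length(rd0) != length(rd1)) stop("rd0 and rd1 lengths differ")
  res <- cpp_invert_table(table@rd0Grid, table@rd1Grid, table@muaAxis,
                          table@muspAxis, as.numeric(rd0), as.numeric(rd1))
  data.frame(mua = res$mua, musp = res$musp, oob = res$oob)
})

# vectorized bilinear interpolation on a rectilinear grid
interpBilinear <- function(ax, ay, grid, qx, qy) {
  if (any(qx < ax[1L] - 1e-12) || any(qx > ax[length(ax)] + 1e-12) ||
      any(qy < ay[1L] - 1e-12) || any(qy > ay[length(ay)] + 1e-12))
    stop("query outside the grid axes")
  qx <- pmin(pmax(qx, ax[1L]), ax[length(ax)])
  qy <- pmin(pmax(qy, ay[1L]), ay[length(ay)])
  i <- pmin(pmax(findInterval(qx, ax), 1L), length(ax) - 1L)
  j <- pmin(pmax(findInterval(qy, ay), 1L), length(ay) - 1L)
  tx <- (qx - ax[i]) / (ax[i + 1L] - ax[i])
  ty <- (qy - ay[j]) / (ay[j + 1L] - ay[j])
  nr <- nrow(grid)
  g11 <- grid[cbind(i, j)];     g21 <- grid[cbind(i + 1L, j)]
  g12 <- grid[cbind(i, j + 1L)]; g22 <- grid[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * g11 + tx * (1 - ty) * g21 +
    (1 - tx) * ty * g12 + tx * ty * g22
}

#' @describeIn forwardRd bilinear interpolation at (mua, musp); vectorized.
#' @param mua,musp query optical properties (cm^-1).
#' @export
setMethod("forwardRd", "HomogeneousLUT", function(table, mua, musp) {
  list(rd0 = interpBilinear(table@muaAxis, table@muspAxis, table@rd0Grid,
                            mua, musp),
       rd1 = interpBilinear(table@muaAxis, table@muspAxis, table@rd1Grid,
                            mua, musp))
})

#' @describeIn forwardRd collapse at \code{muaEpi} (scalar), then bilinear
#'   interpolation at (muaSub, muspSub); vectorized over the latter.
#' @param muaEpi epidermal absorption (cm^-1), scalar.
#' @param muaSub,muspSub subcutaneous query properties (cm^-1).
#' @export
setMethod("forwardRd", "TwoLayerLUT", function(table, muaEpi, muaSub,
                                               muspSub) {
  forwardRd(collapseLUT(table, muaEpi), muaSub, muspSub)
})

# axis subdivided `factor` times per interval, original nodes retained
subdivideAxis <- function(ax, factor) {
  unique(sort(c(ax, unlist(lapply(seq_len(length(ax) - 1L),
    function(i) seq(ax[i], ax[i + 1L],
                    length.out = factor + 1L)[-c(1L, factor + 1L)])))))
}

# Catmull-Rom resampling of the rows of g (uniform axis ax -> newAx);
# interpolates original nodes exactly, captures curvature to cubic order.
cubicResampleRows <- function(g, ax, newAx) {
  n <- length(ax)
  out <- matrix(NA_real_, length(newAx), ncol(g))
  i <- pmin(pmax(findInterval(newAx, ax), 1L), n - 1L)
  t <- (newAx - ax[i]) / (ax[i + 1L] - ax[i])
  for (k in seq_along(newAx)) {
    tk <- t[k]
    if (tk == 0) { out[k, ] <- g[i[k], ]; next }
    w <- c(0.5 * (-tk + 2 * tk^2 - tk^3),
           0.5 * (2 - 5 * tk^2 + 3 * tk^3),
           0.5 * (tk + 4 * tk^2 - 3 * tk^3),
           0.5 * (-tk^2 + tk^3))
    idx <- pmin(pmax(i[k] + (-1L:2L), 1L), n)
    out[k, ] <- w[1L] * g[idx[1L], ] + w[2L] * g[idx[2L], ] +
      w[3L] * g[idx[3L], ] + w[4L] * g[idx[4L], ]
  }
  out
}

#' Refine a 2-D table before piecewise-linear inversion
#'
#' The forward map is visibly curved across one tabulated step in both
#' directions — strongly so along absorption, where reflectance decays like
#' a pathlength-weighted exponential — so piecewise-linear inversion on the
#' raw grid carries a convexity (chord) bias: a few tenths of a percent in
#' Rd, which inverts to ~1% in recovered absorption at mid-cell queries.
#' Refinement resamples the grid on a denser axis pair using a natural
#' cubic spline along scattering (per absorption row) and Catmull-Rom
#' cubics along absorption (per scattering column). Original nodes are
#' reproduced exactly, so node round trips stay exact.
#'
#' @param table a [HomogeneousLUT-class] (native or collapsed).
#' @param factor subdivision factor per original interval (default 4),
#'   applied to both axes.
#' @return a refined [HomogeneousLUT-class].
#' @export
refineLUT <- function(table, factor = 4L) {
  if (factor <= 1L) return(table)
  axS <- table@muspAxis
  axA <- table@muaAxis
  newS <- subdivideAxis(axS, factor)
  newA <- subdivideAxis(axA, factor)
  alongS <- function(g) t(apply(g, 1L, function(row)
    spline(axS, row, xout = newS, method = "natural")$y))
  rd0 <- cubicResampleRows(alongS(table@rd0Grid), axA, newA)
  rd1 <- cubicResampleRows(alongS(table@rd1Grid), axA, newA)
  rd0 <- pmax(rd0, 0)
  rd1 <- pmin(pmax(rd1, 0), rd0)
  new("HomogeneousLUT", wavelength = table@wavelength,
      muaAxis = newA, muspAxis = newS, rd0Grid = rd0, rd1Grid = rd1,
      provenance = c(table@provenance, list(refined = as.integer(factor))))
}

#' Serialize / restore lookup tables
#'
#' Tables round-trip bit-exactly through R's native serialization; all build
#' provenance travels inside the object.
#'
#' @param lut a lookup table (or the list returned by [buildDeviceLUTs()]).
#' @param path file path.
#' @export
writeLUT <- function(lut, path) {
  saveRDS(lut, path)
  invisible(path)
}

#' @rdname writeLUT
#' @export
readLUT <- function(path) {
  obj <- readRDS(path)
  ok <- is(obj, "TwoLayerLUT") || is(obj, "HomogeneousLUT") ||
    (is.list(obj) && all(c("twoLayer", "homogeneous") %in% names(obj)))
  if (!ok) stop("file does not contain a lookup table")
  obj
}

#' @export
setMethod("show", "TwoLayerLUT", function(object) {
  cat(sprintf(
    "TwoLayerLUT %g nm: %d x %d x %d grid (mua_epi, mua_sub, musp_sub)\n",
    object@wavelength, length(object@muaEpiAxis),
    length(object@muaSubAxis), length(object@muspSubAxis)))
  cat(sprintf("  mus'_epi = %.2f cm^-1, d_epi = %g cm, photons/run = %g\n",
              object@musEpiPrime, object@depiModel,
              object@provenance$nPhotons[1L]))
})

#' @export
setMethod("show", "HomogeneousLUT", function(object) {
  kind <- if (!is.null(object@provenance$collapsedAt))
    sprintf("collapsed two-layer (mua_epi = %.3g)",
            object@provenance$collapsedAt) else "homogeneous"
  cat(sprintf("HomogeneousLUT [%s]: %d x %d grid (mua, musp)\n", kind,
              length(object@muaAxis), length(object@muspAxis)))
})
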