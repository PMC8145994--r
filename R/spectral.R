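#' @include lut.R
NULL

# Compiled molar extinction coefficients of oxy- and deoxyhemoglobin
# (cm^-1 / M, base-10), standard whole-blood tabulation, 650-900 nm.
# Absorption is mu_a = ln(10) * eps * C with C in mol/L.
.hbTable <- data.frame(
  wavelength = c(650, 660, 670, 680, 690, 700, 710, 720, 730, 740, 750,
                 760, 770, 780, 790, 800, 810, 820, 830, 840, 850, 860,
                 870, 880, 890, 900),
  hbo2 = c(368.0, 319.6, 294.0, 277.6, 276.0, 290.0, 316.8, 353.2, 390.0,
           446.0, 518.0, 586.0, 650.0, 710.0, 756.0, 816.0, 864.0, 916.0,
           974.0, 1022.0, 1058.0, 1092.0, 1128.0, 1154.0, 1178.0, 1198.0),
  hb = c(3750.1, 3226.6, 2795.1, 2407.9, 2052.0, 1794.3, 1540.5, 1325.9,
         1102.2, 1115.9, 1405.2, 1548.5, 1311.9, 1075.4, 925.0, 761.7,
         717.1, 693.8, 693.0, 692.4, 691.3, 691.1, 660.0, 626.6, 613.3,
         602.0))

#' Hemoglobin molar extinction coefficients
#'
#' Linear interpolation of a compiled standard tabulation of oxy- and
#' deoxyhemoglobin molar extinction coefficients (cm^-1/M, base 10).
#' The deoxyhemoglobin spectrum carries the characteristic dip near 730-740
#' nm and peak near 760 nm that drive the structure of the spectral fit.
#'
#' @param wavelength wavelengths (nm) within 650-900.
#' @return matrix with columns \code{hbo2} and \code{hb}.
#' @examples
#' hbExtinction(c(662, 735, 859))
#' @export
hbExtinction <- function(wavelength) {
  if (any(wavelength < 650 | wavelength > 900))
    stop("tabulation covers 650-900 nm")
  cbind(hbo2 = approx(.hbTable$wavelength, .hbTable$hbo2, wavelength)$y,
        hb = approx(.hbTable$wavelength, .hbTable$hb, wavelength)$y)
}

#' Melanin extinction spectrum
#'
#' Exponential melanin model \code{exp(-0.009 * lambda + 12.93)} used to tie
#' the epidermal absorption at the three device wavelengths to a single
#' degree of freedom.
#'
#' @param wavelength nm.
#' @return extinction values (arbitrary scale; only ratios are used).
#' @export
melaninExtinction <- function(wavelength) exp(-0.009 * wavelength + 12.93)

#' Epidermal absorption implied by a melanin index
#'
#' The melanin index MI = d_epi * mua_epi(662) is the approximate epidermal
#' optical thickness at 662 nm. Given MI and the model thickness, the
#' absorption at any wavelength follows the melanin spectrum:
#' mua_epi(lambda) = (MI / d_epi) * exp(-0.009 * (lambda - 662)).
#'
#' @param mi melanin index (>= 0).
#' @param wavelength nm (vectorized).
#' @param depi model epidermal thickness (cm), default 0.011.
#' @return epidermal absorption coefficient(s), cm^-1.
#' @examples
#' miToMuaEpi(0.16, 662)  # ~14.5 cm^-1
#' @export
miToMuaEpi <- function(mi, wavelength, depi = 0.011) {
  if (any(mi < 0)) stop("mi must be >= 0")
  (mi / depi) * melaninExtinction(wavelength) / melaninExtinction(662)
}

#' Subcutaneous absorption implied by a hemodynamic state
#'
#' @param tHb total hemoglobin (micromolar).
#' @param stO2 oxygen saturation (fraction).
#' @param wavelength nm.
#' @return absorption coefficients (cm^-1), one per wavelength.
#' @export
hemoglobinMua <- function(tHb, stO2, wavelength) {
  eps <- hbExtinction(wavelength)
  c1 <- tHb * stO2 * 1e-6        # mol/L
  c2 <- tHb * (1 - stO2) * 1e-6
  log(10) * as.vector(eps %*% c(c1, c2))
}

#' Least-squares hemoglobin unmixing of an absorption spectrum
#'
#' Unconstrained linear least squares of the subcutaneous absorption spectrum
#' against the oxy-/deoxyhemoglobin extinction coefficients. The mean squared
#' residual over the wavelengths (MSE, cm^-2) measures spectral fit quality;
#' the adjusted MSE divides by (1 - StO2) and is +Inf at StO2 >= 1, where the
#' fit would imply a non-physical negative deoxyhemoglobin fraction.
#'
#' @param muaSub absorption coefficients (cm^-1), one per wavelength.
#' @param wavelength nm (>= 3 values for a meaningful residual).
#' @return list with concentrations \code{cHbO}, \code{cHb}, \code{tHb}
#'   (micromolar), saturation \code{stO2} (fraction), residuals,
#'   \code{mse}, \code{adjMse} and a \code{physiological} flag (FALSE when
#'   StO2 falls outside [0, 1]).
#' @export
fitHemoglobin <- function(muaSub, wavelength = c(662, 735, 859)) {
  if (length(muaSub) != length(wavelength))
    stop("muaSub and wavelength lengths differ")
  if (any(!is.finite(muaSub))) stop("muaSub must be finite")
  E <- log(10) * hbExtinction(wavelength)
  fit <- lm.fit(E, muaSub)
  cM <- unname(coef(fit))               # mol/L
  e <- unname(fit$residuals)            # cm^-1 per wavelength
  mse <- mean(e^2)
  cHbO <- cM[1L] * 1e6; cHb <- cM[2L] * 1e6
  tHb <- cHbO + cHb
  stO2 <- if (tHb != 0) cHbO / tHb else NA_real_
  adj <- if (is.na(stO2) || stO2 >= 1) Inf else mse / (1 - stO2)
  list(cHbO = cHbO, cHb = cHb, tHb = tHb, stO2 = stO2, residuals = e,
       mse = mse, adjMse = adj,
       physiological = !is.na(stO2) && stO2 >= 0 && stO2 <= 1)
}

#' Fit the reduced-scattering power law
#'
#' Least-squares fit of \code{musp(lambda) = A * (lambda / lambda0)^-b} on
#' the log-log scale. With two wavelengths the fit is exact.
#'
#' @param musp reduced scattering (cm^-1) at the given wavelengths.
#' @param wavelength nm (>= 2 distinct values).
#' @param lambda0 reference wavelength (nm), default 735.
#' @return list with amplitude \code{A} (cm^-1 at lambda0), power \code{b}
#'   and \code{lambda0}.
#' @examples
#' fitScatterPowerLaw(c(7.1, 5.3), c(690, 830))$b  # ~1.58
#' @export
fitScatterPowerLaw <- function(musp, wavelength, lambda0 = 735) {
  if (any(musp <= 0)) stop("musp must be > 0")
  if (length(unique(wavelength)) < 2L) stop("need >= 2 distinct wavelengths")
  X <- cbind(1, -log(wavelength / lambda0))
  fit <- lm.fit(X, log(musp))
  list(A = exp(unname(coef(fit)[1L])), b = unname(coef(fit)[2L]),
       lambda0 = lambda0)
}

#' Pre-collapse a two-layer LUT set over a melanin-index grid
#'
#' For each candidate MI and wavelength, the two-layer table is collapsed at
#' the implied epidermal absorption. The result can be fed to [optimizeMI()]
#' to amortize the collapse across many measurements.
#'
#' @param luts list of [TwoLayerLUT-class], one per wavelength.
#' @param miGrid candidate melanin indices.
#' @param refine scattering-axis refinement factor passed to [refineLUT()].
#' @return list (over MI) of lists (over wavelength) of collapsed, refined
#'   tables.
#' @export
precollapseMI <- function(luts, miGrid = seq(0, 0.176, length.out = 161),
                          refine = 4L) {
  depi <- luts[[1L]]@depiModel
  wl <- vapply(luts, function(l) l@wavelength, 1.0)
  lapply(miGrid, function(mi) {
    mua <- miToMuaEpi(mi, wl, depi)
    lapply(seq_along(luts), function(i)
      refineLUT(collapseLUT(luts[[i]], mua[i]), refine))
  })
}

#' Optimize the melanin index by hemoglobin spectral-fit error
#'
#' For each candidate melanin index, the two-layer tables are collapsed at
#' the implied epidermal absorption per wavelength, the measured reflectance
#' pair is inverted to subcutaneous optical properties, and the absorption
#' spectrum is unmixed into hemoglobin concentrations. The selected MI
#' minimizes the fit MSE ("mse" mode, appropriate for simulated
#' two-chromophore data) or the adjusted MSE ("adjusted" mode, the in-vivo
#' variant that divides by 1 - StO2). Exact ties resolve to the smallest MI.
#'
#' @param rd an [SfdReflectance-class] with one entry per device wavelength
#'   (e.g. from [baselineAverageRd()]).
#' @param luts list of [TwoLayerLUT-class], one per wavelength, in the same
#'   order.
#' @param miGrid candidate MI values (default 161 evenly spaced on
#'   0-0.176).
#' @param mode "mse" or "adjusted".
#' @param collapsed optional output of [precollapseMI()] for these
#'   \code{luts} and \code{miGrid}.
#' @return an [MIFitResult-class].
#' @export
optimizeMI <- function(rd, luts, miGrid = seq(0, 0.176, length.out = 161),
                       mode = c("mse", "adjusted"), collapsed = NULL) {
  mode <- match.arg(mode)
  wl <- vapply(luts, function(l) l@wavelength, 1.0)
  if (length(rd@rd0) != length(wl))
    stop("reflectance and LUT wavelength counts differ")
  if (is.null(collapsed)) collapsed <- precollapseMI(luts, miGrid)
  nmi <- length(miGrid); nwl <- length(wl)
  muaSub <- matrix(NA_real_, nmi, nwl)
  muspSub <- matrix(NA_real_, nmi, nwl)
  oob <- matrix(FALSE, nmi, nwl)
  for (m in seq_len(nmi)) {
    for (i in seq_len(nwl)) {
      inv <- invertRd(collapsed[[m]][[i]], rd@rd0[i], rd@rd1[i])
      muaSub[m, i] <- inv$mua
      muspSub[m, i] <- inv$musp
      oob[m, i] <- inv$oob
    }
  }
  # vectorized hemoglobin unmixing across the MI grid
  E <- log(10) * hbExtinction(wl)
  P <- solve(crossprod(E), t(E))            # 2 x nwl pseudo-inverse
  conc <- muaSub %*% t(P)                   # nmi x 2, mol/L
  resid <- muaSub - conc %*% t(E)
  mse <- rowMeans(resid^2)
  cHbO <- conc[, 1L] * 1e6; cHb <- conc[, 2L] * 1e6
  tHb <- cHbO + cHb
  stO2 <- ifelse(tHb != 0, cHbO / tHb, NA_real_)
  adj <- ifelse(is.na(stO2) | stO2 >= 1, Inf, mse / (1 - stO2))
  crit <- if (mode == "mse") mse else adj
  # a clamped (out-of-gamut) inversion is not a valid candidate solution:
  # exclude such MI values from the argmin, as a table lookup that returns
  # no value would
  crit[apply(oob, 1L, any)] <- Inf
  if (all(!is.finite(crit)))
    stop("melanin-index optimization failed: no finite criterion value")
  sel <- which(crit == min(crit, na.rm = TRUE))[1L]  # smallest MI on ties
  new("MIFitResult", miGrid = miGrid, wavelength = wl, muaSub = muaSub,
      muspSub = muspSub, oob = oob, cHbO = cHbO, cHb = cHb, tHb = tHb,
      stO2 = stO2, mse = mse, adjMse = adj, selectedMI = miGrid[sel],
      selectedIdx = as.integer(sel), mode = mode)
}

#' @export
setMethod("show", "MIFitResult", function(object) {
  i <- object@selectedIdx
  cat(sprintf(
    "MIFitResult: MI = %.4f selected by %s over %d candidates\n",
    object@selectedMI, object@mode, length(object@miGrid)))
  cat(sprintf("  tHb = %.2f uM, StO2 = %.1f%%, MSE = %.3g cm^-2\n",
              object@tHb[i], 100 * object@stO2[i], object@mse[i]))
})
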