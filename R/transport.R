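#' @include AllGenerics.R
NULL

#' Construct a layered transport medium
#'
#' @param thickness layer thicknesses from the surface down (cm). The deepest
#'   layer's thickness is the absorbing bottom boundary when
#'   \code{semiInfinite} is TRUE.
#' @param musp reduced scattering coefficient per layer (cm^-1).
#' @param g anisotropy per layer (default 0.8); the full scattering
#'   coefficient is recovered through the similarity relation
#'   mu_s = mu_s' / (1 - g).
#' @param n refractive index per layer (default 1.4). All layers must share
#'   the same index; internal interfaces are index-matched.
#' @param ambientIndex index above the surface (default 1, air).
#' @param semiInfinite is the deepest layer a semi-infinite stand-in?
#' @return a [TransportMedium-class].
#' @examples
#' skinMedium(0.011, c(16.89, 8.94))
#' @export
skinMedium <- function(thickness = NULL, musp, g = 0.8, n = 1.4,
                       ambientIndex = 1.0, semiInfinite = TRUE) {
  nl <- length(musp)
  if (is.null(thickness))
    thickness <- if (nl == 1L) 10 else c(rep(0.011, nl - 1L), 10)
  if (length(thickness) == nl - 1L) thickness <- c(thickness, 10)
  g <- rep_len(g, nl); n <- rep_len(n, nl)
  if (length(unique(n)) != 1L)
    stop("all layers must share one refractive index (index-matched internal interfaces)")
  new("TransportMedium",
      layers = data.frame(thickness = thickness, musp = musp, g = g, n = n),
      ambientIndex = ambientIndex, semiInfinite = semiInfinite)
}

#' @describeIn runWhiteMC photons are traced without absorption (white Monte
#'   Carlo): Henyey-Greenstein scattering, unpolarized Fresnel
#'   reflection/escape at the top surface, termination at the bottom of the
#'   deepest layer. Exit radius and per-layer pathlengths are recorded so any
#'   absorption can be applied afterwards by Beer-Lambert weighting.
#' @param maxPathlength termination cap on the total pathlength (cm). The
#'   default 450 cm makes the largest neglected Beer factor
#'   exp(-0.01 * 450) ~ 1e-2 at the smallest tabulated absorption
#'   0.01 cm^-1, biasing scored reflectance by well under 0.1%. Use
#'   \code{Inf} for a cap-free run.
#' @export
setMethod("runWhiteMC", "TransportMedium",
  function(medium, nPhotons, seed, maxPathlength = 450) {
    nPhotons <- as.integer(nPhotons)
    if (nPhotons < 1000L) stop("nPhotons must be at least 1e3")
    validObject(medium)
    ly <- medium@layers
    res <- cpp_white_mc(ly$thickness, ly$musp, ly$g, ly$n[1L],
                        medium@ambientIndex, nPhotons, as.numeric(seed),
                        as.numeric(maxPathlength))
    new("PhotonPaths", medium = medium, weight = res$weight,
        radius = res$radius, pathlengths = res$pathlengths,
        nPhotons = as.numeric(res$n_photons),
        nLost = as.numeric(res$n_lost), seed = as.numeric(seed),
        maxPathlength = as.numeric(maxPathlength))
  })

#' Direct absorbing Monte Carlo reference simulation
#'
#' Companion simulation that applies absorption during flight (steps drawn
#' from the total interaction coefficient, survival weighting by the
#' single-scattering albedo, Russian roulette below 1e-4). Used as an
#' independent cross-check of the white Monte Carlo + Beer rescaling route.
#'
#' @inheritParams runWhiteMC
#' @param mua absorption coefficient per layer (cm^-1).
#' @param fx spatial frequencies (mm^-1) at which to score.
#' @return an [SfdReflectance-class] with Monte Carlo standard errors.
#' @export
runDirectMC <- function(medium, mua, nPhotons, seed, fx = c(0, 0.1)) {
  validObject(medium)
  ly <- medium@layers
  if (length(mua) != nrow(ly)) stop("mua must have one value per layer")
  res <- cpp_direct_mc(ly$thickness, ly$musp, ly$g, mua, ly$n[1L],
                       medium@ambientIndex, as.integer(nPhotons),
                       fx * 10, as.numeric(seed))  # mm^-1 -> cm^-1
  new("SfdReflectance", wavelength = NA_real_, rd0 = res$rd[1L],
      rd1 = res$rd[2L], se0 = res$se[1L], se1 = res$se[2L], fx = fx)
}

#' @describeIn scoreSFD each exit record contributes
#'   \code{weight * exp(-sum(mua * L)) * J0(2 pi fx rho)}; photons that never
#'   exited contribute zero. At fx = 0 this is the total diffuse reflectance.
#' @param fx spatial frequencies (mm^-1), default \code{c(0, 0.1)}.
#' @param wavelength optional wavelength tag (nm) for the result.
#' @export
setMethod("scoreSFD", "PhotonPaths",
  function(paths, muaPerLayer, fx = c(0, 0.1), wavelength = NA_real_) {
    if (length(muaPerLayer) != ncol(paths@pathlengths))
      stop("muaPerLayer must have one value per layer")
    if (any(muaPerLayer < 0)) stop("absorption coefficients must be >= 0")
    if (length(fx) != 2L) stop("fx must hold exactly two frequencies")
    w <- paths@weight * exp(-as.vector(paths@pathlengths %*% muaPerLayer))
    n <- paths@nPhotons
    vals <- numeric(2L); ses <- numeric(2L)
    for (j in 1:2) {
      fcm <- fx[j] * 10  # mm^-1 -> cm^-1
      x <- if (fcm == 0) w else w * besselJ(2 * pi * fcm * paths@radius, 0)
      m <- sum(x) / n
      v <- sum(x * x) / n - m * m
      vals[j] <- m
      ses[j] <- sqrt(max(v, 0) / n)
    }
    new("SfdReflectance", wavelength = wavelength, rd0 = vals[1L],
        rd1 = vals[2L], se0 = ses[1L], se1 = ses[2L], fx = fx)
  })

#' Total diffuse reflectance of a semi-infinite medium (diffusion theory)
#'
#' Standard-diffusion-approximation prediction used as an analytic
#' cross-check of the Monte Carlo engine at low absorption.
#'
#' @param mua,musp optical properties (cm^-1).
#' @param n tissue refractive index.
#' @param fx spatial frequency (mm^-1).
#' @return predicted Rd(fx).
#' @export
diffusionRd <- function(mua, musp, n = 1.4, fx = 0) {
  reff <- 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  A <- (1 - reff) / (2 * (1 + reff))
  mutr <- mua + musp
  ap <- musp / mutr
  mueff <- sqrt(3 * mua * mutr)
  mueffp <- sqrt(mueff^2 + (2 * pi * fx * 10)^2)
  3 * A * ap / ((mueffp / mutr + 1) * (mueffp / mutr + 3 * A))
}

#' @export
setMethod("show", "TransportMedium", function(object) {
  cat(sprintf("TransportMedium: %d layer(s), ambient n = %.3g%s\n",
              nrow(object@layers), object@ambientIndex,
              if (object@semiInfinite) ", bottom semi-infinite" else ""))
  print(object@layers)
})

#' @export
setMethod("show", "PhotonPaths", function(object) {
  cat(sprintf(
    "PhotonPaths: %g launched, %d escaped (%.1f%%), %g lost; seed %g\n",
    object@nPhotons, length(object@weight),
    100 * length(object@weight) / object@nPhotons, object@nLost,
    object@seed))
})

#' @export
setMethod("show", "SfdReflectance", function(object) {
  cat(sprintf("SfdReflectance at fx = {%g, %g} mm^-1\n",
              object@fx[1L], object@fx[2L]))
  df <- data.frame(wavelength = object@wavelength, rd0 = object@rd0,
                   rd1 = object@rd1)
  print(df, row.names = FALSE)
})

#' @describeIn SfdReflectance-class reflectance at fx = 0.
#' @export
setMethod("rd0", "SfdReflectance", function(x) x@rd0)

#' @describeIn SfdReflectance-class reflectance at the modulated frequency.
#' @export
setMethod("rd1", "SfdReflectance", function(x) x@rd1)

#' @describeIn SfdReflectance-class wavelengths (nm).
#' @export
setMethod("wavelengths", "SfdReflectance", function(x) x@wavelength)
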