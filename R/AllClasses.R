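#' @include twoLayerSFDI-package.R
NULL

#' Layered transport medium
#'
#' Geometry and transport properties of a plane-parallel layered medium:
#' one row of \code{layers} per layer from the illuminated surface downward,
#' with thickness (cm), reduced scattering \code{musp} (cm^-1), anisotropy
#' \code{g} and refractive index \code{n}. The deepest layer may be flagged
#' semi-infinite, in which case its stated thickness acts as the absorbing
#' bottom boundary of the simulation.
#'
#' @slot layers data.frame with columns \code{thickness}, \code{musp},
#'   \code{g}, \code{n}.
#' @slot ambientIndex refractive index above the top surface.
#' @slot semiInfinite logical; is the bottom layer a semi-infinite stand-in?
#' @export
setClass("TransportMedium",
  representation(layers = "data.frame", ambientIndex = "numeric",
                 semiInfinite = "logical"),
  prototype(ambientIndex = 1.0, semiInfinite = TRUE))

setValidity("TransportMedium", function(object) {
  ly <- object@layers
  msg <- character()
  need <- c("thickness", "musp", "g", "n")
  if (!all(need %in% names(ly)))
    return(paste("layers must have columns", paste(need, collapse = ", ")))
  if (nrow(ly) < 1L) msg <- c(msg, "medium must have at least one layer")
  if (any(ly$thickness <= 0)) msg <- c(msg, "layer thickness must be > 0")
  if (any(ly$musp <= 0)) msg <- c(msg, "musp must be > 0")
  if (any(ly$g < 0 | ly$g >= 1)) msg <- c(msg, "anisotropy must satisfy 0 <= g < 1")
  if (any(ly$n < 1)) msg <- c(msg, "refractive index must be >= 1")
  if (length(object@ambientIndex) != 1L || object@ambientIndex < 1)
    msg <- c(msg, "ambientIndex must be a single value >= 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Photon exit records from a white Monte Carlo run
#'
#' One row per photon that escaped the top surface: exit weight, exit radius
#' (cm) and the pathlength travelled in each layer (cm). Because the
#' simulation is run without absorption, any pair of layer absorption
#' coefficients can be applied afterwards through Beer-Lambert weights.
#'
#' @slot medium the [TransportMedium-class] that was simulated.
#' @slot weight numeric, exit weight per photon (in (0, 1]).
#' @slot radius numeric, exit radius from the beam axis (cm).
#' @slot pathlengths matrix, photons x layers, pathlength per layer (cm).
#' @slot nPhotons number of photons launched.
#' @slot nLost photons terminated at the bottom boundary or by the
#'   pathlength cap.
#' @slot seed RNG seed of the run.
#' @slot maxPathlength pathlength cap (cm) used for termination.
#' @export
setClass("PhotonPaths",
  representation(medium = "TransportMedium", weight = "numeric",
                 radius = "numeric", pathlengths = "matrix",
                 nPhotons = "numeric", nLost = "numeric", seed = "numeric",
                 maxPathlength = "numeric"))

setValidity("PhotonPaths", function(object) {
  msg <- character()
  nex <- length(object@weight)
  if (length(object@radius) != nex || nrow(object@pathlengths) != nex)
    msg <- c(msg, "weight, radius and pathlengths must agree in length")
  if (nex > 0) {
    if (any(object@weight <= 0 | object@weight > 1))
      msg <- c(msg, "exit weights must lie in (0, 1]")
    if (any(object@radius < 0)) msg <- c(msg, "exit radii must be >= 0")
    if (any(object@pathlengths < 0)) msg <- c(msg, "pathlengths must be >= 0")
    if (any(object@pathlengths[, 1L] <= 0))
      msg <- c(msg, "pathlength in the entry layer must be > 0")
  }
  if (ncol(object@pathlengths) != nrow(object@medium@layers))
    msg <- c(msg, "pathlength columns must match the layer count")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Diffuse reflectance at the two SFDI spatial frequencies
#'
#' Holds Rd at fx = 0 and at the modulated frequency (default 0.1 mm^-1) for
#' one or more wavelengths, together with Monte Carlo standard errors where
#' the values come from a simulation.
#'
#' @slot wavelength wavelengths (nm), one per element of \code{rd0}.
#' @slot rd0,rd1 diffuse reflectance at \code{fx[1]} and \code{fx[2]}.
#' @slot se0,se1 Monte Carlo standard errors (zero when not applicable).
#' @slot fx the two spatial frequencies (mm^-1).
#' @export
setClass("SfdReflectance",
  representation(wavelength = "numeric", rd0 = "numeric", rd1 = "numeric",
                 se0 = "numeric", se1 = "numeric", fx = "numeric"),
  prototype(fx = c(0, 0.1), se0 = 0, se1 = 0))

setValidity("SfdReflectance", function(object) {
  msg <- character()
  n <- length(object@rd0)
  if (length(object@rd1) != n) msg <- c(msg, "rd0 and rd1 lengths differ")
  if (length(object@fx) != 2L) msg <- c(msg, "fx must hold two frequencies")
  if (any(!is.finite(object@rd0)) || any(!is.finite(object@rd1)))
    msg <- c(msg, "reflectance must be finite")
  else {
    # allow a whisker of Monte Carlo noise on the physical ordering
    tol <- 3 * pmax(object@se0, object@se1) + 1e-9
    if (any(object@rd0 < 0) || any(object@rd0 > 1 + 1e-9))
      msg <- c(msg, "rd0 must lie in [0, 1]")
    if (any(object@rd1 > object@rd0 + tol))
      msg <- c(msg, "rd1 must not exceed rd0")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Two-layer Monte Carlo lookup table for one wavelength
#'
#' Gridded forward map (mua_epi, mua_sub, musp_sub) -> (Rd(0), Rd(fx)) built
#' by Beer-Lambert rescaling of white Monte Carlo pathlength records. The
#' epidermal reduced scattering and model thickness are fixed per wavelength.
#'
#' @slot wavelength nm.
#' @slot muaEpiAxis,muaSubAxis,muspSubAxis grid axes (cm^-1).
#' @slot musEpiPrime fixed epidermal reduced scattering (cm^-1).
#' @slot depiModel model epidermal thickness (cm).
#' @slot rd0Grid,rd1Grid 3-D arrays over (muaEpi, muaSub, muspSub).
#' @slot provenance list: photon count, seeds, pathlength cap, version.
#' @export
setClass("TwoLayerLUT",
  representation(wavelength = "numeric", muaEpiAxis = "numeric",
                 muaSubAxis = "numeric", muspSubAxis = "numeric",
                 musEpiPrime = "numeric", depiModel = "numeric",
                 rd0Grid = "array", rd1Grid = "array", provenance = "list"))

setValidity("TwoLayerLUT", function(object) {
  msg <- character()
  dims <- c(length(object@muaEpiAxis), length(object@muaSubAxis),
            length(object@muspSubAxis))
  if (!identical(dim(object@rd0Grid), as.integer(dims)) ||
      !identical(dim(object@rd1Grid), as.integer(dims)))
    msg <- c(msg, "grid dimensions must match the axes")
  for (ax in list(object@muaEpiAxis, object@muaSubAxis, object@muspSubAxis))
    if (is.unsorted(ax, strictly = TRUE))
      msg <- c(msg, "axes must be strictly increasing")
  if (any(!is.finite(object@rd0Grid)) || any(!is.finite(object@rd1Grid)))
    msg <- c(msg, "grids must be finite")
  else {
    if (min(object@rd0Grid) < 0 || max(object@rd0Grid) > 1 ||
        min(object@rd1Grid) < -1e-9)
      msg <- c(msg, "grids must lie in [0, 1]")
    if (any(object@rd1Grid > object@rd0Grid + 1e-9))
      msg <- c(msg, "rd1 grid must not exceed rd0 grid")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Homogeneous (single-layer) Monte Carlo lookup table
#'
#' Conventional two-frequency SFDI table: forward map (mua, musp) ->
#' (Rd(0), Rd(fx)). Also the container returned when a [TwoLayerLUT-class]
#' is collapsed at a fixed epidermal absorption.
#'
#' @slot wavelength nm (NA for a wavelength-independent table).
#' @slot muaAxis,muspAxis grid axes (cm^-1).
#' @slot rd0Grid,rd1Grid matrices over (mua, musp).
#' @slot provenance list of build metadata.
#' @export
setClass("HomogeneousLUT",
  representation(wavelength = "numeric", muaAxis = "numeric",
                 muspAxis = "numeric", rd0Grid = "matrix",
                 rd1Grid = "matrix", provenance = "list"))

setValidity("HomogeneousLUT", function(object) {
  msg <- character()
  if (!identical(dim(object@rd0Grid),
                 c(length(object@muaAxis), length(object@muspAxis))) ||
      !identical(dim(object@rd0Grid), dim(object@rd1Grid)))
    msg <- c(msg, "grid dimensions must match the axes")
  if (is.unsorted(object@muaAxis, strictly = TRUE) ||
      is.unsorted(object@muspAxis, strictly = TRUE))
    msg <- c(msg, "axes must be strictly increasing")
  if (any(!is.finite(object@rd0Grid)) || any(!is.finite(object@rd1Grid)))
    msg <- c(msg, "grids must be finite")
  else if (any(object@rd1Grid > object@rd0Grid + 1e-9))
    msg <- c(msg, "rd1 grid must not exceed rd0 grid")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Result of the melanin-index optimization
#'
#' Full grid of candidate melanin indices with, per candidate, the recovered
#' subcutaneous optical properties, hemoglobin fit, mean squared fit error
#' and adjusted error, plus the selected index.
#'
#' @slot miGrid candidate melanin indices.
#' @slot wavelength the wavelengths (nm) used.
#' @slot muaSub,muspSub matrices (MI x wavelength) of recovered properties.
#' @slot oob logical matrix, out-of-gamut flags from the inversion.
#' @slot cHbO,cHb,tHb micromolar concentrations per MI candidate.
#' @slot stO2 oxygen saturation (fraction) per candidate.
#' @slot mse,adjMse fit error curves (cm^-2); adjMse is +Inf where StO2 >= 1.
#' @slot selectedMI,selectedIdx the minimizer under \code{mode}.
#' @slot mode "mse" or "adjusted".
#' @export
setClass("MIFitResult",
  representation(miGrid = "numeric", wavelength = "numeric",
                 muaSub = "matrix", muspSub = "matrix", oob = "matrix",
                 cHbO = "numeric", cHb = "numeric", tHb = "numeric",
                 stO2 = "numeric", mse = "numeric", adjMse = "numeric",
                 selectedMI = "numeric", selectedIdx = "integer",
                 mode = "character"))

#' Dynamic SFDI measurement (diffuse-reflectance movie)
#'
#' Time-resolved stack of calibrated diffuse reflectance over a circular
#' field of view, as produced during a baseline/compression/recovery
#' protocol, plus the ground-truth sidecar when synthesized.
#'
#' @slot rd 5-D array [y, x, wavelength, fx, time].
#' @slot times frame timestamps (s).
#' @slot wavelength nm.
#' @slot fx the two spatial frequencies (mm^-1).
#' @slot pixelPitch mm per pixel.
#' @slot fovMask logical matrix, circular field-of-view support.
#' @slot pressure optional pressure trace (kPa), length 0 or length(times).
#' @slot timeline named numeric: baseline/compression/recovery bounds (s).
#' @slot truth list, ground-truth sidecar (empty for measured data).
#' @export
setClass("SfdiMovie",
  representation(rd = "array", times = "numeric", wavelength = "numeric",
                 fx = "numeric", pixelPitch = "numeric", fovMask = "matrix",
                 pressure = "numeric", timeline = "numeric", truth = "list"))

setValidity("SfdiMovie", function(object) {
  d <- dim(object@rd)
  msg <- character()
  if (length(d) != 5L) msg <- c(msg, "rd must be [y, x, wavelength, fx, time]")
  else {
    if (d[3L] != length(object@wavelength)) msg <- c(msg, "wavelength dim mismatch")
    if (d[4L] != length(object@fx)) msg <- c(msg, "fx dim mismatch")
    if (d[5L] != length(object@times)) msg <- c(msg, "time dim mismatch")
    if (!identical(dim(object@fovMask), d[1:2])) msg <- c(msg, "fovMask dim mismatch")
  }
  if (length(object@pressure) &&
      length(object@pressure) != length(object@times))
    msg <- c(msg, "pressure trace must match the timebase")
  if (length(object@times) > 1 &&
      max(abs(diff(diff(object@times)))) > 1e-6)
    msg <- c(msg, "frame cadence must be uniform")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Software-phantom specification
#'
#' Ground-truth description of a two-layer software phantom: melanin index,
#' epidermal thickness and scattering, subcutaneous scattering, and the
#' hemodynamic state (total hemoglobin, oxygen saturation) that determines
#' subcutaneous absorption through the embedded extinction spectra.
#'
#' @slot mi melanin index (dimensionless).
#' @slot depi epidermal thickness (cm).
#' @slot wavelength nm.
#' @slot muspEpi,muspSub reduced scattering per wavelength (cm^-1).
#' @slot tHb total hemoglobin (micromolar).
#' @slot stO2 oxygen saturation (fraction).
#' @export
setClass("PhantomSpec",
  representation(mi = "numeric", depi = "numeric", wavelength = "numeric",
                 muspEpi = "numeric", muspSub = "numeric", tHb = "numeric",
                 stO2 = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@mi < 0) msg <- c(msg, "mi must be >= 0")
  if (object@depi <= 0) msg <- c(msg, "depi must be > 0")
  if (any(object@muspEpi <= 0) || any(object@muspSub <= 0))
    msg <- c(msg, "reduced scattering must be > 0")
  if (object@stO2 < 0 || object@stO2 > 1) msg <- c(msg, "stO2 must lie in [0, 1]")
  if (object@tHb <= 0) msg <- c(msg, "tHb must be > 0")
  if (length(object@muspEpi) != length(object@wavelength) ||
      length(object@muspSub) != length(object@wavelength))
    msg <- c(msg, "scattering vectors must match the wavelengths")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
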