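#' @include AllClasses.R
NULL

#' Run a layered white Monte Carlo simulation
#'
#' @param medium a [TransportMedium-class].
#' @param nPhotons number of photons to launch (>= 1000).
#' @param seed integer seed for the simulation's own RNG stream.
#' @param ... further arguments passed to methods.
#' @return a [PhotonPaths-class] collection of exit records.
#' @export
setGeneric("runWhiteMC", function(medium, nPhotons, seed, ...)
  standardGeneric("runWhiteMC"))

#' Score exit records in the spatial frequency domain
#'
#' @param paths a [PhotonPaths-class] object.
#' @param muaPerLayer absorption coefficient per layer (cm^-1).
#' @param ... further arguments passed to methods.
#' @return an [SfdReflectance-class] scalar result.
#' @export
setGeneric("scoreSFD", function(paths, muaPerLayer, ...)
  standardGeneric("scoreSFD"))

#' Collapse a two-layer LUT at a fixed epidermal absorption
#'
#' @param lut a [TwoLayerLUT-class].
#' @param muaEpi epidermal absorption (cm^-1) at which to interpolate.
#' @return a [HomogeneousLUT-class]-shaped 2-D table over
#'   (mua_sub, musp_sub).
#' @export
setGeneric("collapseLUT", function(lut, muaEpi) standardGeneric("collapseLUT"))

#' Invert measured reflectance pairs through a 2-D lookup table
#'
#' @param table a [HomogeneousLUT-class] (native or collapsed two-layer).
#' @param rd0,rd1 diffuse reflectance at the two spatial frequencies.
#' @return data.frame with columns \code{mua}, \code{musp}, \code{oob}.
#' @export
setGeneric("invertRd", function(table, rd0, rd1) standardGeneric("invertRd"))

#' Evaluate a lookup table in the forward direction
#'
#' @param table a [HomogeneousLUT-class] or [TwoLayerLUT-class].
#' @param ... coordinates; see methods.
#' @return list with components \code{rd0} and \code{rd1}.
#' @export
setGeneric("forwardRd", function(table, ...) standardGeneric("forwardRd"))

#' @rdname SfdReflectance-class
#' @param object,x an object.
#' @export
setGeneric("rd0", function(x) standardGeneric("rd0"))

#' @rdname SfdReflectance-class
#' @export
setGeneric("rd1", function(x) standardGeneric("rd1"))

#' @rdname SfdReflectance-class
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
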