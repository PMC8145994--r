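#' @include spectral.R
NULL

#' Three-phase sinusoidal demodulation
#'
#' Recovers the planar (DC) and modulated (AC) reflectance amplitudes from
#' three frames acquired under sinusoidal illumination at equally spaced
#' phase shifts: M0 = (I1 + I2 + I3) / 3 and
#' M1 = sqrt(2)/3 * sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2), the symmetric
#' three-phase form, which recovers the sinusoid amplitude exactly at any
#' phase offset.
#'
#' @param i1,i2,i3 intensity images (matrices or numerics of equal shape).
#' @param mask optional logical mask of pixels to blank (e.g. saturated
#'   pixels); masked pixels become NA in both outputs.
#' @return list with components \code{m0} and \code{m1}.
#' @examples
#' ph <- 2 * pi * (0:2) / 3
#' demodulate(10 + 2 * cos(1 + ph[1]), 10 + 2 * cos(1 + ph[2]),
#'            10 + 2 * cos(1 + ph[3]))  # m0 = 10, m1 = 2
#' @export
demodulate <- function(i1, i2, i3, mask = NULL) {
  if (!identical(dim(i1), dim(i2)) || !identical(dim(i1), dim(i3)) ||
      length(i1) != length(i2) || length(i1) != length(i3))
    stop("the three frames must have identical shape")
  if (min(i1, i2, i3, na.rm = TRUE) < 0)
    stop("intensities must be non-negative")
  m0 <- (i1 + i2 + i3) / 3
  m1 <- sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
  if (!is.null(mask)) {
    m0[mask] <- NA_real_
    m1[mask] <- NA_real_
  }
  list(m0 = m0, m1 = m1)
}

#' Mask saturated pixels
#'
#' @param frames list of intensity images.
#' @param satLevel sensor saturation level.
#' @return logical mask, TRUE where any frame is at or above saturation.
#' @export
maskSaturated <- function(frames, satLevel) {
  Reduce(`|`, lapply(frames, function(f) f >= satLevel))
}

#' Theoretical reference reflectance of the calibration phantom
#'
#' The reference phantom is characterized at two wavelengths; its reduced
#' scattering is carried to the device wavelengths by the scattering power
#' law and its absorption is taken as the mean of the two characterized
#' values. The homogeneous Monte Carlo table then gives the theoretical
#' Rd at both spatial frequencies per device wavelength.
#'
#' @param homLUT a [HomogeneousLUT-class] forward table.
#' @param wavelengths device wavelengths (nm).
#' @param charWavelengths wavelengths at which the phantom was characterized.
#' @param charMua,charMusp characterized optical properties (cm^-1).
#' @return an [SfdReflectance-class] with one entry per device wavelength.
#' @export
phantomReferenceRd <- function(homLUT, wavelengths = c(662, 735, 859),
                               charWavelengths = c(690, 830),
                               charMua = c(0.047, 0.052),
                               charMusp = c(7.1, 5.3)) {
  sf <- fitScatterPowerLaw(charMusp, charWavelengths)
  musp <- sf$A * (wavelengths / sf$lambda0)^(-sf$b)
  mua <- rep(mean(charMua), length(wavelengths))
  fwd <- forwardRd(homLUT, mua, musp)
  new("SfdReflectance", wavelength = wavelengths, rd0 = fwd$rd0,
      rd1 = fwd$rd1, se0 = rep(0, length(wavelengths)),
      se1 = rep(0, length(wavelengths)), fx = homLUT@provenance$fx %||% c(0, 0.1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate demodulated magnitudes to diffuse reflectance
#'
#' Pixelwise ratio against the reference-phantom demodulation, scaled by the
#' phantom's theoretical reflectance: Rd(fx) = M(fx) / Mref(fx) * Rd,ref(fx).
#' The ratio cancels the illumination profile and camera gain, so the result
#' is invariant to any common rescaling of the raw frames.
#'
#' @param meas demodulated measurement, list with \code{m0}, \code{m1}.
#' @param ref demodulated reference-phantom acquisition, same shape.
#' @param rdRef0,rdRef1 theoretical reference reflectance at the two
#'   frequencies (scalars, one wavelength at a time).
#' @param minRef reference pixels whose magnitude falls below
#'   \code{minRef} times the median reference magnitude are flagged invalid
#'   (NA).
#' @return list with calibrated \code{rd0}, \code{rd1} images.
#' @export
calibrate <- function(meas, ref, rdRef0, rdRef1, minRef = 1e-3) {
  bad0 <- !(ref$m0 > minRef * median(ref$m0, na.rm = TRUE))
  bad1 <- !(ref$m1 > minRef * median(ref$m1, na.rm = TRUE))
  rd0 <- meas$m0 / ref$m0 * rdRef0
  rd1 <- meas$m1 / ref$m1 * rdRef1
  rd0[bad0] <- NA_real_
  rd1[bad1] <- NA_real_
  list(rd0 = rd0, rd1 = rd1)
}
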