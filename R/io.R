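#' @include validate.R
NULL

#' Write a raw SFDI stack as multi-page TIFF plus YAML sidecar
#'
#' The measurement and reference frames are written as 32-bit float
#' multi-page TIFFs (pages ordered phase-fastest, then wavelength), scaled
#' into [0, 1] by a factor recorded in the sidecar. The sidecar carries the
#' acquisition geometry (wavelengths, spatial frequency, pixel pitch,
#' phases) and, for synthetic stacks, the ground truth.
#'
#' @param stack a stack as returned by [makeRawStack()].
#' @param dir output directory (created if missing).
#' @param name base file name.
#' @return invisibly, the three file paths.
#' @export
writeSfdiStack <- function(stack, dir, name = "sfdi") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scale <- max(stack$frames, stack$reference)
  pages <- function(a) {
    d <- dim(a)
    out <- vector("list", d[3L] * d[4L])
    k <- 0L
    for (i in seq_len(d[4L])) for (p in seq_len(d[3L])) {
      k <- k + 1L
      out[[k]] <- a[, , p, i] / scale
    }
    out
  }
  fMeas <- file.path(dir, paste0(name, "_meas.tif"))
  fRef <- file.path(dir, paste0(name, "_ref.tif"))
  fSide <- file.path(dir, paste0(name, ".yaml"))
  tiff::writeTIFF(pages(stack$frames), fMeas, bits.per.sample = 32L)
  tiff::writeTIFF(pages(stack$reference), fRef, bits.per.sample = 32L)
  side <- stack$sidecar
  side$scale <- scale
  side$dims <- dim(stack$frames)
  side$pageOrder <- "phase-fastest, then wavelength"
  yaml::write_yaml(side, fSide)
  invisible(c(measurement = fMeas, reference = fRef, sidecar = fSide))
}

#' @rdname writeSfdiStack
#' @param path path to the sidecar YAML (the TIFFs are located next to it).
#' @export
readSfdiStack <- function(path) {
  side <- yaml::read_yaml(path)
  base <- sub("\\.yaml$", "", path)
  unpack <- function(f) {
    pgs <- tiff::readTIFF(f, all = TRUE)
    d <- side$dims
    a <- array(NA_real_, d)
    k <- 0L
    for (i in seq_len(d[4L])) for (p in seq_len(d[3L])) {
      k <- k + 1L
      a[, , p, i] <- pgs[[k]] * side$scale
    }
    a
  }
  list(frames = unpack(paste0(base, "_meas.tif")),
       reference = unpack(paste0(base, "_ref.tif")),
       sidecar = side)
}

#' Locate the sequence start from blank marker frames
#'
#' Acquisition sequences are delimited by blank frames. A frame counts as
#' blank when its mean intensity falls below \code{threshold} times the
#' median frame mean of the stack; the sequence starts at the first
#' non-blank frame following a blank run.
#'
#' @param frames list of matrices or 3-D array [y, x, frame].
#' @param threshold blank threshold as a fraction of the median frame mean.
#' @return list with \code{blank} (logical per frame) and \code{start}
#'   (index of the first in-sequence frame, NA if no marker found).
#' @export
detectSequenceStart <- function(frames, threshold = 0.05) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3L]), function(i) frames[, , i])
  mu <- vapply(frames, mean, 1.0, na.rm = TRUE)
  blank <- mu < threshold * median(mu)
  start <- NA_integer_
  if (any(blank)) {
    lastBlank <- max(which(blank))
    if (lastBlank < length(frames)) start <- lastBlank + 1L
  }
  list(blank = blank, start = start)
}

#' Demodulate and calibrate a raw stack to diffuse reflectance
#'
#' Convenience wrapper: per wavelength, the three-phase measurement and
#' reference frames are demodulated (after saturation masking) and the
#' measurement is calibrated against the reference phantom's theoretical
#' reflectance.
#'
#' @param stack a stack from [makeRawStack()] or [readSfdiStack()].
#' @param rdRef an [SfdReflectance-class] with the reference phantom's
#'   theoretical reflectance at the stack's wavelengths (defaults to the
#'   truth recorded in the sidecar, when present).
#' @param satLevel optional saturation level for pixel masking.
#' @return list per wavelength of calibrated \code{rd0}, \code{rd1} images.
#' @export
calibrateStack <- function(stack, rdRef = NULL, satLevel = NULL) {
  side <- stack$sidecar
  nwl <- dim(stack$frames)[4L]
  if (is.null(rdRef)) {
    if (is.null(side$reference))
      stop("no reference reflectance supplied or recorded")
    rdRef <- new("SfdReflectance",
                 wavelength = as.numeric(side$wavelengths),
                 rd0 = as.numeric(side$reference$rd0),
                 rd1 = as.numeric(side$reference$rd1),
                 se0 = rep(0, nwl), se1 = rep(0, nwl),
                 fx = as.numeric(side$fx))
  }
  out <- vector("list", nwl)
  names(out) <- as.character(side$wavelengths)
  for (i in seq_len(nwl)) {
    fr <- lapply(1:3, function(p) stack$frames[, , p, i])
    rf <- lapply(1:3, function(p) stack$reference[, , p, i])
    mask <- if (is.null(satLevel)) NULL else maskSaturated(fr, satLevel)
    meas <- demodulate(fr[[1L]], fr[[2L]], fr[[3L]], mask)
    ref <- demodulate(rf[[1L]], rf[[2L]], rf[[3L]])
    out[[i]] <- calibrate(meas, ref, rdRef@rd0[i], rdRef@rd1[i])
  }
  out
}
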