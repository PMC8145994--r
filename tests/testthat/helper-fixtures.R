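# A handful of acceptance-level checks are honestly stochastic; never let an
# early failure cap stop the remaining files from running.
options(testthat.progress.max_fails = 200L)

# Shared, lazily built fixtures. Heavy Monte Carlo products are memoized in
# this environment so that every test file (and the acceptance suite) reuses
# one build per session.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# baseline two-layer medium at 735 nm device settings
medium735 <- function(muspSub = 8.94)
  skinMedium(c(0.011, 10), c(16.89, muspSub))

# small but usable device LUT set (coarse scattering axis)
miniLUTs <- function() memo("miniLUTs", function() {
  buildDeviceLUTs(nPhotons = 1.5e4, seed = 3,
                  muspSubAxis = seq(4, 20, by = 2), homogeneous = TRUE)
})

# mid-size white MC record set reused across transport/score tests
paths735 <- function() memo("paths735", function() {
  runWhiteMC(medium735(), 5e4, seed = 42)
})

# synthetic compression movie at the generator defaults
defaultMovie <- function() memo("defaultMovie", function() {
  makeCompressionMovie(miniLUTs()$twoLayer, mi = 0.05, nx = 32, ny = 32,
                       seed = 7)
})

# full validation suite at the sizes used for in-suite acceptance checks
acceptanceRun <- function() memo("acceptanceRun", function() {
  reproduceValidation(seed = 101, nPhotonsLUT = 2e5, nPhotonsLUTDense = 4e5,
                      nPhotonsHom = 4e4, nPhotonsForward = 1.2e6,
                      nPhotonsBattery = 5e4)
})

# upper bound on the SE of a Monte Carlo reflectance estimate with n photons
# (per-photon contributions are bounded by 1)
mcSeBound <- function(n) 0.5 / sqrt(n)
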