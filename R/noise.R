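#' Apply the camera noise model to a trace
#'
#' Shot noise plus read noise: each sample becomes
#' \deqn{Poisson(g\,(I + b))/g - b + N(0, \sigma_r)}
#' where `g` is the photon conversion gain, `b` the background entering
#' the measurement and `sigma_r` the Gaussian read-noise SD. For
#' trace-level simulation (no rendered image), the per-pixel background
#' and read noise of the camera model are scaled to the photometric
#' aperture: `b = background * n_pixels` and
#' `sigma_r = read_sd * sqrt(n_pixels)`, so a simulated trace carries the
#' same noise an aperture-photometry measurement of a rendered movie
#' would.
#'
#' @param trace an [intensity_trace()] (noise-free expected signal).
#' @param config a [sim_config()] supplying `gain`, `read_sd`,
#'   `background`.
#' @param seed integer seed; fixed seed gives identical output.
#' @param n_pixels number of aperture pixels the background/read terms
#'   are integrated over. Default 49 (the radius-4 pixel aperture).
#' @return a new `IntensityTrace` with noisy `raw` values.
#' @export
add_noise <- function(trace, config, seed = 1, n_pixels = 49) {
  stopifnot(inherits(trace, "IntensityTrace"),
            inherits(config, "SimulationConfig"))
  g <- config$gain
  b <- config$background * n_pixels
  sr <- config$read_sd * sqrt(n_pixels)
  expected <- g * (trace$raw + b)
  if (any(expected < 0)) {
    warning("negative expected photon count clamped to 0")
    expected <- pmax(expected, 0)
  }
  noisy <- with_seed(seed, {
    stats::rpois(length(expected), expected) / g - b +
      stats::rnorm(length(expected), 0, sr)
  })
  intensity_trace(trace$site_id, trace$channel, trace$time, noisy,
                  background = rep(config$background, length(noisy)))
}
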