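#' Movie stack container
#'
#' One channel's image time series plus acquisition metadata. `data` is a
#' `(height, width, frames)` array in a.u.; `times` gives each frame's
#' acquisition time (frame `k` at `(k-1) * dt` unless stated otherwise,
#' as for the Gag channel which is imaged only at the start and end of
#' the record).
#'
#' @param data 3-D numeric array `(height, width, frames)`.
#' @param times numeric frame times (s).
#' @param channel channel label.
#' @param psf_sigma PSF sigma (px) used to render/expected in the data.
#' @param background nominal background level (a.u./pixel).
#' @return object of class `MovieStack`.
#' @export
movie_stack <- function(data, times, channel = "unknown",
                        psf_sigma = NA_real_, background = 0) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(times))
  structure(
    list(data = data, times = as.numeric(times), channel = channel,
         psf_sigma = psf_sigma, background = background),
    class = "MovieStack"
  )
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<MovieStack> %s: %d x %d px, %d frames (%.4g - %.4g s)\n",
              x$channel, d[1], d[2], d[3], min(x$times), max(x$times)))
  invisible(x)
}

# Integrated 2-D Gaussian footprint of a unit-amplitude spot over a pixel
# window; rows/cols are 0-based pixel indices, (r0, c0) the subpixel
# center. Sums to 1 over the full plane.
gaussian_footprint <- function(rows, cols, r0, c0, sigma) {
  pr <- stats::pnorm(rows + 0.5, r0, sigma) - stats::pnorm(rows - 0.5, r0, sigma)
  pc <- stats::pnorm(cols + 0.5, c0, sigma) - stats::pnorm(cols - 0.5, c0, sigma)
  outer(pr, pc)
}

#' Render a cohort into synthetic TIRF movie stacks
#'
#' Each event is a stationary sub-diffraction spot: an integrated 2-D
#' Gaussian of width `psf_sigma` whose summed amplitude at frame `k`
#' equals the event's kinetic trace value at time `(k-1) * dt`. The two
#' ESCRT channels get the full time series; the Gag reference channel is
#' rendered for the first and last frame times only. A constant
#' background is added, then (optionally) Poisson shot noise and Gaussian
#' read noise per pixel.
#'
#' @param events an `EventCohort` from [simulate_cohort()], or a list of
#'   [event_spec()] (then `dims` must be given in `config`).
#' @param config the [sim_config()] used to draw the cohort.
#' @param seed integer seed for the noise.
#' @param noise logical; `FALSE` returns the exact expected images.
#' @return list with `channels` (named list of [movie_stack()]: `early`,
#'   `late`, `gag`), `truth` (ground-truth table incl. per-frame true
#'   intensities as attribute `traces`), and `config`.
#' @export
render_movie <- function(events, config, seed = 1, noise = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  dims <- attr(events, "dims") %||% config$dims
  if (is.null(dims)) stop_invalid("image dims unknown; pass a cohort or set config$dims")
  sigma <- config$psf_sigma
  margin <- 3 * sigma
  pos <- vapply(events, function(e) e$position, numeric(2))
  if (length(events)) {
    if (any(pos[1, ] < margin | pos[1, ] > dims[1] - 1 - margin |
            pos[2, ] < margin | pos[2, ] > dims[2] - 1 - margin)) {
      stop_invalid("event positions must lie >= 3*psf_sigma inside the image")
    }
    if (length(events) > 1L) {
      d <- as.matrix(stats::dist(t(pos)))
      diag(d) <- Inf
      if (min(d) < 4 * sigma) {
        warning("events closer than 4*psf_sigma: photometry contract void")
      }
    }
  }
  times <- (seq_len(config$n_frames) - 1) * config$dt
  gag_times <- times[c(1L, length(times))]

  render_channel <- function(channel, ch_times) {
    arr <- array(config$background, c(dims[1], dims[2], length(ch_times)))
    for (ev in events) {
      tr <- simulate_trace(ev, channel, ch_times)
      r0 <- ev$position[1]; c0 <- ev$position[2]
      wr <- max(0, floor(r0 - 6 * sigma)):min(dims[1] - 1, ceiling(r0 + 6 * sigma))
      wc <- max(0, floor(c0 - 6 * sigma)):min(dims[2] - 1, ceiling(c0 + 6 * sigma))
      fp <- gaussian_footprint(wr, wc, r0, c0, sigma)
      # stationary spot: one footprint, amplitude modulated per frame
      contrib <- array(as.vector(fp) %o% tr$raw,
                       c(length(wr), length(wc), length(ch_times)))
      arr[wr + 1L, wc + 1L, ] <- arr[wr + 1L, wc + 1L, ] + contrib
    }
    arr
  }

  stacks <- list(
    early = render_channel("early", times),
    late  = render_channel("late", times),
    gag   = render_channel("gag", gag_times)
  )
  if (noise) {
    stacks <- with_seed(seed, lapply(stacks, function(arr) {
      n <- length(arr)
      noisy <- stats::rpois(n, config$gain * pmax(arr, 0)) / config$gain
      if (config$read_sd > 0) noisy <- noisy + stats::rnorm(n, 0, config$read_sd)
      array(noisy, dim(arr))
    }))
  }
  channels <- list(
    early = movie_stack(stacks$early, times, "early", sigma, config$background),
    late  = movie_stack(stacks$late, times, "late", sigma, config$background),
    gag   = movie_stack(stacks$gag, gag_times, "gag", sigma, config$background)
  )
  truth <- if (inherits(events, "EventCohort")) as.data.frame(events) else NULL
  true_traces <- do.call(rbind, lapply(events, function(ev) {
    do.call(rbind, lapply(c("early", "late"), function(ch) {
      tr <- simulate_trace(ev, ch, times)
      data.frame(event_id = ev$id, channel = ch,
                 frame = seq_along(times) - 1L, time_s = times,
                 intensity = tr$raw)
    }))
  }))
  attr(truth, "traces") <- true_traces
  list(channels = channels, truth = truth, config = config)
}

#' Write rendered movie channels as TIFF stacks plus sidecars
#'
#' Writes one multi-page 16-bit TIFF per channel, the ground-truth table
#' as CSV and the simulation configuration as a JSON sidecar.
#'
#' @param movie result of [render_movie()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_movie <- function(movie, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (ch in names(movie$channels)) {
    p <- file.path(dir, paste0(ch, ".tif"))
    write_tiff_stack(movie$channels[[ch]]$data, p)
    paths[ch] <- p
  }
  if (!is.null(movie$truth)) {
    utils::write.csv(movie$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(movie$truth, "traces"),
                     file.path(dir, "ground_truth_traces.csv"),
                     row.names = FALSE)
    paths["truth"] <- file.path(dir, "ground_truth.csv")
  }
  cfg <- movie$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "params")],
                       file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  paths["config"] <- file.path(dir, "sim_config.json")
  invisible(paths)
}
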