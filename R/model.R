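#' Per-channel three-phase kinetic parameters
#'
#' Describes one channel's ground-truth recruitment kinetics at a budding
#' site: a sigmoidal assembly (phase I), a plateau of duration `tau_ret`
#' (phase II) and a sigmoidal disassembly (phase III). A `locked` channel
#' (ATP depletion) never disassembles and plateaus at
#' `lock_multiplier * A2`.
#'
#' The realized curve is the smooth sigmoid-pulse
#' \deqn{I(t) = A_1 + (A_{eff} - A_1)\, \sigma_r(t)\, \sigma_f(t)}
#' with \eqn{\sigma_r(t) = 1/(1 + e^{-(t - t_{0a})/dx_a})} and
#' \eqn{\sigma_f(t) = 1/(1 + e^{ (t - t_{0d})/dx_d})} (the falling factor is
#' dropped when `locked`). The disassembly midpoint is placed so that the
#' interval between the assembly sigmoid reaching 90% of its range and the
#' disassembly sigmoid falling below 90% equals `tau_ret` exactly:
#' `t0_d = t0_a + log(9) * dx_a + tau_ret + log(9) * dx_d`.
#'
#' @param A1 baseline (a.u.), `>= 0`.
#' @param A2 plateau (a.u.), `> A1`.
#' @param t0_a assembly midpoint (s).
#' @param dx_a assembly width (s), `> 0`.
#' @param tau_ret retention duration (s), `>= 0`.
#' @param dx_d disassembly width (s), `> 0`.
#' @param locked logical; `TRUE` suppresses phase III.
#' @param lock_multiplier plateau scaling under ATP depletion, `>= 1`.
#' @param release_time for ATP-repletion traces: time (s) at which a locked
#'   structure is released and disassembly begins (the falling sigmoid's
#'   90% point is placed at `release_time`); `NA` otherwise.
#' @return an object of class `ChannelKinetics`.
#' @export
channel_kinetics <- function(A1 = 0, A2, t0_a, dx_a, tau_ret, dx_d,
                             locked = FALSE, lock_multiplier = 1,
                             release_time = NA_real_) {
  if (!(A2 > A1) || A1 < 0) stop_invalid("need A2 > A1 >= 0")
  if (dx_a <= 0) stop_invalid("dx_a must be > 0")
  if (dx_d <= 0) stop_invalid("dx_d must be > 0")
  if (tau_ret < 0) stop_invalid("tau_ret must be >= 0")
  if (lock_multiplier < 1) stop_invalid("lock_multiplier must be >= 1")
  structure(
    list(A1 = A1, A2 = A2, t0_a = t0_a, dx_a = dx_a, tau_ret = tau_ret,
         dx_d = dx_d, locked = isTRUE(locked),
         lock_multiplier = lock_multiplier, release_time = release_time),
    class = "ChannelKinetics"
  )
}

# Derived instants of a ChannelKinetics (all in seconds).
ck_assembly_end <- function(ck) ck$t0_a + LN9 * ck$dx_a            # 90% of rise
ck_disassembly_onset <- function(ck) {
  if (ck$locked) return(NA_real_)
  if (is.finite(ck$release_time %||% NA_real_)) return(ck$release_time)
  ck_assembly_end(ck) + ck$tau_ret
}
ck_t0_d <- function(ck) ck_disassembly_onset(ck) + LN9 * ck$dx_d   # fall midpoint

#' Ground-truth specification of one budding event
#'
#' Bundles a site position, a phenotype label, per-channel
#' [channel_kinetics()] for the two ESCRT channels, and a constant Gag
#' amplitude. Phenotypes follow the observed classes: in the major
#' phenotype the late channel (VPS4) keeps its plateau for some seconds
#' after the early channel (ALIX/CHMP4b) has disassembled
#' (`delayed_late_channel`); in the minor phenotype both disassemble
#' together (`co_disassembly`); under ATP depletion both are `locked`.
#'
#' @param id integer event id.
#' @param position numeric `(row, col)` pixel position (0-based, subpixel).
#' @param phenotype one of `"delayed_late_channel"`, `"co_disassembly"`,
#'   `"locked"`.
#' @param early,late [channel_kinetics()] for the early and late ESCRT
#'   channels.
#' @param gag_amplitude constant Gag channel intensity (a.u.).
#' @param condition `"WT"`, `"ATP_depleted"` or `"ATP_repleted"`.
#' @return an object of class `EventSpec`.
#' @export
event_spec <- function(id, position, phenotype, early, late,
                       gag_amplitude,
                       condition = c("WT", "ATP_depleted", "ATP_repleted")) {
  condition <- match.arg(condition)
  phenotype <- match.arg(phenotype,
                         c("delayed_late_channel", "co_disassembly", "locked"))
  stopifnot(inherits(early, "ChannelKinetics"),
            inherits(late, "ChannelKinetics"),
            length(position) == 2, gag_amplitude > 0)
  if (phenotype == "locked" && !(early$locked && late$locked)) {
    stop_invalid("locked phenotype requires both channels locked")
  }
  if (phenotype == "delayed_late_channel" && !early$locked && !late$locked) {
    gap <- ck_disassembly_onset(late) - ck_disassembly_onset(early)
    if (!is.na(gap) && gap <= 0) {
      stop_invalid("delayed_late_channel requires a strictly positive ",
                   "late-minus-early disassembly onset gap (got ",
                   signif(gap, 3), " s)")
    }
  }
  structure(
    list(id = id, position = as.numeric(position), phenotype = phenotype,
         early = early, late = late, gag_amplitude = gag_amplitude,
         condition = condition),
    class = "EventSpec"
  )
}

#' Background-corrected intensity-versus-time trace
#'
#' Container for one event/channel trace: time base, raw (background
#' corrected) intensities and, once [normalize_traces()] has been applied,
#' the normalized intensities and the cohort scale factor.
#'
#' @param site_id site/event identifier.
#' @param channel channel label (e.g. `"early"`, `"late"`, `"gag"`).
#' @param time numeric time base (s), strictly increasing.
#' @param raw raw intensity (a.u.), same length as `time`.
#' @param background per-frame local background (a.u./pixel).
#' @param normalized normalized intensity or `NULL`.
#' @param scale cohort normalization scale factor (`NA` until normalized).
#' @return an object of class `IntensityTrace`.
#' @export
intensity_trace <- function(site_id, channel, time, raw,
                            background = rep(0, length(time)),
                            normalized = NULL, scale = NA_real_) {
  time <- as.numeric(time)
  raw <- as.numeric(raw)
  if (length(time) == 0L) stop_invalid("empty time base")
  if (length(raw) != length(time)) stop_invalid("time/raw length mismatch")
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop_invalid("time must be strictly increasing")
  }
  structure(
    list(site_id = site_id, channel = channel, time = time, raw = raw,
         background = as.numeric(background), normalized = normalized,
         scale = scale),
    class = "IntensityTrace"
  )
}

# Working values of a trace: normalized if available, else raw.
trace_values <- function(trace) trace$normalized %||% trace$raw

# Robust per-trace maximum: max of the 3-frame median-smoothed values.
# Used consistently by normalization and cohort summaries.
trace_max <- function(trace, smooth_frames = 3L, use = c("raw", "values")) {
  use <- match.arg(use)
  x <- if (use == "raw") trace$raw else trace_values(trace)
  max(median_smooth(x, smooth_frames))
}

#' @export
print.IntensityTrace <- function(x, ...) {
  cat(sprintf(
    "<IntensityTrace> site %s / %s: %d frames, dt = %.4g s, max(raw) = %.4g a.u.%s\n",
    format(x$site_id), x$channel, length(x$time),
    if (length(x$time) > 1) x$time[2] - x$time[1] else NA,
    max(x$raw),
    if (!is.null(x$normalized)) sprintf(", scale = %.4g", x$scale) else ""
  ))
  invisible(x)
}

#' Simulate a noise-free ground-truth trace
#'
#' Evaluates an event's three-phase kinetic model for one channel on a
#' given time base. The result is the exact expected signal; add camera
#' noise with [add_noise()].
#'
#' @param spec an [event_spec()].
#' @param channel `"early"`, `"late"` or `"gag"` (Gag is constant).
#' @param times strictly increasing numeric time base (s).
#' @param seed unused (the ground truth is deterministic); kept so all
#'   simulation entry points share a signature.
#' @return an [intensity_trace()] with the noise-free signal in `raw`.
#' @export
simulate_trace <- function(spec, channel = c("early", "late", "gag"),
                           times, seed = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(spec, "EventSpec"))
  times <- as.numeric(times)
  if (length(times) == 0L) stop_invalid("'times' is empty")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_invalid("'times' must be strictly increasing")
  }
  raw <- if (channel == "gag") {
    rep(spec$gag_amplitude, length(times))
  } else {
    eval_channel_kinetics(spec[[channel]], times)
  }
  intensity_trace(spec$id, channel, times, raw)
}

# Smooth sigmoid-pulse evaluation of a ChannelKinetics.
eval_channel_kinetics <- function(ck, t) {
  amp <- if (ck$locked) ck$lock_multiplier * ck$A2 else ck$A2
  rise <- 1 / (1 + exp(-(t - ck$t0_a) / ck$dx_a))
  fall <- if (ck$locked) 1 else 1 / (1 + exp((t - ck_t0_d(ck)) / ck$dx_d))
  ck$A1 + (amp - ck$A1) * rise * fall
}
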