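#' Segment a trace into the three recruitment phases
#'
#' On the `smooth_frames`-frame median-smoothed trace, the plateau level
#' is the mean of the top decile of smoothed values. Phase I ends
#' (`t_I_end`) at the first time the smoothed trace reaches
#' `level_frac` (90%) of the plateau above baseline; phase II ends
#' (`t_II_end`) at the last time it remains above that level before a
#' sustained decline (at least `decline_frames` consecutive frames
#' below). If no sustained decline occurs the trace is `locked`
#' (censored) and `t_II_end` is the record end.
#'
#' A trace qualifies as containing a recruitment event when the smoothed
#' maximum exceeds the baseline (median of the lowest decile) by more
#' than 5 robust noise SDs, the noise SD being estimated from first
#' differences of the raw samples.
#'
#' @param trace an [intensity_trace()] with at least 20 frames.
#' @param smooth_frames median smoothing window (frames).
#' @param decline_frames consecutive below-level frames that count as a
#'   sustained decline.
#' @param level_frac fraction of the plateau defining "full recruitment".
#' @return list with `t_I_end`, `t_II_end` (s), `locked`, `status`
#'   (`"ok"` or `"no-event"`), `plateau`, `baseline`.
#' @export
segment_phases <- function(trace, smooth_frames = 5, decline_frames = 5,
                           level_frac = 0.9) {
  stopifnot(inherits(trace, "IntensityTrace"))
  x <- trace_values(trace)
  t <- trace$time
  if (length(x) < 20L) stop_invalid("trace shorter than 20 frames")
  s <- median_smooth(x, smooth_frames)
  plateau <- mean(s[s >= stats::quantile(s, 0.9)])
  baseline <- stats::median(s[s <= stats::quantile(s, 0.1)])
  noise <- diff_noise_sd(x)
  if (!((plateau - baseline) > 0) || (max(s) - baseline) <= 5 * noise) {
    return(list(t_I_end = NA_real_, t_II_end = NA_real_, locked = FALSE,
                status = "no-event", plateau = plateau, baseline = baseline))
  }
  level <- baseline + level_frac * (plateau - baseline)
  above <- s >= level
  i1 <- which(above)[1]
  if (is.na(i1)) {
    return(list(t_I_end = NA_real_, t_II_end = NA_real_, locked = FALSE,
                status = "no-event", plateau = plateau, baseline = baseline))
  }
  # sustained decline: first run of >= decline_frames below-level frames
  # after i1
  below <- !above
  below[seq_len(i1)] <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  decl <- which(r$values & r$lengths >= decline_frames)
  if (length(decl) == 0L) {
    list(t_I_end = t[i1], t_II_end = t[length(t)], locked = TRUE,
         status = "ok", plateau = plateau, baseline = baseline)
  } else {
    d0 <- starts[decl[1]]
    last_above <- max(which(above[seq_len(d0 - 1L)]))
    list(t_I_end = t[i1], t_II_end = t[last_above], locked = FALSE,
         status = "ok", plateau = plateau, baseline = baseline)
  }
}
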