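# Dual-channel phenotype classification and cohort-level statistics.

#' Classify a dual-channel event
#'
#' Computes the late-minus-early disassembly-onset delay
#' \eqn{\Delta\tau} from the fitted sigmoids' 90% crossings
#' (`t0_d - log(9) dx_d`) and classifies: `delayed_late_channel` when
#' \eqn{\Delta\tau >} `delay_threshold` (the major phenotype, "the late
#' channel's platform remains"), `co_disassembly` when
#' \eqn{|\Delta\tau| \le} threshold, `locked` when both channels are
#' censored (no disassembly within the record), otherwise
#' `unclassifiable`.
#'
#' @param fit_early,fit_late [fit_event()] results for the early and late
#'   channel of one site.
#' @param delay_threshold delay (s) separating major from minor
#'   phenotype.
#' @return object of class `EventPhenotype`: list with `site_id`,
#'   `class`, `delay_s`, `max_early`, `max_late`, `scale`, `reason`.
#' @export
classify_event <- function(fit_early, fit_late, delay_threshold = 5) {
  stopifnot(inherits(fit_early, "KineticFit"), inherits(fit_late, "KineticFit"))
  out <- list(site_id = fit_early$site_id, class = "unclassifiable",
              delay_s = NA_real_, max_early = fit_early$max_intensity,
              max_late = fit_late$max_intensity,
              scale = fit_early$scale %||% NA_real_, reason = "")
  if (fit_early$status == "no-event" || fit_late$status == "no-event") {
    out$reason <- "no recruitment event in one channel"
    return(structure(out, class = "EventPhenotype"))
  }
  if (fit_early$censored && fit_late$censored) {
    out$class <- "locked"
    return(structure(out, class = "EventPhenotype"))
  }
  if (fit_early$status != "ok" || fit_late$status != "ok" ||
      fit_early$censored || fit_late$censored) {
    out$reason <- "poor or one-sided censored fits"
    return(structure(out, class = "EventPhenotype"))
  }
  onset <- function(f) f$fit_disassembly$t0 - LN9 * f$fit_disassembly$dx
  delay <- onset(fit_late) - onset(fit_early)
  out$delay_s <- delay
  out$class <- if (delay > delay_threshold) "delayed_late_channel"
               else if (abs(delay) <= delay_threshold) "co_disassembly"
               else "unclassifiable"
  if (out$class == "unclassifiable") out$reason <- "early channel delayed"
  structure(out, class = "EventPhenotype")
}

#' Compare normalized maxima between conditions
#'
#' Fold change of the mean normalized maximum intensity,
#' `mean(depleted) / mean(WT)`, with a seeded bootstrap 95% interval.
#' Both cohorts must have been normalized with a shared scale factor —
#' mixing per-cohort scales would silently cancel the effect the
#' comparison measures, so it is an error.
#'
#' @param wt,depleted lists of `EventPhenotype`.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return list with `fold_change`, `ci` (2.5/97.5 percentiles),
#'   `mean_wt`, `mean_depleted`, `n_wt`, `n_depleted`.
#' @export
compare_conditions <- function(wt, depleted, n_boot = 2000, seed = 1) {
  if (length(wt) == 0L || length(depleted) == 0L) {
    stop_invalid("both cohorts must be non-empty")
  }
  maxima <- function(ph) {
    unlist(lapply(ph, function(p) c(p$max_early, p$max_late)))
  }
  scales <- unlist(lapply(c(wt, depleted), `[[`, "scale"))
  scales <- scales[is.finite(scales)]
  if (length(scales) && diff(range(scales)) > 1e-9 * max(abs(scales))) {
    stop_invalid("cohorts were normalized with different scale factors; ",
                 "re-normalize with a shared scale before comparing")
  }
  mw <- maxima(wt); md <- maxima(depleted)
  fold <- mean(md) / mean(mw)
  ci <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      mean(sample(md, replace = TRUE)) / mean(sample(mw, replace = TRUE))
    }, numeric(1))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  })
  list(fold_change = fold, ci = ci, mean_wt = mean(mw),
       mean_depleted = mean(md), n_wt = length(wt),
       n_depleted = length(depleted))
}

#' Aggregate cohort statistics
#'
#' Per-channel means and SDs of assembly/disassembly rates, retention
#' time and total assembly time; phenotype fractions with counts; mean
#' and SD of normalized maxima. Events with poor fits are excluded from
#' the rate/time summaries (the study's calculations use the major
#' phenotype; set `major_only = FALSE` to include minor-phenotype events
#' in the kinetic summaries).
#'
#' @param fits list of `KineticFit` (both channels, any order).
#' @param phenotypes list of `EventPhenotype`.
#' @param major_only restrict kinetic summaries to the major phenotype.
#' @return object of class `CohortSummary`.
#' @export
summarize_cohort <- function(fits, phenotypes, major_only = TRUE) {
  if (length(phenotypes) == 0L) stop_invalid("need >= 1 classified event")
  cls <- vapply(phenotypes, `[[`, character(1), "class")
  classified <- cls[cls != "unclassifiable"]
  frac <- if (length(classified)) {
    table(factor(classified,
                 c("delayed_late_channel", "co_disassembly", "locked"))) /
      length(classified)
  } else {
    table(factor(character(0),
                 c("delayed_late_channel", "co_disassembly", "locked")))
  }
  keep_ids <- vapply(phenotypes, function(p) as.numeric(p$site_id), numeric(1))
  use_ids <- if (major_only) keep_ids[cls == "delayed_late_channel"] else
    keep_ids[cls != "unclassifiable"]
  rows <- do.call(rbind, lapply(fits, kinetic_fit_row))
  kin <- rows[rows$status == "ok" & rows$site_id %in% use_ids, , drop = FALSE]
  stat <- function(x) {
    x <- x[is.finite(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      n = length(x))
  }
  per_channel <- lapply(split(kin, kin$channel), function(d) {
    list(r_a = stat(d$r_a), r_d = stat(d$r_d), tau_ret = stat(d$tau_ret),
         T_a = stat(d$T_a), max_intensity = stat(d$max_intensity))
  })
  maxima <- unlist(lapply(phenotypes, function(p) c(p$max_early, p$max_late)))
  structure(
    list(n_events = length(phenotypes), n_classified = length(classified),
         n_unclassifiable = sum(cls == "unclassifiable"),
         phenotype_fractions = as.list(frac),
         phenotype_counts = as.list(table(factor(classified,
           c("delayed_late_channel", "co_disassembly", "locked")))),
         per_channel = per_channel, maxima = stat(maxima),
         major_only = major_only),
    class = "CohortSummary"
  )
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("<CohortSummary> %d events (%d classified, %d unclassifiable)\n",
              x$n_events, x$n_classified, x$n_unclassifiable))
  fr <- unlist(x$phenotype_fractions)
  cat("  phenotypes:",
      paste(sprintf("%s %.0f%%", names(fr), 100 * fr), collapse = ", "), "\n")
  for (ch in names(x$per_channel)) {
    pc <- x$per_channel[[ch]]
    cat(sprintf(
      "  %s: r_a %.3g +/- %.3g, r_d %.3g +/- %.3g a.u./s; tau %.3g +/- %.3g s; T_a %.3g +/- %.3g s (n=%d)\n",
      ch, pc$r_a["mean"], pc$r_a["sd"], pc$r_d["mean"], pc$r_d["sd"],
      pc$tau_ret["mean"], pc$tau_ret["sd"], pc$T_a["mean"], pc$T_a["sd"],
      as.integer(pc$r_a["n"])))
  }
  invisible(x)
}
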