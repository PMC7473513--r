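# Build dual-channel events with a constructed onset gap and classify the
# fitted kinetics.
dual_event_fits <- function(gap, tau_late = 15, locked = FALSE) {
  times <- default_times()
  ck_late <- channel_kinetics(A1 = 0, A2 = 5000, t0_a = 13, dx_a = 1.2,
                              tau_ret = tau_late, dx_d = 1.2,
                              locked = locked)
  tau_early <- (ck_late$t0_a + log(9) * ck_late$dx_a + tau_late - gap) -
    (12 + log(9) * 1.0)
  ck_early <- channel_kinetics(A1 = 0, A2 = 5200, t0_a = 12, dx_a = 1.0,
                               tau_ret = max(tau_early, 0), dx_d = 1.0,
                               locked = locked)
  ev <- event_spec(1, c(20, 20),
                   if (locked) "locked" else if (gap > 0)
                     "delayed_late_channel" else "co_disassembly",
                   ck_early, ck_late, 8000,
                   condition = if (locked) "ATP_depleted" else "WT")
  list(early = fit_event(simulate_trace(ev, "early", times)),
       late = fit_event(simulate_trace(ev, "late", times)))
}

test_that("a built-in 10 s late-channel delay is classified major", {
  f <- dual_event_fits(gap = 10)
  ph <- classify_event(f$early, f$late)
  expect_equal(ph$class, "delayed_late_channel")
  expect_lt(abs(ph$delay_s - 10), 0.5)
})

test_that("co-disassembly and locked events are classified as such", {
  f0 <- dual_event_fits(gap = 0)
  expect_equal(classify_event(f0$early, f0$late)$class, "co_disassembly")
  fl <- dual_event_fits(gap = 0, locked = TRUE)
  expect_equal(classify_event(fl$early, fl$late)$class, "locked")
})

test_that("a channel without an event is unclassifiable with a reason", {
  f <- dual_event_fits(gap = 10)
  noev <- fit_event(intensity_trace(
    1, "early", default_times(),
    escrtkinetics:::with_seed(3, rnorm(300, 100, 10))))
  ph <- classify_event(noev, f$late)
  expect_equal(ph$class, "unclassifiable")
  expect_match(ph$reason, "no recruitment")
})

test_that("channel relabeling flips the delay sign", {
  f <- dual_event_fits(gap = 10)
  ph <- classify_event(f$early, f$late)
  sw <- classify_event(f$late, f$early)
  expect_equal(sw$delay_s, -ph$delay_s, tolerance = 1e-9)
  expect_false(sw$class == "delayed_late_channel")
})

make_pheno <- function(id, max_early, max_late, scale = 1,
                       class = "delayed_late_channel") {
  structure(list(site_id = id, class = class, delay_s = 10,
                 max_early = max_early, max_late = max_late,
                 scale = scale, reason = ""),
            class = "EventPhenotype")
}

test_that("fold change is exact on constructed cohorts", {
  wt <- lapply(1:20, function(i) make_pheno(i, 4000 + 50 * i, 5000))
  dep <- lapply(1:20, function(i) make_pheno(i, 2 * (4000 + 50 * i), 10000,
                                             class = "locked"))
  cmp <- compare_conditions(wt, dep, n_boot = 500, seed = 2)
  expect_equal(cmp$fold_change, 2, tolerance = 1e-12)
  expect_true(cmp$ci[1] <= 2 && 2 <= cmp$ci[2])
  same <- compare_conditions(wt, wt, n_boot = 200, seed = 2)
  expect_equal(same$fold_change, 1)
})

test_that("mixed normalization scales abort the comparison", {
  wt <- lapply(1:5, function(i) make_pheno(i, 4000, 5000, scale = 1))
  dep <- lapply(1:5, function(i) make_pheno(i, 8000, 10000, scale = 2))
  expect_error(compare_conditions(wt, dep, n_boot = 100), "scale")
  expect_error(compare_conditions(list(), dep), "non-empty")
})

test_that("cohort summaries conserve counts and fractions", {
  f <- dual_event_fits(gap = 10)
  phenos <- c(lapply(1:6, function(i) make_pheno(i, 4000, 5000)),
              lapply(7:8, function(i) make_pheno(i, 4000, 5000,
                                                 class = "co_disassembly")),
              list(make_pheno(9, NA, NA, class = "unclassifiable")))
  s <- summarize_cohort(list(f$early, f$late), phenos)
  expect_equal(s$n_events, 9)
  expect_equal(s$n_classified + s$n_unclassifiable, 9)
  expect_equal(sum(unlist(s$phenotype_fractions)), 1)
  expect_equal(unname(unlist(s$phenotype_counts)), c(6, 2, 0))
})

test_that("single-event summaries report means without SDs", {
  f <- dual_event_fits(gap = 10)
  ph <- classify_event(f$early, f$late)
  s <- summarize_cohort(list(f$early, f$late), list(ph))
  expect_equal(unname(s$per_channel$late$tau_ret["mean"]), f$late$tau_ret)
  expect_true(is.na(s$per_channel$late$tau_ret["sd"]))
})

test_that("cohort rate ratios recover the generating kinetics", {
  cfg <- sim_config(n_events = 120)
  co <- simulate_cohort(cfg, seed = 23)
  times <- default_times()
  fits <- list(); phenos <- list()
  for (ev in co) {
    fe <- fit_event(add_noise(simulate_trace(ev, "early", times), cfg,
                              seed = 4000 + 2 * ev$id))
    fl <- fit_event(add_noise(simulate_trace(ev, "late", times), cfg,
                              seed = 4001 + 2 * ev$id))
    fits <- c(fits, list(fe, fl))
    phenos <- c(phenos, list(classify_event(fe, fl)))
  }
  s <- summarize_cohort(fits, phenos)
  est_ratio <- s$per_channel$late$r_a[["mean"]] /
    s$per_channel$early$r_a[["mean"]]
  truth <- as.data.frame(co)
  major <- truth$phenotype == "delayed_late_channel"
  true_ratio <- mean(truth$rate_assembly[major & truth$channel == "late"]) /
    mean(truth$rate_assembly[major & truth$channel == "early"])
  expect_rel_equal(est_ratio, true_ratio, 0.15)
  # the late channel assembles more slowly by construction
  expect_lt(est_ratio, 1)
})
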