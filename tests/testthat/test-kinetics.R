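test_that("segmentation recovers the constructed phase boundaries", {
  times <- default_times()
  tr <- simulate_trace(clean_event(tau = 15), "late", times)
  seg <- segment_phases(tr)
  expect_equal(seg$status, "ok")
  expect_false(seg$locked)
  # gap between threshold crossings equals the retention within 1 frame
  expect_lt(abs((seg$t_II_end - seg$t_I_end) - 15), 0.2 + 1e-9)
})

test_that("locked traces are censored at the record end", {
  tr <- simulate_trace(clean_event(locked = TRUE, phenotype = "locked"),
                       "late", default_times())
  seg <- segment_phases(tr)
  expect_true(seg$locked)
  expect_equal(seg$t_II_end, 59.8)
})

test_that("traces without an event are gated out", {
  x <- escrtkinetics:::with_seed(31, rnorm(300, 100, 10))
  seg <- segment_phases(intensity_trace(1, "early", default_times(), x))
  expect_equal(seg$status, "no-event")
  f <- fit_event(intensity_trace(1, "early", default_times(), x))
  expect_equal(f$status, "no-event")
  expect_true(is.na(f$r_a))
})

test_that("exact sigmoid samples are recovered to < 0.1%", {
  t <- seq(0, 30, by = 0.2)
  for (dir in c("rising", "falling")) {
    y <- boltzmann_curve(t, 200, 6200, 14, 1.7, dir)
    f <- fit_boltzmann_segment(intensity_trace(1, "x", t, y), c(0, 30), dir)
    expect_equal(f$status, "ok")
    expect_rel_equal(f$A1, 200, 0.001)
    expect_rel_equal(f$A2, 6200, 0.001)
    expect_rel_equal(f$t0, 14, 0.001)
    expect_rel_equal(f$dx, 1.7, 0.001)
  }
})

test_that("noisy sigmoids recover the width within 10% (median over seeds)", {
  t <- seq(0, 30, by = 0.2)
  y0 <- boltzmann_curve(t, 0, 5000, 14, 1.7)
  errs <- vapply(1:100, function(s) {
    y <- y0 + escrtkinetics:::with_seed(s, rnorm(length(t), 0, 100))
    f <- fit_boltzmann_segment(intensity_trace(1, "x", t, y), c(0, 30),
                               "rising")
    abs(f$dx - 1.7) / 1.7
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("degenerate windows are flagged poor but still report", {
  t <- seq(0, 10, by = 0.2)
  f <- fit_boltzmann_segment(intensity_trace(1, "x", t, rep(5, length(t))),
                             c(0, 10), "rising")
  expect_equal(f$status, "poor")
  expect_true(is.finite(f$dx))
  expect_error(fit_boltzmann_segment(intensity_trace(1, "x", t[1:5], 1:5),
                                     c(0, 0.8), "rising"),
               "10 samples")
})

test_that("rates follow the maximum-slope formula and its scaling laws", {
  fa <- list(A1 = 0, A2 = 10000, t0 = 10, dx = 25, status = "ok")
  expect_equal(unname(compute_rates(fa)["r_a"]), 100)
  f2 <- fa; f2$A2 <- 20000
  expect_equal(unname(compute_rates(f2)["r_a"]), 200)
  f3 <- fa; f3$dx <- 50
  expect_equal(unname(compute_rates(f3)["r_a"]), 50)
  # finite-difference oracle on the fitted curve
  tt <- seq(-100, 100, by = 1e-3)
  num <- max(diff(boltzmann_curve(tt, 0, 10000, 10, 25))) / 1e-3
  expect_rel_equal(num, unname(compute_rates(fa)["r_a"]), 0.001)
  poor <- fa; poor$status <- "poor"
  expect_true(is.na(compute_rates(poor)["r_a"]))
})

test_that("retention time follows the 90% crossing definition", {
  fa <- list(A1 = 0, A2 = 5000, t0 = 12, dx = 0.5, status = "ok")
  fd <- list(A1 = 0, A2 = 5000, t0 = 12 + log(9) * 0.5 + 15 + log(9) * 0.5,
             dx = 0.5, status = "ok")
  expect_equal(retention_time(fa, fd), 15)
  # co-terminal: disassembly starts exactly at assembly completion
  fd0 <- fd; fd0$t0 <- fa$t0 + log(9) * (fa$dx + fd$dx)
  expect_equal(retention_time(fa, fd0), 0)
  fd_neg <- fd; fd_neg$t0 <- fd0$t0 - 2
  expect_warning(tau <- retention_time(fa, fd_neg), "clipped")
  expect_equal(tau, 0)
})

test_that("steep generator traces yield the constructed retention", {
  tr <- simulate_trace(clean_event(tau = 15, dxa = 0.5, dxd = 0.5),
                       "late", default_times())
  f <- fit_event(tr)
  expect_equal(f$status, "ok")
  expect_lt(abs(f$tau_ret - 15), 0.5)
  # fitted boundaries are consistent: tau == t_II_end - t_I_end
  expect_equal(f$tau_ret, f$t_II_end - f$t_I_end, tolerance = 1e-9)
})

test_that("total assembly time depends on the width only", {
  fa <- list(A1 = 0, A2 = 5000, t0 = 12, dx = 2.276, status = "ok")
  expect_equal(total_assembly_time(fa), 10, tolerance = 1e-3)
  fa2 <- fa; fa2$A1 <- 1000; fa2$A2 <- 9000; fa2$t0 <- 40
  expect_equal(total_assembly_time(fa2), total_assembly_time(fa))
  fa3 <- fa; fa3$dx <- 1e-6
  expect_lt(total_assembly_time(fa3), 1e-4)
  expect_true(is.na(total_assembly_time(list(status = "poor", dx = 1))))
})

test_that("kinetic estimates are scale- and time-shift-equivariant", {
  times <- default_times()
  tr <- simulate_trace(clean_event(), "late", times)
  f <- fit_event(tr)
  for (c_scale in c(0.5, 3)) {
    fc <- fit_event(intensity_trace(1, "late", times, c_scale * tr$raw))
    expect_rel_equal(fc$r_a, c_scale * f$r_a, 1e-4)
    expect_rel_equal(fc$r_d, c_scale * f$r_d, 1e-4)
    expect_lt(abs(fc$tau_ret - f$tau_ret), 1e-3)
    expect_lt(abs(fc$T_a - f$T_a), 1e-3)
  }
  fs <- fit_event(intensity_trace(1, "late", times + 7, tr$raw))
  expect_lt(abs(fs$t_I_end - (f$t_I_end + 7)), 1e-3)
  expect_lt(abs(fs$t_II_end - (f$t_II_end + 7)), 1e-3)
  expect_rel_equal(fs$r_a, f$r_a, 1e-4)
  expect_lt(abs(fs$tau_ret - f$tau_ret), 1e-3)
  expect_lt(abs(fs$T_a - f$T_a), 1e-3)
})
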