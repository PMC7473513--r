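# Shared fixture builders. Everything is generated in code; no data files.

# A well-separated three-phase event: phases do not overlap, so segment
# fits are exactly identifiable.
clean_event <- function(id = 1, A2 = 5000, t0 = 12, dxa = 1.2, tau = 15,
                        dxd = 1.2, pos = c(20, 20),
                        phenotype = "co_disassembly", gag = 8000,
                        locked = FALSE, lock_multiplier = 1) {
  ck <- channel_kinetics(A1 = 0, A2 = A2, t0_a = t0, dx_a = dxa,
                         tau_ret = tau, dx_d = dxd, locked = locked,
                         lock_multiplier = lock_multiplier)
  event_spec(id, pos, phenotype, ck, ck, gag,
             condition = if (locked) "ATP_depleted" else "WT")
}

default_times <- function(n = 300, dt = 0.2) (seq_len(n) - 1) * dt

# A deterministic, identifiable 10-event parameter grid inside the
# default WT ranges (used by the noise-free oracle-equivalence checks).
grid_cohort <- function(n = 10) {
  A2 <- seq(3000, 8000, length.out = n)
  t0 <- seq(11, 16, length.out = n)
  Ta <- seq(6, 14, length.out = n)
  tau <- seq(10, 25, length.out = n)
  Td <- seq(4, 8, length.out = n)
  side <- ceiling(sqrt(n))
  events <- lapply(seq_len(n), function(i) {
    pos <- c(12 + ((i - 1) %/% side) * 20, 12 + ((i - 1) %% side) * 20)
    clean_event(i, A2 = A2[i], t0 = t0[i], dxa = Ta[i] / log(81),
                tau = tau[i], dxd = Td[i] / log(81), pos = pos)
  })
  dims <- rep(2 * 12 + side * 20, 2)
  structure(events, dims = dims, class = "EventCohort")
}

# Constant-signal trace whose smoothed maximum equals `value` exactly.
flat_trace <- function(value, id = 1, channel = "early", n = 30) {
  intensity_trace(id, channel, default_times(n), rep(value, n))
}

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
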