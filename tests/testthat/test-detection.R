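# Detection fixtures are rendered frames with known ground truth.

render_frame <- function(positions, amps, dims = c(64, 64), sigma = 1.3,
                         background = 100, noise_seed = NULL, read_sd = 10) {
  img <- matrix(background, dims[1], dims[2])
  for (i in seq_len(nrow(positions))) {
    rows <- 0:(dims[1] - 1); cols <- 0:(dims[2] - 1)
    pr <- pnorm(rows + 0.5, positions[i, 1], sigma) -
      pnorm(rows - 0.5, positions[i, 1], sigma)
    pc <- pnorm(cols + 0.5, positions[i, 2], sigma) -
      pnorm(cols - 0.5, positions[i, 2], sigma)
    img <- img + amps[i] * outer(pr, pc)
  }
  if (!is.null(noise_seed)) {
    img <- escrtkinetics:::with_seed(noise_seed, {
      matrix(rpois(length(img), img) + rnorm(length(img), 0, read_sd),
             dims[1], dims[2])
    })
  }
  img
}

test_that("well-separated spots are found with subpixel accuracy", {
  pos <- rbind(c(20.3, 15.8), c(40.6, 44.2), c(15.2, 48.9))
  frame <- render_frame(pos, amps = c(4000, 5000, 6000), noise_seed = 3)
  det <- detect_spots(frame, 1.3, threshold_snr = 5)
  expect_equal(nrow(det), 3L)
  for (i in seq_len(3)) {
    d <- sqrt((det$row - pos[i, 1])^2 + (det$col - pos[i, 2])^2)
    expect_lt(min(d), 0.5)
  }
  # determinism
  expect_identical(det, detect_spots(frame, 1.3, threshold_snr = 5))
})

test_that("blank frames yield no detections", {
  expect_equal(nrow(detect_spots(matrix(7, 32, 32), 1.3)), 0L)
  # noise-only false positives are rare at threshold 5
  fp <- vapply(1:50, function(s) {
    frame <- render_frame(matrix(numeric(0), 0, 2), numeric(0),
                          noise_seed = 100 + s)
    nrow(detect_spots(frame, 1.3, threshold_snr = 5))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.99)
})

test_that("detection is translation-equivariant and monotone in threshold", {
  pos <- rbind(c(22.5, 19.5), c(41.5, 40.5))
  frame <- render_frame(pos, c(5000, 5000))
  shifted <- render_frame(pos + 3, c(5000, 5000))
  d0 <- detect_spots(frame, 1.3)
  d3 <- detect_spots(shifted, 1.3)
  expect_equal(nrow(d3), nrow(d0))
  o0 <- d0[order(d0$row), ]; o3 <- d3[order(d3$row), ]
  expect_equal(o3$row, o0$row + 3, tolerance = 1e-6)
  expect_equal(o3$col, o0$col + 3, tolerance = 1e-6)
  frame_n <- render_frame(pos, c(5000, 2000), noise_seed = 11)
  counts <- vapply(c(1, 3, 5, 10, 50, 1000), function(thr) {
    nrow(detect_spots(frame_n, 1.3, thr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("noise-free separated spots give recall and precision 1", {
  cfg <- sim_config(n_events = 9, n_frames = 25)
  co <- simulate_cohort(cfg, seed = 13)
  mv <- render_movie(co, cfg, noise = FALSE)
  det <- detect_spots(mv$channels$gag$data[, , 1], cfg$psf_sigma, 5)
  pos <- t(vapply(co, function(e) e$position, numeric(2)))
  expect_equal(nrow(det), nrow(pos))
  d <- vapply(seq_len(nrow(pos)), function(i) {
    min(sqrt((det$row - pos[i, 1])^2 + (det$col - pos[i, 2])^2))
  }, numeric(1))
  expect_true(all(d < 0.5))
})

test_that("build_event_sites matches greedily and applies the threshold", {
  det <- data.frame(row = c(10, 30, 50), col = c(10, 30, 50),
                    peak = c(5, 4, 3), quality = "ok")
  sites <- build_event_sites(det, det, max_displacement = 2)
  expect_true(all(sites$status == "valid"))
  expect_equal(sites$displacement_px, rep(0, 3))
  moved <- det
  moved$row[2] <- moved$row[2] + 5
  sites2 <- build_event_sites(det, moved, max_displacement = 2)
  expect_equal(sum(sites2$status == "valid"), 2L)
  expect_match(sites2$reason[sites2$status == "rejected"][1], "displacement")
})

test_that("simulated stationary VLPs are recovered as valid sites", {
  cfg <- sim_config(n_events = 10)
  co <- simulate_cohort(cfg, seed = 7)
  mv <- render_movie(co, cfg, seed = 8, noise = TRUE)
  g <- mv$channels$gag$data
  sites <- build_event_sites(detect_spots(g[, , 1], 1.3, 5),
                             detect_spots(g[, , 2], 1.3, 5), 2)
  expect_gte(sum(sites$status == "valid"), 9L)
})

test_that("colocalize applies the radius inclusively", {
  site <- data.frame(site_id = 1, row = 20, col = 20)
  det <- data.frame(row = 20, col = 20, peak = 1, quality = "ok")
  hit <- colocalize(site, det, radius = 2)
  expect_true(hit$colocalized)
  expect_equal(hit$offset, c(0, 0))
  far <- data.frame(row = 20, col = 22.4, peak = 1, quality = "ok")
  expect_false(colocalize(site, far, radius = 2)$colocalized)
  expect_false(colocalize(site, det[0, ], radius = 2)$colocalized)
})

test_that("coincident ESCRT events colocalize with Gag sites", {
  cfg <- sim_config(n_events = 10)
  co <- simulate_cohort(cfg, seed = 17)
  mv <- render_movie(co, cfg, seed = 18, noise = TRUE)
  sites <- build_event_sites(
    detect_spots(mv$channels$gag$data[, , 1], 1.3, 5),
    detect_spots(mv$channels$gag$data[, , 2], 1.3, 5), 2)
  valid <- sites[sites$status == "valid", ]
  proj <- apply(mv$channels$early$data, c(1, 2), mean)
  det <- detect_spots(proj, 1.3, 5)
  rate <- mean(vapply(seq_len(nrow(valid)), function(i) {
    colocalize(valid[i, ], det, 2)$colocalized
  }, logical(1)))
  expect_gte(rate, 0.95)
})
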