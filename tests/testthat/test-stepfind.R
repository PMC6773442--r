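# Step detection, dwell histograms, pause extraction, step-size statistics.

test_that("both detectors are exact on noiseless staircases", {
  y <- rep(c(0, 3.9, 7.8, 11.8, 15.7), each = 150)
  for (f in list(tstep_find(y, dt = 0.005), km_step_find(y, dt = 0.005))) {
    expect_equal(nrow(f), 5)
    expect_equal(f$level, c(0, 3.9, 7.8, 11.8, 15.7))
    expect_equal(f$end[-5], c(150, 300, 450, 600))
  }
})

test_that("pure noise yields few false splits and a near-unity counter-fit quality", {
  set.seed(12)
  y <- rnorm(10000, sd = 14)
  ft <- tstep_find(y, dt = 0.005, alpha = 0.01)
  # false-split rate well under 1% of candidate positions tested
  expect_lt((nrow(ft) - 1) / 10000, 0.01)
  fk <- km_step_find(y, dt = 0.005)
  expect_lt((nrow(fk) - 1) / 10000, 0.01)
  # the counter-fit quality of pure noise stays near 1
  if (nrow(fk) > 1) expect_lt(attr(fk, "quality"), 1.05)
})

test_that("a single high-SNR step is found at the right index", {
  set.seed(3)
  y <- c(rnorm(400, 0, 1), rnorm(400, 10, 1))
  fk <- km_step_find(y, dt = 0.005)
  bounds <- fk$end[-nrow(fk)]
  expect_true(any(abs(bounds - 400) <= 3))
  # the dominant level change sits at the true step
  jmp <- which.max(abs(diff(fk$level)))
  expect_lte(abs(fk$end[jmp] - 400), 3)
  expect_gt(attr(fk, "quality"), 1.5)
})

test_that("resolvable synthetic steps are recovered by both detectors", {
  # benchmark in the resolvable regime: 5-bp (3.9 nm) steps, 14 nm noise at
  # 200 Hz, dwells of at least 2 s (boundary evidence >= ~5 sigma)
  set.seed(8)
  n_steps <- 12
  true_sizes <- rep(3.92, n_steps)
  recovered <- c(0, 0); total <- c(0, 0); found <- c(0, 0)
  for (r in 1:6) {
    dwells <- 2 + rexp(n_steps + 1, 1 / 2)
    lev <- c(0, cumsum(true_sizes))
    y <- unlist(lapply(seq_along(lev), function(i) {
      rep(lev[i], round(dwells[i] * 200))
    })) + rnorm(sum(round(dwells * 200)), sd = 14)
    jumps <- cumsum(round(dwells * 200))[seq_len(n_steps)]
    fits <- list(tstep_find(y, dt = 0.005, decimate = 10, window_samples = 40,
                            min_seg = 6),
                 km_step_find(y, dt = 0.005, decimate = 10, min_seg = 6))
    for (d in 1:2) {
      f <- fits[[d]]
      det <- f$end[-nrow(f)]
      # matched within the changepoint localization scale (sigma^2/delta^2
      # ~ 26 samples, exponential tails) rather than to the sample
      hit <- vapply(jumps, function(j) any(abs(det - j) <= 150), logical(1))
      recovered[d] <- recovered[d] + sum(hit)
      total[d] <- total[d] + n_steps
      found[d] <- found[d] + length(det)
    }
  }
  expect_gt(recovered[1] / total[1], 0.85)
  expect_gt(recovered[2] / total[2], 0.85)
  # cross-detector consistency of boundary counts within 15%
  expect_lt(abs(found[1] - found[2]) / max(found), 0.15)
})

test_that("bp conversion round-trips and maps the full-open level to 174 bp", {
  cfg <- calibrated_config()
  traj <- simulate_trajectory(hp174, cfg, prof174, seed = 41)
  tr <- render_measurement(traj, quiet_meas(), seed = 1)
  fit <- tstep_find(tr)
  fb <- to_bp(fit)
  expect_equal(max(fb$level), 174, tolerance = 1e-6)
  expect_equal(min(fb$level), 0, tolerance = 1e-6)
  # converting twice is a no-op
  expect_identical(to_bp(fb), fb)
  trb <- to_bp(tr)
  expect_equal(max(trb$position_bp), 174, tolerance = 1e-6)
})

test_that("dwell histograms conserve total time and localize planted pauses", {
  cfg <- calibrated_config()
  trajs <- lapply(1:10, function(s) simulate_trajectory(hp174, cfg, prof174,
                                                        seed = 300 + s))
  dh <- dwell_histogram(trajs, bin_bp = 1, L = 174)
  expect_equal(sum(dh$dwell_s),
               sum(vapply(trajs, function(t) max(t$times), numeric(1))),
               tolerance = 1e-9)
  # planted 5-s pause at 90 bp dominates the histogram
  planted <- lapply(trajs, function(t) {
    i <- which(t$ledger$bp_from <= 91 & t$ledger$bp_to >= 91)[1]
    t$ledger$pause_s[i] <- 5
    t
  })
  dh2 <- dwell_histogram(planted, bin_bp = 1, L = 174)
  expect_lte(abs(dh2$position_bp[which.max(dh2$dwell_s)] - 90), 1)
})

test_that("pause extraction is monotone in the threshold and respects motion bounds", {
  cfg <- calibrated_config()
  traj <- simulate_trajectory(hp174, cfg, prof174, seed = 51)
  tr <- render_measurement(traj, quiet_meas(), seed = 1)
  fb <- to_bp(tstep_find(tr))
  thresholds <- c(0.02, 0.05, 0.14, 0.5)
  counts <- vapply(thresholds, function(th) {
    nrow(extract_pauses(fb, min_duration_s = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(nrow(extract_pauses(fb, min_duration_s = 1e6)), 0)
  tab <- extract_pauses(fb, min_duration_s = 0.05)
  expect_true(all(tab$duration_s >= 0.05))
  expect_true(all(tab$position_bp >= -1 & tab$position_bp <= 175))
})

test_that("step sizes from noiseless traces form a delta at the true size", {
  # slow motor, deterministic pauses: every dwell outlasts the minimum segment
  cfg <- calibrated_config(target_mean_rate = 10,
                           pause_draw = "deterministic")
  fits <- lapply(1:4, function(s) {
    traj <- simulate_trajectory(hp174, cfg, prof174, seed = 800 + s)
    tstep_find(render_measurement(traj, quiet_meas(), seed = 1))
  })
  sd0 <- step_size_distribution(fits, quiet_meas())
  expect_lt(abs(sd0$center - 5), 0.3)
  expect_true(all(abs(sd0$sizes - 5) < 0.5 | abs(sd0$sizes - 4) < 0.5))
})
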