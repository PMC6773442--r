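# WLC conversion, pause-time models, calibration, stochastic trajectories,
# measurement rendering, analog competition pauses.

test_that("WLC interpolation gives ~0.8 nm per unwound bp at assay force", {
  x <- wlc_extension_per_nt(8, 1, 0.65)
  expect_equal(round(2 * x, 1), 0.8)
  # contour-length asymptote from below
  expect_lt(wlc_extension_per_nt(500, 1, 0.65), 0.65)
  expect_gt(wlc_extension_per_nt(500, 1, 0.65), 0.6)
  # monotone in force
  expect_lt(wlc_extension_per_nt(4, 1, 0.65), x)
  expect_error(wlc_extension_per_nt(-1), "positive")
})

test_that("pause-time models coincide at n = 1 and obey closed forms", {
  p <- flat_profile(2.0, 20)
  c_sim <- sim_config("simultaneous", n = 1, A = 0.3)
  c_del <- sim_config("delayed", n = 1, A = 0.3)
  expect_equal(pause_time_mean(1:20, c_sim, p), pause_time_mean(1:20, c_del, p))
  # uniform G = 2 kBT, n = 5, A = 1: exp(10) vs 5 exp(2)
  c_sim5 <- sim_config("simultaneous", n = 5, A = 1)
  c_del5 <- sim_config("delayed", n = 5, A = 1)
  expect_equal(pause_time_mean(1, c_sim5, p), exp(10), tolerance = 1e-10)
  expect_equal(pause_time_mean(1, c_del5, p), 5 * exp(2), tolerance = 1e-10)
  # delayed additivity over the step's base pairs
  c_del1 <- sim_config("delayed", n = 1, A = 1)
  expect_equal(pause_time_mean(2, c_del5, prof174),
               sum(pause_time_mean(6:10, c_del1, prof174)), tolerance = 1e-10)
  expect_error(pause_time_mean(99, c_del5, p), "beyond")
})

test_that("prefactor calibration hits the target rate and is invariant to energy shifts", {
  cfg <- calibrated_config()
  expect_lt(abs(expected_mean_rate(cfg, prof174) - 46) / 46, 0.005)
  shifted <- prof174
  shifted$g1bp <- shifted$g1bp + 0.7
  cfg2 <- sim_config()
  cfg2$A <- calibrate_prefactor(hp174, cfg2, shifted)
  expect_lt(abs(expected_mean_rate(cfg2, shifted) - 46) / 46, 0.005)
  # a target above the translocation bound is rejected
  fast <- sim_config(target_mean_rate = 150)
  expect_error(calibrate_prefactor(hp174, fast, prof174), "translocation")
})

test_that("trajectories unwind the full stem with a conserved time ledger", {
  cfg <- calibrated_config()
  traj <- simulate_trajectory(hp174, cfg, prof174, seed = 21)
  expect_equal(max(traj$positions), 174)
  expect_true(all(diff(traj$positions) > 0))
  expect_true(all(diff(traj$times) > 0))
  expect_equal(sum(traj$ledger$pause_s + traj$ledger$trans_s), max(traj$times),
               tolerance = 1e-10)
  expect_equal(sum(traj$ledger$bp_to - traj$ledger$bp_from + 1), 174)
  # deterministic pauses: total time equals the closed-form sum exactly
  cfg_det <- calibrated_config(pause_draw = "deterministic")
  td <- simulate_trajectory(hp174, cfg_det, prof174, seed = 1)
  expect_equal(max(td$times),
               sum(pause_time_mean(seq_len(nrow(td$ledger)), cfg_det, prof174)) +
                 174 / cfg_det$v_trans, tolerance = 1e-10)
})

test_that("Monte-Carlo mean duration matches the analytic expectation", {
  hp <- make_hairpin(30, background_gc = 0.5, seed = 6)
  prof <- compute_bp_energies(hp, cond_assay)
  cfg <- calibrated_config(substrate = hp, profile = prof)
  tot <- vapply(1:400, function(s) {
    max(simulate_trajectory(hp, cfg, prof, seed = s)$times)
  }, numeric(1))
  expected <- 30 / 46
  sem <- stats::sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * sem)
})

test_that("rendering reproduces the staircase geometry and the noise floor", {
  cfg <- calibrated_config()
  traj <- simulate_trajectory(hp174, cfg, prof174, seed = 31)
  tr0 <- render_measurement(traj, quiet_meas(), seed = 1)
  risers <- diff(unique(tr0$extension_nm))
  npb <- 2 * wlc_extension_per_nt()
  expect_true(all(abs(risers - 5 * npb) < 1e-9 | abs(risers - 4 * npb) < 1e-9))
  # noise sd of a long static stretch within 5%
  mc <- meas_config()
  tr <- render_measurement(traj, mc, seed = 2, pad_s = 10)
  base <- tr$extension_nm[tr$time_s < 10]
  expect_lt(abs(stats::sd(base) - 14) / 14, 0.05)
  expect_equal(unique(round(diff(tr$time_s), 10)), 1 / 200)
})

test_that("analog competition pauses extend dwells by the binomial mean", {
  cfg <- calibrated_config()
  # zero analog: identical to the plain simulation under the same seed
  t_plain <- simulate_trajectory(hp174, cfg, prof174, seed = 77)
  t_zero <- simulate_atpgs_trajectory(hp174, cfg, prof174, atp_mM = 1,
                                      atpgs_mM = 0, seed = 77)
  expect_equal(t_plain$times, t_zero$times)
  # mean added pause per full step ~ m P / k_off
  P <- binding_prob(0.5, 0.5, 1.2)
  added <- unlist(lapply(1:60, function(s) {
    ta <- simulate_atpgs_trajectory(hp174, cfg, prof174, 0.5, 0.5,
                                    k_ratio = 1.2, k_off_per_s = 2.5, C = 1,
                                    seed = 4000 + s)
    tp <- simulate_trajectory(hp174, cfg, prof174, seed = 4000 + s)
    full <- ta$ledger$bp_to - ta$ledger$bp_from + 1 == 5
    ta$ledger$pause_s[full] - tp$ledger$pause_s[full]
  }))
  sem <- stats::sd(added) / sqrt(length(added))
  expect_lt(abs(mean(added) - 5 * P / 2.5), 3 * sem)
  # unwinding slows monotonically with the analog fraction
  rate_at <- vapply(c(0.05, 0.2, 0.5), function(f) {
    tot <- vapply(1:25, function(s) {
      max(simulate_atpgs_trajectory(hp174, cfg, prof174, 1 - f, f,
                                    seed = 600 + s)$times)
    }, numeric(1))
    174 / mean(tot)
  }, numeric(1))
  expect_true(all(diff(rate_at) < 0))
})

test_that("the simultaneous model concentrates pausing more than delayed release", {
  for (seed in 1:5) {
    hp <- make_hairpin(60, gc_clusters = list(list(center = 30, width = 10,
                                                   gc = 0.9)),
                       background_gc = 0.3, seed = seed)
    prof <- compute_bp_energies(hp, cond_assay)
    stopifnot(max(prof$g1bp) - min(prof$g1bp) >= 1)
    ratio <- vapply(c("simultaneous", "delayed"), function(m) {
      cfg <- sim_config(m, n = 5, A = 1)
      tau <- pause_time_mean(1:12, cfg, prof)
      max(tau) / stats::median(tau)
    }, numeric(1))
    expect_gt(ratio[["simultaneous"]], ratio[["delayed"]])
  }
})
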