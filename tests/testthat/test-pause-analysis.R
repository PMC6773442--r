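# Pause-stability regression, binned durations, model selection, salt
# predictions, power-law amplification, lifetime mixtures, competition model.

test_that("regression on identical peak lists is exact", {
  r <- pause_energy_regression(c(30, 60, 90, 120), c(30, 60, 90, 120))
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_lt(r$chisq, 1e-10)
  expect_error(pause_energy_regression(c(1, 50), c(1, 50)), "3")
})

test_that("regression slope is unbiased under peak-position jitter", {
  set.seed(5)
  energy <- c(25, 55, 90, 120, 150)
  slopes <- vapply(1:40, function(r) {
    pause_energy_regression(energy + rnorm(5, sd = 2), energy)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.05)
})

test_that("mutual-nearest pairing reports unpaired peaks instead of dropping them", {
  r <- pause_energy_regression(c(30, 60, 90, 140), c(31, 59, 91, 120))
  expect_equal(nrow(r$pairs), 3)
  expect_true(120 %in% r$unpaired$energy)
  expect_true(140 %in% r$unpaired$pause)
})

test_that("binned pause durations agree with a brute-force oracle", {
  set.seed(6)
  tab <- data.frame(position_bp = runif(200, 0, 174),
                    duration_s = rexp(200, 2), trace_id = 1)
  b <- binned_pause_durations(tab, bin_bp = 5, L = 174)
  for (i in sample(nrow(b), 8)) {
    lo <- b$position_bp[i] - 2.5; hi <- b$position_bp[i] + 2.5
    sel <- tab$duration_s[tab$position_bp > lo & tab$position_bp <= hi]
    if (length(sel)) expect_equal(b$mean_s[i], mean(sel), tolerance = 1e-9)
  }
  expect_equal(sum(b$n), 200)
  # a planted long pause dominates its bin
  tab$duration_s[which.min(abs(tab$position_bp - 92))] <- 50
  b2 <- binned_pause_durations(tab, bin_bp = 5, L = 174)
  expect_equal(b2$position_bp[which.max(b2$mean_s)],
               b2$position_bp[findInterval(tab$position_bp[
                 which.max(tab$duration_s)], seq(0, 175, 5))])
})

test_that("the chi-square scan recovers the generating model and step size", {
  cfg <- calibrated_config("delayed", 5)
  tabs <- lapply(1:80, function(s) {
    extract_pauses(simulate_trajectory(hp174, cfg, prof174, seed = 5000 + s),
                   min_duration_s = 0, trace_id = s)
  })
  ref <- binned_pause_durations(tabs, bin_bp = 5, L = 174)
  ms <- model_selection_chi2(ref, hp174, prof174, n_traces = 50, seed = 77)
  best <- attr(ms, "best")
  expect_equal(best$model, "delayed")
  expect_equal(best$n, 5)
  # chi2_nu at the generating cell is near 1 under matched noise
  truth_cell <- ms[ms$model == "delayed" & ms$n == 5, ]
  expect_lt(truth_cell$chisq_nu, 2.5)
  # symmetric self-consistency for the other model
  cfg2 <- calibrated_config("simultaneous", 2)
  tabs2 <- lapply(1:80, function(s) {
    extract_pauses(simulate_trajectory(hp174, cfg2, prof174, seed = 9000 + s),
                   min_duration_s = 0, trace_id = s)
  })
  ref2 <- binned_pause_durations(tabs2, bin_bp = 5, L = 174)
  ms2 <- model_selection_chi2(ref2, hp174, prof174, n_traces = 50, seed = 78)
  expect_equal(attr(ms2, "best")$model, "simultaneous")
  expect_equal(attr(ms2, "best")$n, 2)
})

test_that("salt predictions anchor at the calibration point and order the models", {
  cfg5 <- calibrated_config("delayed", 5)
  cfg2 <- calibrated_config("simultaneous", 2)
  na <- c(25, 50, 150, 300, 500)
  del <- salt_rate_prediction(hp174, "delayed", 5, cfg5$A, na)
  sim <- salt_rate_prediction(hp174, "simultaneous", 2, cfg2$A, na)
  # anchored at the reference (50 mM) to the calibration target
  expect_equal(del$rate_bp_s[2], 46, tolerance = 1e-6)
  expect_equal(sim$rate_bp_s[2], 46, tolerance = 1e-6)
  expect_true(all(diff(del$rate_bp_s) < 0))
  expect_true(all(diff(sim$rate_bp_s) < 0))
  # the simultaneous model is the more salt-sensitive
  drop_del <- 1 - del$rate_bp_s[5] / del$rate_bp_s[1]
  drop_sim <- 1 - sim$rate_bp_s[5] / sim$rate_bp_s[1]
  expect_gt(drop_sim, drop_del)
})

test_that("salt ordering holds across substrate GC compositions", {
  for (gc in c(0.2, 0.5, 0.8)) {
    hp <- make_hairpin(80, background_gc = gc, seed = round(100 * gc))
    prof <- compute_bp_energies(hp, cond_assay)
    c5 <- calibrated_config("delayed", 5, hp, prof)
    c2 <- calibrated_config("simultaneous", 2, hp, prof)
    del <- salt_rate_prediction(hp, "delayed", 5, c5$A, c(25, 500))
    sim <- salt_rate_prediction(hp, "simultaneous", 2, c2$A, c(25, 500))
    expect_gt(1 - sim$rate_bp_s[2] / sim$rate_bp_s[1],
              1 - del$rate_bp_s[2] / del$rate_bp_s[1])
  }
})

test_that("power-law fits recover planted exponents and flag linear data", {
  # construct dwell values that follow A x^P exactly in the fit's own
  # coordinates (x = exp of the bp energy, 1-bp window)
  x <- exp(prof174$g1bp)
  dwell <- data.frame(position_bp = 0:174, dwell_s = 0)
  set.seed(7)
  dwell$dwell_s[match(seq_len(174), round(dwell$position_bp))] <-
    1e-3 * x^10 * (1 + rnorm(length(x), sd = 0.05))
  class(dwell) <- c("dwell_histogram", "data.frame")
  fit <- dwell_power_law(dwell, prof174, window_bp = 1)
  expect_lt(abs(fit$power - 10), 2 * max(fit$power_se, 0.5))
  # linear data has exponent ~1
  dwell$dwell_s[match(seq_len(174), round(dwell$position_bp))] <- 0.02 * x
  fit1 <- dwell_power_law(dwell, prof174, window_bp = 1)
  expect_lt(abs(fit1$power - 1), 0.05)
})

test_that("delayed-release dwell shows no strong amplification", {
  cfg <- calibrated_config()
  trajs <- lapply(1:60, function(s) simulate_trajectory(hp174, cfg, prof174,
                                                        seed = 1200 + s))
  dh <- dwell_histogram(trajs, bin_bp = 1, L = 174)
  fit <- dwell_power_law(dh, prof174)
  expect_lt(fit$power, 2.5)
  expect_gt(fit$power, 0.1)
})

test_that("exponential mixture fitting selects the right component count", {
  set.seed(10)
  f1 <- pause_lifetime_fit(rexp(500, 1 / 0.4))
  expect_equal(f1$n_components, 1)
  expect_lt(abs(f1$lifetimes - 0.4) / 0.4, 0.1)
  d2 <- c(rexp(400, 1 / 1.8), rexp(400, 1 / 0.4))
  f2 <- pause_lifetime_fit(d2)
  expect_equal(f2$n_components, 2)
  expect_lt(abs(f2$lifetimes[1] - 1.8), 2 * f2$lifetime_se[1] + 0.2)
  expect_lt(abs(f2$lifetimes[2] - 0.4), 2 * f2$lifetime_se[2] + 0.1)
  expect_equal(sum(f2$amplitudes), 1, tolerance = 1e-9)
  # permutation invariance
  f2b <- pause_lifetime_fit(sample(d2))
  expect_equal(f2$lifetimes, f2b$lifetimes, tolerance = 1e-6)
})

test_that("constant-affinity competition cannot produce strong amplification", {
  base <- hrdc_competition_baseline(prof174, n = 5, A = 8e-4, k_bind = 0,
                                    k_release = 0.5)
  cfg <- sim_config("delayed", 5, A = 8e-4)
  expect_equal(base$mean_dwell_s,
               pause_time_mean(seq_len(nrow(base)), cfg, prof174),
               tolerance = 1e-12)
  withb <- hrdc_competition_baseline(prof174, n = 5, A = 8e-4, k_bind = 5,
                                     k_release = 0.5)
  # capture probability is monotone in the core pause time
  ord <- order(withb$tau_core_s)
  expect_true(all(diff(withb$p_capture[ord]) >= -1e-12))
  # over a 1-3 kBT energy sweep the dwell-stability exponent stays modest
  g_sweep <- seq(1, 3, length.out = 40)
  tau <- 5 * 8e-4 * exp(g_sweep)
  p <- 5 / (5 + 1 / tau)
  dwell <- tau + p / 0.5
  pw <- stats::coef(stats::lm(log(dwell) ~ g_sweep))[2]  # power vs exp(G)
  expect_lt(pw, 2)
})
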