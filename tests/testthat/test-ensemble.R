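# Single-turnover ensemble kinetics: closed forms, branching limits,
# stochastic oracle agreement, quenched-flow synthesis, global fitting.

test_that("the n = 1 chain reduces to the single-exponential closed form", {
  sp <- ensemble_spec("uniform", n = 1, k = 2, f_P = 0.7, k_rebind = 0)
  tt <- c(0.1, 0.5, 1, 3, 10)
  expect_equal(nstep_transient(sp, tt), 0.7 * (1 - exp(-2 * tt)),
               tolerance = 1e-8)
})

test_that("long-time limits follow the productive fraction and rebinding", {
  no_rb <- ensemble_spec("uniform", n = 3, k = 5, f_P = 0.55, k_rebind = 0)
  expect_equal(nstep_transient(no_rb, 1e3), 0.55, tolerance = 1e-6)
  rb <- ensemble_spec("uniform", n = 3, k = 5, f_P = 0.55, k_rebind = 0.1)
  expect_gt(nstep_transient(rb, 500), 0.99)
  # probability is conserved and the transient is non-decreasing
  fr <- nstep_transient(rb, seq(0, 50, by = 1))
  expect_true(all(diff(fr) >= -1e-10))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("productive-path mean completion time is Erlang n/k", {
  sp <- ensemble_spec("uniform", n = 5, k = 10, f_P = 1, k_rebind = 0)
  tt <- seq(0, 5, by = 0.002)
  fr <- nstep_transient(sp, tt)
  # mean completion time = integral of (1 - F)
  mean_t <- sum(1 - fr) * 0.002
  expect_equal(mean_t, 5 / 10, tolerance = 0.01)
})

test_that("a uniform-energy duplex collapses the sequence model onto the uniform chain", {
  fk <- fork_substrate(strrep("ATA", 11))
  cond <- cond_assay
  prof <- compute_bp_energies(fk, cond)
  # force a truly flat profile via a poly-AT-like duplex: use closed-form rate
  spd <- ensemble_spec("delayed", n = 33, A = 1e-3, f_P = 0.8, k_rebind = 0)
  k_eff <- 1 / sum(1e-3 * exp(prof$g1bp))
  spu <- ensemble_spec("uniform", n = 1, k = k_eff, f_P = 0.8, k_rebind = 0)
  tt <- c(0.5, 1, 2, 5, 10)
  expect_equal(seqdep_transient(spd, fk, cond, tt), nstep_transient(spu, tt),
               tolerance = 1e-8)
})

test_that("higher GC content slows the transient at fixed pre-factor", {
  gc79 <- make_fork(26, seed = 3)
  gc36 <- make_fork(12, seed = 5)
  sp <- ensemble_spec("delayed", n = 5, A = 4e-4, f_P = 0.6, k_rebind = 0.03)
  tt <- c(0.2, 0.5, 1, 2, 5, 20, 60)
  f79 <- seqdep_transient(sp, gc79, cond_assay, tt)
  f36 <- seqdep_transient(sp, gc36, cond_assay, tt)
  expect_true(all(f79 < f36))
})

test_that("matrix-exponential transients match the stochastic oracle", {
  fk <- make_fork(16, seed = 6)
  sp <- ensemble_spec("delayed", n = 5, A = 4e-4, f_P = 0.6, k_rebind = 0.05)
  tt <- c(0.1, 0.3, 1, 3, 10, 30, 100)
  det <- seqdep_transient(sp, fk, cond_assay, tt)
  sto <- ensemble_stochastic(sp, tt, n_mol = 20000, seed = 4, fork = fk)
  mc_err <- sqrt(pmax(det * (1 - det), 1e-4) / 20000)
  expect_true(all(abs(det - sto) < 4 * mc_err + 0.005))
})

test_that("lag time before 10% completion grows with n at fixed mean time", {
  t10 <- vapply(c(1, 3, 5, 7), function(n) {
    sp <- ensemble_spec("uniform", n = n, k = n / 0.5, f_P = 1, k_rebind = 0)
    tt <- seq(0, 2, by = 0.001)
    tt[which(nstep_transient(sp, tt) >= 0.1)[1]]
  }, numeric(1))
  expect_true(all(diff(t10) > 0))
})

test_that("quenched-flow synthesis is exact at zero noise and seeded", {
  fk <- make_fork(12, seed = 5)
  sp <- ensemble_spec("delayed", n = 5, A = 4e-4, f_P = 0.6, k_rebind = 0.03)
  tp <- c(0.1, 0.5, 2, 10, 60, 150)
  q0 <- simulate_quenchflow(fk, sp, tp, noise_sd = 0, n_replicates = 2,
                            seed = 1)
  expect_equal(q0$fraction[q0$rep == 1],
               seqdep_transient(sp, fk, cond_assay, tp), tolerance = 1e-10)
  q1 <- simulate_quenchflow(fk, sp, tp, noise_sd = 0.05, n_replicates = 40,
                            seed = 2)
  expect_equal(q1, simulate_quenchflow(fk, sp, tp, noise_sd = 0.05,
                                       n_replicates = 40, seed = 2))
  # replicate SEM ~ noise/sqrt(reps) away from the clipping boundaries
  mid <- q1[q1$time_s == 2, ]
  expect_lt(abs(stats::sd(mid$fraction) - 0.05) / 0.05, 0.5)
  expect_true(all(q1$fraction >= 0 & q1$fraction <= 1))
})

test_that("global fitting recovers the generating step size across GC contents", {
  forks <- list(gc36 = make_fork(12, seed = 5), gc48 = make_fork(16, seed = 6),
                gc79 = make_fork(26, seed = 3))
  A5 <- calibrate_prefactor(forks$gc79, sim_config("delayed", 5),
                            compute_bp_energies(forks$gc79, cond_assay))
  truth <- ensemble_spec("delayed", n = 5, A = A5, f_P = 0.6, k_rebind = 0.03)
  tp <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 40, 80, 150)
  qd <- simulate_quenchflow(forks, truth, tp, noise_sd = 0.02,
                            n_replicates = 3, seed = 7)
  gf <- global_fit(qd, variant = "delayed", n_range = 1:7, substrates = forks)
  expect_equal(gf$best_n, 5)
  expect_lt(abs(gf$best$A - A5) / A5, 0.25)
  expect_lt(abs(gf$best$f_P - 0.6), 0.1)
  # uniform-variant self-consistency; dense early sampling resolves the lag
  truth_u <- ensemble_spec("uniform", n = 5, k = 8, f_P = 0.6, k_rebind = 0.03)
  tp_dense <- c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.7, 1, 1.5, 2, 3, 5, 10, 20,
                40, 80, 150)
  qu <- simulate_quenchflow(forks, truth_u, tp_dense, noise_sd = 0.02,
                            n_replicates = 3, seed = 1)
  gu <- global_fit(qu, variant = "uniform", n_range = 1:7)
  expect_equal(gu$best_n, 5)
})

test_that("a single-substrate fit without early lag coverage is degenerate in n", {
  fk <- make_fork(16, seed = 6)
  truth <- ensemble_spec("uniform", n = 5, k = 8, f_P = 0.6, k_rebind = 0.03)
  # sampling that misses the initial lag: k and n trade off freely
  tp <- c(2, 5, 10, 20, 40, 80, 150)
  q <- simulate_quenchflow(fk, truth, tp, noise_sd = 0.02, n_replicates = 3,
                           seed = 9)
  g <- global_fit(q, variant = "uniform", n_range = 2:7)
  spread <- diff(range(g$table$chisq_nu)) / min(g$table$chisq_nu)
  expect_lt(spread, 0.01)
})
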