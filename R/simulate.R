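# Stochastic unwinding simulator and measurement model.
#
# Two microscopic stepping models over an n-bp kinetic step:
#   simultaneous: tau_p(i) = A * exp( sum of the n bp opening costs )
#                 (all n bps open in one activated event)
#   delayed:      tau_p(i) = sum over the n bps of A * exp(G_1bp)
#                 (bps open one at a time; ssDNA released after n bp)
# Step i covers bps n(i-1)+1 .. min(n*i, L); the final partial step uses the
# remaining bps. Pauses are exponentially distributed with the model value as
# the mean (a deterministic mode exists for exact tests); translocation is a
# deterministic delay of (bp in step)/v_trans followed by an instantaneous
# jump. kBT is fixed at 25 C (4.11 pN nm).

.KBT_PN_NM <- 4.11

#' Simulation configuration
#'
#' @param model `"delayed"` (sequential melting, delayed ssDNA release) or
#'   `"simultaneous"` (cooperative n-bp melting).
#' @param n kinetic step size in bp (>= 1).
#' @param A Boltzmann pre-factor in seconds, or `NULL` to calibrate against
#'   `target_mean_rate`.
#' @param v_trans post-melt translocation rate in bp/s.
#' @param target_mean_rate calibration target for the ensemble mean unwinding
#'   rate, bp/s (the helicase core construct unwinds at 46 nt/s).
#' @param pause_draw `"exponential"` or `"deterministic"`.
#' @return a `sim_config` object.
#' @export
sim_config <- function(model = c("delayed", "simultaneous"), n = 5L, A = NULL,
                       v_trans = 100, target_mean_rate = 46,
                       pause_draw = c("exponential", "deterministic")) {
  model <- match.arg(model)
  pause_draw <- match.arg(pause_draw)
  n <- as.integer(n)
  if (n < 1) stop("kinetic step size n must be >= 1")
  if (!is.null(A) && A <= 0) stop("prefactor A must be positive")
  if (v_trans <= 0) stop("v_trans must be positive")
  if (target_mean_rate <= 0) stop("target_mean_rate must be positive")
  structure(list(model = model, n = n, A = A, v_trans = v_trans,
                 target_mean_rate = target_mean_rate, pause_draw = pause_draw),
            class = "sim_config")
}

#' Measurement configuration
#'
#' Defaults reproduce the stated magnetic-tweezers conditions: 8 pN applied
#' force, 1 nm ssDNA persistence length, 0.65 nm inter-phosphate distance,
#' 200 Hz sampling, 14 nm baseline noise per sample.
#'
#' @param force_pN applied force.
#' @param persistence_nm ssDNA persistence length.
#' @param interphosphate_nm ssDNA contour length per nucleotide.
#' @param sampling_hz sampling rate.
#' @param noise_sigma_nm Gaussian noise SD per sample.
#' @return a `meas_config` object.
#' @export
meas_config <- function(force_pN = 8, persistence_nm = 1.0,
                        interphosphate_nm = 0.65, sampling_hz = 200,
                        noise_sigma_nm = 14) {
  vals <- c(force_pN, persistence_nm, interphosphate_nm, sampling_hz)
  if (any(vals <= 0) || noise_sigma_nm < 0) stop("invalid measurement config")
  structure(list(force_pN = force_pN, persistence_nm = persistence_nm,
                 interphosphate_nm = interphosphate_nm,
                 sampling_hz = sampling_hz, noise_sigma_nm = noise_sigma_nm),
            class = "meas_config")
}

#' Worm-like-chain extension per ssDNA nucleotide
#'
#' Solves the WLC interpolation relation F Lp / kBT = x + 1/(4(1-x)^2) - 1/4
#' for the fractional extension x and returns x times the inter-phosphate
#' distance. At 8 pN with Lp = 1 nm and 0.65 nm/nt this is ~0.39 nm/nt, i.e.
#' ~0.8 nm per unwound base pair (two released nucleotides).
#'
#' @param force_pN applied force (> 0).
#' @param persistence_nm persistence length.
#' @param interphosphate_nm contour length per nucleotide.
#' @return extension per nucleotide in nm.
#' @export
wlc_extension_per_nt <- function(force_pN = 8, persistence_nm = 1.0,
                                 interphosphate_nm = 0.65) {
  if (force_pN <= 0) stop("force must be positive")
  rhs <- force_pN * persistence_nm / .KBT_PN_NM
  f <- function(x) x + 1 / (4 * (1 - x)^2) - 0.25 - rhs
  if (f(1e-12) > 0 || f(1 - 1e-9) < 0) stop("no WLC root in (0, 1)")
  x <- stats::uniroot(f, c(1e-12, 1 - 1e-9), tol = 1e-12)$root
  x * interphosphate_nm
}

#' Extension rise per unwound base pair
#'
#' Each opened bp releases two nucleotides into the tether.
#' @param mc a [meas_config()].
#' @return nm per bp.
#' @export
nm_per_bp <- function(mc = meas_config()) {
  2 * wlc_extension_per_nt(mc$force_pN, mc$persistence_nm, mc$interphosphate_nm)
}

# bp covered by each kinetic step for a stem of length L
step_plan <- function(L, n) {
  starts <- seq(1, L, by = n)
  data.frame(step = seq_along(starts), from = starts,
             to = pmin(starts + n - 1, L))
}

#' Mean pause time of one kinetic step
#'
#' @param i kinetic step index (step i covers bps n(i-1)+1..min(n i, L)).
#' @param config a [sim_config()] (its `A` must be set).
#' @param profile a [compute_bp_energies()] result.
#' @return mean pause duration in seconds.
#' @export
pause_time_mean <- function(i, config, profile) {
  plan <- step_plan(length(profile$g1bp), config$n)
  if (any(i < 1 | i > nrow(plan))) stop("step index beyond substrate")
  A <- config$A
  if (is.null(A)) stop("config$A is not set; calibrate or supply it")
  vapply(i, function(ii) {
    g <- profile$g1bp[plan$from[ii]:plan$to[ii]]
    switch(config$model,
           simultaneous = A * exp(sum(g)),
           delayed = sum(A * exp(g)))
  }, numeric(1))
}

# sum over steps of the exp() terms multiplying A in the total pause time
.pause_sum_factor <- function(config, profile) {
  plan <- step_plan(length(profile$g1bp), config$n)
  sum(vapply(seq_len(nrow(plan)), function(ii) {
    g <- profile$g1bp[plan$from[ii]:plan$to[ii]]
    switch(config$model, simultaneous = exp(sum(g)), delayed = sum(exp(g)))
  }, numeric(1)))
}

#' Calibrate the Boltzmann pre-factor to a target mean unwinding rate
#'
#' Both stepping models are linear in A, so the A that makes the expected
#' mean rate L / (sum tau_p + sum tau_t) equal `target_mean_rate` is closed
#' form: A = (L/target - L/v_trans) / S with S the model's summed exp-energy
#' factor.
#'
#' @param substrate substrate whose length sets L.
#' @param config a [sim_config()].
#' @param profile matching energy profile.
#' @return the calibrated pre-factor A (seconds).
#' @export
calibrate_prefactor <- function(substrate, config, profile) {
  L <- length(profile$g1bp)
  t_pause <- L / config$target_mean_rate - L / config$v_trans
  if (t_pause <= 0) {
    stop("target rate exceeds the translocation-limited bound (v_trans)")
  }
  t_pause / .pause_sum_factor(config, profile)
}

#' Expected mean unwinding rate under a configuration
#'
#' Closed-form L / (sum tau_p + sum tau_t); the time-weighted (pooled)
#' ensemble rate that calibration targets.
#' @inheritParams calibrate_prefactor
#' @return bp/s.
#' @export
expected_mean_rate <- function(config, profile) {
  L <- length(profile$g1bp)
  L / (config$A * .pause_sum_factor(config, profile) + L / config$v_trans)
}

#' Simulate one unwinding trajectory
#'
#' Per kinetic step: draw the pause duration (exponential with the model mean,
#' or deterministic), then advance the step's bps after a translocation delay
#' of bp/v_trans. Terminates when the full stem is unwound.
#'
#' @param substrate a [hairpin_substrate()].
#' @param config a [sim_config()] with `A` set (see [calibrate_prefactor()]).
#' @param profile matching energy profile.
#' @param seed integer seed.
#' @return a `trajectory`: list with `times`/`positions` (piecewise-constant
#'   record: position jumps at `times`), `L`, and `ledger` (per step: start
#'   time, pause_s, trans_s, bp_from, bp_to, n_analog pauses if any).
#' @export
simulate_trajectory <- function(substrate, config, profile, seed = 1L) {
  .simulate_impl(substrate, config, profile, seed, atpgs = NULL)
}

#' Simulate unwinding with ATP-gamma-S competition pauses
#'
#' Each kinetic step requires m = round(C * bp) nucleotide-binding events.
#' Each event binds the slowly-exchanging analog with probability
#' P = [ATPgS] / (k_ratio [ATP] + [ATPgS]) ([binding_prob()]); each bound
#' analog appends an exponential dwell of mean 1/k_off to the step's pause.
#' No backsliding. With `atpgs_mM = 0` the result is identical to
#' [simulate_trajectory()] for the same seed.
#'
#' @inheritParams simulate_trajectory
#' @param atp_mM,atpgs_mM nucleotide concentrations.
#' @param k_ratio on-rate ratio k_ATP / k_ATPgS.
#' @param k_off_per_s analog release rate (1/s); the printed release time is
#'   0.4 s, i.e. k_off = 2.5/s.
#' @param C mechano-chemical coupling in bp per ATP (C = m/n).
#' @return a `trajectory` whose ledger carries `n_analog` per step.
#' @export
simulate_atpgs_trajectory <- function(substrate, config, profile, atp_mM,
                                      atpgs_mM, k_ratio = 1.2,
                                      k_off_per_s = 2.5, C = 1, seed = 1L) {
  if (C <= 0) stop("invalid coupling C")
  if (atp_mM < 0 || atpgs_mM < 0) stop("concentrations must be >= 0")
  atpgs <- list(P = binding_prob(atp_mM, atpgs_mM, k_ratio),
                k_off = k_off_per_s, C = C)
  .simulate_impl(substrate, config, profile, seed, atpgs = atpgs)
}

.simulate_impl <- function(substrate, config, profile, seed, atpgs) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$A)) stop("config$A is not set; calibrate or supply it")
  L <- length(profile$g1bp)
  plan <- step_plan(L, config$n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_steps <- nrow(plan)
  pause_mean <- pause_time_mean(seq_len(n_steps), config, profile)
  pause <- if (config$pause_draw == "exponential") {
    stats::rexp(n_steps, rate = 1 / pause_mean)
  } else pause_mean
  n_analog <- rep(0L, n_steps)
  if (!is.null(atpgs) && atpgs$P > 0) {
    m <- pmax(1L, as.integer(round(atpgs$C * (plan$to - plan$from + 1))))
    n_analog <- stats::rbinom(n_steps, m, atpgs$P)
    extra <- vapply(n_analog, function(k) {
      if (k == 0) 0 else sum(stats::rexp(k, rate = atpgs$k_off))
    }, numeric(1))
    pause <- pause + extra
  }
  trans <- (plan$to - plan$from + 1) / config$v_trans
  t_end <- cumsum(pause + trans)
  start <- c(0, t_end[-n_steps])
  ledger <- data.frame(step = plan$step, start = start, pause_s = pause,
                       trans_s = trans, bp_from = plan$from, bp_to = plan$to,
                       n_analog = n_analog)
  structure(list(times = c(0, t_end), positions = c(0, plan$to), L = L,
                 substrate = substrate, config = config, seed = seed,
                 ledger = ledger),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d bp in %.2f s (%d kinetic steps, %s, n=%d)>\n",
              x$L, max(x$times), nrow(x$ledger), x$config$model, x$config$n))
  invisible(x)
}

#' Position (bp unwound) of a trajectory at arbitrary times
#' @param traj a trajectory.
#' @param t numeric times (s).
#' @return bp unwound at each t.
#' @export
trajectory_position <- function(traj, t) {
  stats::stepfun(traj$times[-1], traj$positions)(t)
}

#' Render a trajectory into a noisy measured extension trace
#'
#' extension(t) = nm_per_bp * position(t) + Gaussian noise per sample, on a
#' uniform grid at the configured sampling rate. `pad_s` of quiescent baseline
#' is prepended and appended so both terminal plateaus are observable.
#'
#' @param traj a [simulate_trajectory()] result.
#' @param mc a [meas_config()].
#' @param seed integer seed for the noise.
#' @param pad_s flat padding on each end, seconds.
#' @return a `measured_trace`: data.frame `time_s`, `extension_nm` with the
#'   ground-truth trajectory and configs as attributes.
#' @export
render_measurement <- function(traj, mc = meas_config(), seed = 1L,
                               pad_s = 1) {
  dt <- 1 / mc$sampling_hz
  t <- seq(0, max(traj$times) + 2 * pad_s, by = dt)
  pos <- trajectory_position(traj, pmax(t - pad_s, 0))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ext <- nm_per_bp(mc) * pos +
    stats::rnorm(length(t), sd = mc$noise_sigma_nm)
  out <- data.frame(time_s = t, extension_nm = ext)
  attr(out, "trajectory") <- traj
  attr(out, "meas_config") <- mc
  attr(out, "pad_s") <- pad_s
  class(out) <- c("measured_trace", "data.frame")
  out
}
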