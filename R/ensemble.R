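# Single-turnover ensemble unwinding kinetics.
#
# Branching n-step scheme: of all enzyme-DNA complexes, a productive fraction
# f_P traverses n sequential irreversible kinetic steps to full unwinding; the
# non-productive fraction (1 - f_P) dissociates and rebinds at rate k_rebind,
# re-partitioning into productive/non-productive with the same f_P (an
# always-productive-on-rebind alternative is available behind a flag). In the
# uniform variant every step shares one rate k; in the sequence-dependent
# variants the per-step rates are 1/tau_p(i) from the stepping models
# evaluated over the fork duplex (the final partial step uses its own value).
# The transient is solved by matrix exponential of the linear chain.

#' Ensemble kinetic model specification
#'
#' @param variant `"uniform"`, `"simultaneous"` or `"delayed"`.
#' @param n kinetic step size in bp (integer; sets the number of sequential
#'   steps: for the uniform variant exactly `n` steps, for sequence variants
#'   `ceiling(L/n)` steps over the duplex).
#' @param k uniform per-step rate (1/s; uniform variant).
#' @param A Boltzmann pre-factor (s; sequence variants).
#' @param f_P productive fraction in [0, 1].
#' @param k_rebind rebinding rate of dissociated enzyme (1/s).
#' @param rebind_productive if `TRUE`, every rebound enzyme is productive;
#'   default re-partitions with `f_P`.
#' @return an `ensemble_spec`.
#' @export
ensemble_spec <- function(variant = c("uniform", "simultaneous", "delayed"),
                          n = 5L, k = NULL, A = NULL, f_P = 1, k_rebind = 0,
                          rebind_productive = FALSE) {
  variant <- match.arg(variant)
  if (f_P < 0 || f_P > 1) stop("f_P must be in [0, 1]")
  if (k_rebind < 0) stop("k_rebind must be >= 0")
  if (variant == "uniform" && (is.null(k) || k < 0)) {
    stop("uniform variant needs a non-negative rate k")
  }
  if (variant != "uniform" && (is.null(A) || A <= 0)) {
    stop("sequence-dependent variants need a positive pre-factor A")
  }
  structure(list(variant = variant, n = as.integer(n), k = k, A = A,
                 f_P = f_P, k_rebind = k_rebind,
                 rebind_productive = rebind_productive),
            class = "ensemble_spec")
}

# per-step rates for a spec (uniform: n equal rates; sequence: from profile)
.ensemble_rates <- function(spec, fork = NULL,
                            conditions = ionic_conditions()) {
  if (spec$variant == "uniform") return(rep(spec$k, spec$n))
  if (is.null(fork)) stop("sequence-dependent variants need a fork substrate")
  profile <- compute_bp_energies(fork, conditions)
  cfg <- sim_config(model = spec$variant, n = spec$n, A = spec$A)
  n_steps <- nrow(step_plan(length(profile$g1bp), spec$n))
  1 / pause_time_mean(seq_len(n_steps), cfg, profile)
}

# generator matrix for states (N, P1..Ps, U); returns fraction in U over time
.chain_transient <- function(rates, f_P, k_rebind, rebind_productive, times) {
  s <- length(rates)
  dim_n <- s + 2                       # N, P1..Ps, U
  Q <- matrix(0, dim_n, dim_n)
  f_in <- if (rebind_productive) 1 else f_P
  Q[1, 1] <- -k_rebind * f_in
  Q[2, 1] <- k_rebind * f_in
  for (i in seq_len(s)) {
    Q[1 + i, 1 + i] <- Q[1 + i, 1 + i] - rates[i]
    Q[2 + i, 1 + i] <- rates[i]
  }
  p0 <- c(1 - f_P, f_P, rep(0, s - 1), 0)
  vapply(times, function(t) {
    if (t <= 0) return(0)
    p <- as.numeric(Matrix::expm(Q * t) %*% p0)
    p[dim_n]
  }, numeric(1))
}

#' Fraction unwound for the uniform n-step model
#'
#' For `n = 1`, `k_rebind = 0` this reduces to `f_P (1 - exp(-k t))`; the
#' productive path's mean completion time is n/k (Erlang); with
#' `k_rebind > 0` the fraction tends to 1.
#'
#' @param spec a uniform-variant [ensemble_spec()].
#' @param times time points (s).
#' @return fraction unwound at each time.
#' @export
nstep_transient <- function(spec, times) {
  stopifnot(inherits(spec, "ensemble_spec"), spec$variant == "uniform")
  .chain_transient(rep(spec$k, spec$n), spec$f_P, spec$k_rebind,
                   spec$rebind_productive, times)
}

#' Fraction unwound for the sequence-dependent models
#'
#' Per-step rates are the reciprocal mean pause times of the stepping model
#' over the fork's 33-bp duplex (with the final partial step truncated), with
#' the same productive-fraction branching as the uniform model.
#'
#' @param spec a simultaneous/delayed [ensemble_spec()].
#' @param fork a [fork_substrate()].
#' @param conditions [ionic_conditions()].
#' @param times time points (s).
#' @return fraction unwound at each time.
#' @export
seqdep_transient <- function(spec, fork, conditions = ionic_conditions(),
                             times) {
  stopifnot(inherits(spec, "ensemble_spec"), spec$variant != "uniform")
  .chain_transient(.ensemble_rates(spec, fork, conditions), spec$f_P,
                   spec$k_rebind, spec$rebind_productive, times)
}

#' Stochastic ensemble oracle
#'
#' Event-driven simulation of `n_mol` independent molecules through the same
#' branching chain; used as an independent cross-check of the
#' matrix-exponential transient.
#'
#' @param spec an [ensemble_spec()].
#' @param times evaluation times.
#' @param n_mol number of molecules.
#' @param seed integer seed.
#' @param fork,conditions for sequence-dependent variants.
#' @return fraction unwound at each time.
#' @export
ensemble_stochastic <- function(spec, times, n_mol = 10000L, seed = 1L,
                                fork = NULL, conditions = ionic_conditions()) {
  rates <- if (spec$variant == "uniform") rep(spec$k, spec$n) else
    .ensemble_rates(spec, fork, conditions)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t_max <- max(times)
  f_in <- if (spec$rebind_productive) 1 else spec$f_P
  done <- vapply(seq_len(n_mol), function(i) {
    t <- 0
    productive <- stats::runif(1) < spec$f_P
    repeat {
      if (!productive) {
        if (spec$k_rebind <= 0) return(Inf)
        t <- t + stats::rexp(1, spec$k_rebind)
        productive <- stats::runif(1) < f_in
        if (t > t_max) return(Inf)
        next
      }
      t <- t + sum(stats::rexp(length(rates), rates))
      return(t)
    }
  }, numeric(1))
  vapply(times, function(tt) mean(done <= tt), numeric(1))
}

#' Simulate quenched-flow-like single-turnover transients
#'
#' Evaluates the model at the sampled time points, adds Gaussian noise and
#' clips to [0, 1]; replicates share time points.
#'
#' @param substrates list of [fork_substrate()] (or a single one).
#' @param spec an [ensemble_spec()].
#' @param timepoints sampling times (s).
#' @param noise_sd Gaussian noise SD on the fraction.
#' @param n_replicates replicates per substrate.
#' @param seed integer seed.
#' @param conditions [ionic_conditions()].
#' @return a `transient_data` data.frame: `time_s`, `fraction`, `substrate`,
#'   `rep`; ground-truth fractions in attribute `truth`.
#' @export
simulate_quenchflow <- function(substrates, spec, timepoints, noise_sd = 0.03,
                                n_replicates = 3L, seed = 1L,
                                conditions = ionic_conditions()) {
  if (inherits(substrates, "fork_substrate")) substrates <- list(substrates)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list(); truth <- list()
  for (sb in substrates) {
    f <- if (spec$variant == "uniform") nstep_transient(spec, timepoints) else
      seqdep_transient(spec, sb, conditions, timepoints)
    truth[[sb$name]] <- f
    for (r in seq_len(n_replicates)) {
      fr <- pmin(pmax(f + stats::rnorm(length(f), sd = noise_sd), 0), 1)
      rows[[length(rows) + 1]] <- data.frame(
        time_s = timepoints, fraction = fr, substrate = sb$name, rep = r)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  class(out) <- c("transient_data", "data.frame")
  out
}

#' Global fit of single-turnover transients across substrates
#'
#' For each integer step size in `n_range`, the shared parameters (rate `k`
#' or pre-factor `A`, `f_P`, `k_rebind`) are fitted by weighted least squares
#' jointly over all substrates; weights are per-point SEMs across replicates
#' (uniform fallback). Reports the reduced chi-square per n and the argmin.
#'
#' @param transients a [simulate_quenchflow()]-style `transient_data`.
#' @param variant model variant to fit.
#' @param n_range integer step sizes to scan.
#' @param substrates named list of [fork_substrate()] matching the
#'   `substrate` column (required for sequence-dependent variants).
#' @param conditions [ionic_conditions()].
#' @return a `global_fit` list: `table` (per n: parameters, chisq_nu,
#'   converged), `best_n`, `best` (fit at argmin).
#' @export
global_fit <- function(transients, variant = "delayed", n_range = 1:7,
                       substrates = NULL, conditions = ionic_conditions()) {
  agg <- stats::aggregate(fraction ~ time_s + substrate, data = transients,
                          FUN = mean)
  sem <- stats::aggregate(fraction ~ time_s + substrate, data = transients,
                          FUN = function(v) stats::sd(v) / sqrt(length(v)))
  agg$sem <- sem$fraction
  agg$sem[!is.finite(agg$sem) | agg$sem <= 0] <-
    stats::median(agg$sem[is.finite(agg$sem) & agg$sem > 0]) %||% 1
  if (all(!is.finite(agg$sem)) || all(agg$sem == 0)) agg$sem <- 1
  subs <- split(agg, agg$substrate)
  if (variant != "uniform" && is.null(substrates)) {
    stop("sequence-dependent fitting needs the substrate objects")
  }
  fit_one_n <- function(n) {
    model_frac <- function(par, sub_name, times) {
      sp <- if (variant == "uniform") {
        ensemble_spec("uniform", n = n, k = exp(par[1]),
                      f_P = stats::plogis(par[2]), k_rebind = exp(par[3]))
      } else {
        ensemble_spec(variant, n = n, A = exp(par[1]),
                      f_P = stats::plogis(par[2]), k_rebind = exp(par[3]))
      }
      if (variant == "uniform") nstep_transient(sp, times) else
        seqdep_transient(sp, substrates[[sub_name]], conditions, times)
    }
    obj <- function(par) {
      sum(unlist(lapply(subs, function(df) {
        ((df$fraction - model_frac(par, df$substrate[1], df$time_s)) /
           df$sem)^2
      })))
    }
    start <- c(log(if (variant == "uniform") 5 else 1e-3), stats::qlogis(0.6),
               log(0.05))
    op <- tryCatch(stats::optim(start, obj, method = "Nelder-Mead",
                                control = list(maxit = 2000, reltol = 1e-10)),
                   error = function(e) NULL)
    if (is.null(op)) {
      return(list(ok = FALSE, chisq_nu = NA_real_, par = rep(NA_real_, 3)))
    }
    dof <- nrow(agg) - 3
    list(ok = op$convergence == 0, chisq_nu = op$value / dof, par = op$par,
         value = op$value)
  }
  fits <- lapply(n_range, fit_one_n)
  tab <- data.frame(
    n = n_range,
    chisq_nu = vapply(fits, `[[`, numeric(1), "chisq_nu"),
    rate = exp(vapply(fits, function(f) f$par[1], numeric(1))),
    f_P = stats::plogis(vapply(fits, function(f) f$par[2], numeric(1))),
    k_rebind = exp(vapply(fits, function(f) f$par[3], numeric(1))),
    converged = vapply(fits, `[[`, logical(1), "ok"))
  names(tab)[names(tab) == "rate"] <- if (variant == "uniform") "k" else "A"
  best_i <- which.min(tab$chisq_nu)
  structure(list(table = tab, best_n = n_range[best_i],
                 best = tab[best_i, ], variant = variant),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("<global_fit (%s): best n = %d, chisq_nu = %.3g>\n",
              x$variant, x$best_n, x$best$chisq_nu))
  invisible(x)
}
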