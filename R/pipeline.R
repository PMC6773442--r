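# End-to-end pipeline: substrate synthesis -> simulation -> step detection ->
# pause analysis, with a provenance manifest (config hash + seeds).

#' Run the single-molecule analysis pipeline on synthetic data
#'
#' Executes synthesize -> simulate -> detect -> analyze with one seed and one
#' configuration list and returns all intermediate products plus a
#' provenance manifest. Stages:
#' \enumerate{
#'   \item substrate: [default_hairpin()] or a substrate supplied in
#'     `config$substrate`;
#'   \item energy profile and windowed stability peaks;
#'   \item calibrated stochastic trajectories and rendered noisy traces;
#'   \item step detection (configurable detector), dwell histogram, pause
#'     table;
#'   \item pause-position vs energy-peak regression.
#' }
#'
#' @param config list with optional entries `substrate`, `conditions`,
#'   `sim` ([sim_config()]), `meas` ([meas_config()]), `n_traces`,
#'   `detector` ("ledger", "ttest" or "km"), `min_pause_s`, `out_dir`
#'   (results are written there when given).
#' @param seed integer seed for every stochastic stage.
#' @return a `pipeline_result` list with `substrate`, `profile`, `stability`,
#'   `energy_peaks`, `traces` (when a noisy detector is used), `pauses`,
#'   `dwell`, `dwell_peaks`, `regression`, `manifest`.
#' @export
run_pipeline <- function(config = list(), seed = 1L) {
  substrate <- config$substrate %||% default_hairpin()
  conditions <- config$conditions %||% ionic_conditions()
  simc <- config$sim %||% sim_config()
  mc <- config$meas %||% meas_config()
  n_traces <- config$n_traces %||% 50L
  detector <- config$detector %||% "ledger"
  min_pause <- config$min_pause_s %||% 0.14
  profile <- compute_bp_energies(substrate, conditions)
  if (is.null(simc$A)) simc$A <- calibrate_prefactor(substrate, simc, profile)
  stab <- stability_profile(profile, window_bp = 6)
  energy_peaks <- fit_gaussian_peaks(stab$positions, stab$values)
  seeds <- derive_seeds(seed, n_traces)
  pauses <- .simulated_pause_tables(substrate, simc, profile, n_traces, seeds,
                                    detector = detector, mc = mc,
                                    min_duration_s = min_pause)
  trajs <- lapply(seq_len(n_traces), function(i) {
    simulate_trajectory(substrate, simc, profile, seed = seeds[i])
  })
  dwell <- dwell_histogram(trajs, bin_bp = 1, L = substrate$length)
  # ledger dwell is a comb (pauses sit at exact step levels); smooth over one
  # kinetic step before peak fitting, as detector jitter would in real traces
  smooth_w <- min(5L, nrow(dwell))
  dsm <- stats::filter(dwell$dwell_s, rep(1 / smooth_w, smooth_w), sides = 2)
  dsm[is.na(dsm)] <- 0
  dwell_peaks <- fit_gaussian_peaks(dwell$position_bp, as.numeric(dsm))
  regression <- tryCatch(
    pause_energy_regression(dwell_peaks, energy_peaks),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "regression_result"))
  cfg_canon <- jsonlite::toJSON(list(
    substrate = substrate$stem_sequence, conditions = unclass(conditions),
    sim = unclass(simc), meas = unclass(mc), n_traces = n_traces,
    detector = detector, min_pause_s = min_pause),
    auto_unbox = TRUE, digits = NA)
  manifest <- list(config_hash = fnv1a_hash(as.character(cfg_canon)),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("helipause")))
  out <- list(substrate = substrate, profile = profile, stability = stab,
              energy_peaks = energy_peaks, pauses = pauses, dwell = dwell,
              dwell_peaks = dwell_peaks, regression = regression,
              manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(substrate, file.path(config$out_dir, "substrate.fasta"))
    utils::write.table(dwell, file.path(config$out_dir, "dwell_histogram.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %s, %d pause tables, manifest %s>\n",
              x$substrate$name, length(x$pauses), x$manifest$config_hash))
  invisible(x)
}

#' Minimum unwinding rate at which steps of a given size are resolvable
#'
#' A step of `step_bp` base pairs is resolvable when the flanking pauses last
#' at least `min_pause_s`; the corresponding unwinding-rate ceiling is
#' step_bp / min_pause_s (a 4-bp step at 300 ms gives ~13 bp/s). The
#' companion [min_resolvable_pause()] derives the pause floor from the
#' baseline noise.
#'
#' @param step_bp kinetic step size (bp).
#' @param min_pause_s minimum resolvable pause (s).
#' @return rate ceiling in bp/s.
#' @export
resolvable_rate_threshold <- function(step_bp = 4, min_pause_s = 0.3) {
  step_bp / min_pause_s
}

#' Minimum pause duration for a step to clear the baseline noise
#'
#' Requires the SE of the plateau mean, sigma/sqrt(f tau), to be at most
#' `snr_factor` times smaller than the step's extension change.
#'
#' @param step_bp step size (bp).
#' @param mc a [meas_config()].
#' @param snr_factor required ratio of step height to plateau-mean SE.
#' @return minimum pause in seconds.
#' @export
min_resolvable_pause <- function(step_bp = 4, mc = meas_config(),
                                 snr_factor = 1.7) {
  step_nm <- step_bp * nm_per_bp(mc)
  (snr_factor * mc$noise_sigma_nm / step_nm)^2 / mc$sampling_hz
}
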