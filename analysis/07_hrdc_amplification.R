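#!/usr/bin/env Rscript
# Signatures of accessory-domain (HRDC-like) pause amplification: the
# dwell-vs-stability power law for the core model, the constant-affinity
# competition baseline, two-component pause-lifetime mixtures, and the
# suppression of dwell peaks by displaced-strand mismatches.
#
# Outputs (results/07/):
#   power_law.json        exponent for core dwell and competition baseline
#   lifetimes.json        exponential-mixture fit of synthetic pause data
#   mismatch_dwell.tsv    dwell histograms for 0-3 mismatch variants

suppressPackageStartupMessages(library(helipause))
out <- "results/07"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

hp <- default_hairpin()
cond <- ionic_conditions()
prof <- compute_bp_energies(hp, cond)
cfg <- sim_config(model = "delayed", n = 5)
cfg$A <- calibrate_prefactor(hp, cfg, prof)

# core (no accessory domain): dwell scales ~linearly with stability
trajs <- lapply(derive_seeds(707L, 80), function(s) {
  simulate_trajectory(hp, cfg, prof, seed = s)
})
dh <- dwell_histogram(trajs, bin_bp = 1, L = hp$length)
pl_core <- dwell_power_law(dh, prof, window_bp = 10)

# constant-affinity kinetic-competition baseline over a 1-3 kBT sweep
g_sweep <- seq(1, 3, length.out = 40)
tau <- 5 * cfg$A * exp(g_sweep)
p_cap <- 5 / (5 + 1 / tau)
dwell_comp <- tau + p_cap / 0.5
pl_comp <- stats::coef(stats::lm(log(dwell_comp) ~ g_sweep))[[2]]

jsonlite::write_json(list(core_power = pl_core$power,
                          core_power_se = pl_core$power_se,
                          competition_power = pl_comp),
                     file.path(out, "power_law.json"), auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("dwell-vs-stability exponent: core %.2f +/- %.2f; constant-affinity competition %.2f\n",
            pl_core$power, pl_core$power_se, pl_comp))
cat("  (neither reaches the strongly amplified regime: amplified pausing\n   needs stability-dependent accessory-domain affinity)\n")

# pause-lifetime mixture: amplified pausing has two populations
set.seed(708)
d <- c(rexp(400, 1 / 1.8), rexp(400, 1 / 0.4))
lf <- pause_lifetime_fit(d, components = 1:2)
jsonlite::write_json(list(n_components = lf$n_components,
                          lifetimes = lf$lifetimes,
                          lifetime_se = lf$lifetime_se,
                          amplitudes = lf$amplitudes),
                     file.path(out, "lifetimes.json"), auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("lifetime mixture: %d components, tau = %s s\n", lf$n_components,
            paste(sprintf("%.2f", lf$lifetimes), collapse = " / ")))

# mismatch suppression of dwell peaks (mismatched bp opens freely)
mm_sets <- list(none = integer(0), mm90 = 90, mm90_104 = c(90, 104),
                mm90_104_124 = c(90, 104, 124))
rows <- list()
for (nm in names(mm_sets)) {
  sub <- if (length(mm_sets[[nm]])) make_mismatch_variant(hp, mm_sets[[nm]])
         else hp
  pr <- compute_bp_energies(sub, cond)
  cf <- sim_config(model = "delayed", n = 5)
  cf$A <- cfg$A   # same enzyme: pre-factor fixed across substrates
  tj <- lapply(derive_seeds(709L, 60), function(s) {
    simulate_trajectory(sub, cf, pr, seed = s)
  })
  dhv <- dwell_histogram(tj, bin_bp = 1, L = hp$length)
  rows[[nm]] <- cbind(variant = nm, dhv)
}
write.table(do.call(rbind, rows), file.path(out, "mismatch_dwell.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
# a mismatch at bp j removes the opening cost of j, so the kinetic step
# containing j loses its pause: summarize each peak as the summed dwell in a
# +-7 bp window around the cluster center
peak_near <- function(nm, ctr) {
  d <- rows[[nm]]
  sum(d$dwell_s[abs(d$position_bp - ctr) <= 7])
}
cat(sprintf("core dwell near 90 bp: intact %.1f s -> 1 mismatch %.1f s (weak: the core sums per-bp times)\n",
            peak_near("none", 90), peak_near("mm90", 90)))

# the accessory-domain amplifier raises dwell as (windowed stability)^Power;
# the same mismatch then suppresses the peak many-fold
amp_profile <- function(sub) {
  pr <- compute_bp_energies(sub, cond)
  st <- stability_profile(pr, window_bp = 10)
  data.frame(position_bp = st$positions, dwell_amp = st$values^17.2)
}
amp <- lapply(list(none = hp, mm90 = make_mismatch_variant(hp, 90)),
              amp_profile)
write.table(rbind(cbind(variant = "none", amp$none),
                  cbind(variant = "mm90", amp$mm90)),
            file.path(out, "amplified_dwell.tsv"), sep = "	",
            row.names = FALSE, quote = FALSE)
pk_amp <- vapply(amp, function(d) {
  max(d$dwell_amp[abs(d$position_bp - 90) <= 7])
}, numeric(1))
cat(sprintf("amplified (Power = 17.2) dwell peak at 90 bp: %.0f-fold suppression by one mismatch\n",
            pk_amp["none"] / pk_amp["mm90"]))
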