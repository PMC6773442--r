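# Shared fixtures, built once per test run.

hp174 <- default_hairpin()
cond_assay <- ionic_conditions()
prof174 <- compute_bp_energies(hp174, cond_assay)

calibrated_config <- function(model = "delayed", n = 5L,
                              substrate = hp174, profile = prof174, ...) {
  cfg <- sim_config(model = model, n = n, ...)
  cfg$A <- calibrate_prefactor(substrate, cfg, profile)
  cfg
}

# uniform-energy profile helper for closed-form checks
flat_profile <- function(g, L, conditions = cond_assay) {
  structure(list(g1bp = rep(g, L), substrate = NULL, conditions = conditions,
                 parameter_set = "flat", mismatch_energy = 0),
            class = "duplex_energy_profile")
}

# noiseless rendering shortcut
quiet_meas <- function(hz = 200) {
  meas_config(sampling_hz = hz, noise_sigma_nm = 0)
}
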