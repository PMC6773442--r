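#!/usr/bin/env Rscript
# Single-turnover ensemble kinetics on forked substrates: synthesize
# quenched-flow transients for three GC contents under the delayed-release
# 5-bp model and recover the kinetic step size by global fitting.
#
# Outputs (results/05/):
#   transients.tsv      synthetic fraction-unwound time courses
#   global_fit.tsv      chi2_nu and shared parameters per step size n

suppressPackageStartupMessages(library(helipause))
out <- "results/05"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cond <- ionic_conditions()
forks <- list(gc36 = make_fork(12, seed = 5), gc48 = make_fork(16, seed = 6),
              gc79 = make_fork(26, seed = 3))
A5 <- calibrate_prefactor(forks$gc79, sim_config("delayed", 5),
                          compute_bp_energies(forks$gc79, cond))
truth <- ensemble_spec("delayed", n = 5, A = A5, f_P = 0.6, k_rebind = 0.03)

# dense early sampling resolves the initial lag that carries the step-size
# information; sparse coverage there leaves n nearly unidentifiable
timepoints <- c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.7, 1, 1.5, 2, 3, 5, 10, 20,
                40, 80, 150)
qd <- simulate_quenchflow(forks, truth, timepoints, noise_sd = 0.02,
                          n_replicates = 3, seed = 505L, conditions = cond)
write.table(qd, file.path(out, "transients.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

gf <- global_fit(qd, variant = "delayed", n_range = 1:7, substrates = forks,
                 conditions = cond)
write.table(gf$table, file.path(out, "global_fit.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("generating truth: delayed, n = 5, A = %.3g s, f_P = 0.6\n", A5))
cat(sprintf("global-fit argmin: n = %d (chi2_nu %.3g); A = %.3g, f_P = %.2f, k_rebind = %.3g/s\n",
            gf$best_n, gf$best$chisq_nu, gf$best$A, gf$best$f_P,
            gf$best$k_rebind))
near <- gf$table[gf$table$n %in% c(4, 5, 6), c("n", "chisq_nu")]
cat("chi2_nu near the optimum (n = 4 and 5 are nearly equivalent, as\n")
cat("expected for single-turnover transients):\n")
print(near, row.names = FALSE)
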