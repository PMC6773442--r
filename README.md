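# helipause

Sequence-dependent DNA unwinding kinetics and pause analysis for
melting-limited helicases, exercised entirely on synthetic data with
controlled ground truth.

## The problem

A helicase unwinding duplex DNA pauses where the duplex is stable. For
*E. coli* RecQ-family enzymes the pause pattern on a DNA hairpin tracks the
nearest-neighbor melting-energy profile of the sequence, and the *size* of
that effect encodes the microscopic stepping mechanism: an enzyme opening
one base pair per rate-limiting cycle can modulate its dwell by at most
`exp(ΔG) ≈ 7`-fold (the ~2 k<sub>B</sub>T G/C-vs-A/T contrast), while the
much larger observed contrast requires a multi-bp kinetic step. The package
implements the two candidate mechanisms over an *n*-bp kinetic step,

- **simultaneous melting** — τ<sub>p</sub>(i) = A · exp( Σ<sub>s=1..n</sub> G<sub>1bp</sub>((i−1)n+s) ),
- **delayed release** — τ<sub>p</sub>(i) = Σ<sub>s=1..n</sub> A · exp( G<sub>1bp</sub>((i−1)n+s) ),

together with everything needed to discriminate them from data: nearest-
neighbor energetics with monovalent-salt correction, stochastic trajectory
simulation calibrated to a target mean rate, a worm-like-chain measurement
model (8 pN, 14 nm noise at 200 Hz), two step/pause detectors (recursive
Welch-t segmentation and iterative χ²-step placement), dwell histograms and
pause tables, reduced-χ² model/step-size selection, salt-dependence
predictions, *n*-step single-turnover ensemble kinetics with a productive
fraction and rebinding, and the nucleotide-analog (ATPγS) binomial
competition model of mechano-chemical coupling,

- P = [ATPγS] / (k<sub>ratio</sub>·[ATP] + [ATPγS]),  l = mP,
- τ = mP/k<sub>off</sub> + 1/k<sub>step</sub>,  v = n/τ,  C = m/n bp per ATP.

For the audience: single-molecule biophysicists and enzyme kineticists who
want a tested, seeded, end-to-end reference implementation of this analysis
chain, or a simulation harness to probe what their detectors can and cannot
resolve.

## Worked example

```r
library(helipause)

hp   <- default_hairpin()                       # 174 bp, GC clusters at 55/90/120
prof <- compute_bp_energies(hp, ionic_conditions())
prof
#> <duplex_energy_profile: 174 bp, G_1bp 1.43-4.00 kBT, 50 mM Na+, 5 mM Mg2+>

cfg   <- sim_config(model = "delayed", n = 5)   # 1 bp melt, 5 bp release
cfg$A <- calibrate_prefactor(hp, cfg, prof)     # hit 46 bp/s mean rate
cfg$A
#> 0.000799

traj <- simulate_trajectory(hp, cfg, prof, seed = 1)
traj
#> <trajectory: 174 bp in 3.61 s (35 kinetic steps, delayed, n=5)>

tr  <- render_measurement(traj, meas_config(), seed = 2)   # noisy nm trace
fit <- to_bp(tstep_find(tr))                               # detect, nm -> bp
head(extract_pauses(fit, min_duration_s = 0.14), 3)
#>   position_bp duration_s trace_id
#> 1       0.963      1.205        1
#> 2      17.207      0.165        1
#> 3      31.983      0.235        1

fit_coupling(simulate_coupling_dataset(seed = 1))
#> <coupling_fit: C 0.92 +/- 0.10 bp/ATP, k_ratio 1.06 +/- 0.19, 1/k_off 0.40 s, k_step 10.0/s>
```

The per-bp opening cost spans 1.4–4.0 k<sub>B</sub>T across the synthetic
hairpin; the calibrated delayed-release motor opens all 174 bp in ~3.6 s
(46 bp/s); detected pauses concentrate at the planted GC clusters; and the
coupling fit recovers roughly one ATP per base pair with a near-unity
nucleotide on-rate ratio from a six-fraction analog titration.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write tables under `results/`:

1. `01_substrates_and_energies.R` — substrates, energy/stability profiles, peaks
2. `02_simulate_unwinding.R` — calibration, trajectories, salt predictions
3. `03_step_detection.R` — both detectors, pause tables, dwell histograms
4. `04_model_selection.R` — reduced-χ² scan over (model, n); pause–stability regression
5. `05_ensemble_kinetics.R` — quenched-flow transients, global n-scan fit
6. `06_coupling.R` — step sizes under analog pausing, coupling fit, occupancy
7. `07_hrdc_amplification.R` — power-law amplification, lifetime mixtures, mismatch suppression

Each script states what it found on stdout; all randomness is seeded.

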