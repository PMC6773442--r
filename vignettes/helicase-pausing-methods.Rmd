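---
title: "Models and methods: sequence-dependent helicase unwinding and pausing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sequence-dependent helicase unwinding and pausing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helipause)
```

# Scope

`helipause` models the unwinding of duplex DNA by a helicase whose forward
motion is rate-limited by base-pair melting, and provides the full analysis
chain used to characterize such a motor from single-molecule and ensemble
data: duplex energetics, stochastic trajectory simulation, a magnetic-tweezers
measurement model, step/pause detection, kinetic step-size selection by
reduced chi-square, single-turnover ensemble kinetics, and a nucleotide-analog
competition model of mechano-chemical coupling. Every input is synthetic with
controlled ground truth, so each stage of the chain can be validated against
the truth that generated its data.

# Duplex energetics

The opening cost of base pair $j$, $G_{1bp}(j)$ (in $k_BT$, positive), is the
mean of its two flanking nearest-neighbor stack free energies (terminal base
pairs use their single stack), computed from the unified oligonucleotide
nearest-neighbor parameter set (SantaLucia 1998) with the per-stack
monovalent-salt entropy correction $\Delta S' = \Delta S + 0.368\,\ln[\mathrm{Mon}^+]$.
Divalent magnesium is folded into an equivalent monovalent concentration,
$[\mathrm{Mon}^+] = [\mathrm{Na}^+] + 3.3\sqrt{[\mathrm{Mg}^{2+}]}$ (molar), a
standard empirical equivalence. Temperature is fixed at 25&nbsp;°C
($k_BT = 4.11$ pN·nm); the assay buffer default is 50&nbsp;mM Na⁺ +
5&nbsp;mM Mg²⁺.

Under these defaults the interior G/C-context cost exceeds the A/T-context
cost by about 2.0 $k_BT$, i.e. a Boltzmann dwell ratio near 7-fold for
single-bp melting — the anchor that motivates multi-bp kinetic steps: observed
pause contrast much larger than 7-fold cannot come from 1-bp stepping.

A displaced-strand mismatch is stored as an annotation (the tracked strand is
unchanged); the mismatched pair's opening cost defaults to 0 (free to open),
configurable via `mismatch_energy`. No mismatch nearest-neighbor
thermodynamics are attempted.

The windowed **stability profile** is the running mean of $\exp(G_{1bp})$
over a 6-bp window — exponentiate first, then average. The order matters
(Jensen's inequality) and is pinned by tests. A window starting at $j$ is
reported at $j + \lfloor w/2 \rfloor$.

# Stepping models and simulation

Two microscopic models share an $n$-bp kinetic step (step $i$ covers bps
$n(i-1)+1 \dots \min(ni, L)$, the last step truncated):

* **simultaneous melting** — all $n$ bps open in one activated event:
  $\tau_p(i) = A\,\exp\!\big(\sum_{s} G_{1bp}\big)$;
* **delayed release** — bps open one at a time but the nascent ssDNA is
  released only after $n$ bp: $\tau_p(i) = \sum_{s} A\,\exp(G_{1bp})$.

Both are linear in the pre-factor $A$, so calibrating the expected mean rate
$L/(\sum_i \tau_p + \sum_i \tau_t)$ to a target (46 bp/s, the reference
construct's mean unwinding rate) is closed-form. Translocation after each
melt is a deterministic delay of $n/v_\mathrm{trans}$ ($v_\mathrm{trans}$ =
100 bp/s) followed by an instantaneous jump. Pause durations are drawn
exponentially with the model value as the mean; a deterministic mode exists
for exact tests. The simulator has no backsliding or strand switching. The
"mean rate" throughout is the pooled (time-weighted) rate — total bp over
total time — which is the quantity the calibration equation fixes;
per-trace mean-of-rates is Jensen-biased upward by a few percent at
$L = 174$ bp.

The measurement model renders bp positions into tether extension through the
worm-like-chain interpolation formula
$FL_p/k_BT = x + \tfrac{1}{4}(1-x)^{-2} - \tfrac{1}{4}$ at 8 pN with a 1 nm
ssDNA persistence length and 0.65 nm per nucleotide: 0.39 nm per released
nucleotide, ~0.79 nm per unwound bp (two nucleotides). Gaussian noise of
14 nm SD is added independently per sample at 200 Hz. The noise is modelled
as white; real bead noise is correlated (low-passed), which concentrates less
power at the frequencies that matter for step detection — see the detection
limit below.

The nucleotide-analog mode adds, per kinetic step, $m = C\,n$ binding events,
each being the slowly released analog with probability
$P = [\mathrm{analog}]/(k_\mathrm{ratio}[\mathrm{ATP}] + [\mathrm{analog}])$;
each bound analog appends an exponential dwell of mean $1/k_\mathrm{off}$
(0.4 s) to the step's pause.

# Step detection and its limits

Two detectors share one output contract (segment boundaries, mean levels,
durations):

* `tstep_find` — recursive binary segmentation on the Welch *t* statistic
  between the samples adjacent to each candidate changepoint (up to
  `window_samples` per side), splitting at the maximal $|t|$ above the
  $\alpha$-level critical value;
* `km_step_find` — iterative placement of the single best
  chi-square-reducing step, stopping when the best remaining step's reduction
  falls below $z_\mathrm{accept}^2$ times a robust noise variance (median
  absolute successive difference), with the counter-fit quality ratio
  reported as a diagnostic.

Both feed a shared polish pass: each boundary is re-localized at the exact
least-squares split of its flanking bracket, and boundaries whose
full-segment Welch $|t|$ falls below `z_merge` are merged away, iterated to a
fixed point. An optional `decimate` argument block-averages the trace before
detection (boundary polish is always at full resolution): coarse-graining
removes none of the boundary evidence but shrinks the changepoint search
multiplicity, which is what limits detection near the noise floor. All
defaults were calibrated on synthetic benchmarks generated by this package;
both detectors are exact on noiseless staircases.

**Detection limit.** A 5-bp step is a 3.9 nm extension change. With white
14-nm noise at 200 Hz and ~1 s flanking dwells the per-boundary evidence is
$z = \Delta/\sigma\sqrt{2/n} \approx 2.8$, *below* the
$\sqrt{2\ln n} \approx 3.6$ selection noise of a changepoint search over
traces of this length. Consequences, all quantified in the tests: any
false-positive-controlled detector misses ~25–35% of boundaries; merged
steps concentrate at multiples of 5 bp; boundary localization has an
exponential tail of scale $\sigma^2/\Delta^2 \approx 26$ samples; and
threshold selection biases accepted step sizes upward by about +1 bp
(winner's curse). The detected step-size distribution at a 50% analog
fraction is therefore a unimodal hump whose fitted center sits near 7 bp
rather than at the generating 5 bp — an oracle that is handed the true
boundaries of all pauses ≥ 0.3 s recovers 5.1 bp from the same rendered
traces. Reproducing a 5-bp center from detected steps under these conditions
would require either longer pauses (≥ ~3 s), lower effective noise
(≲ 8 nm white-equivalent), or a noise model with less power at the step
frequencies. The step-size histogram is fitted with a BIC-selected sum of
1–3 Gaussians and the dominant (largest-area) component reported, which
keeps the merged-step satellites (10, 15 bp) from dragging a single-Gaussian
center even higher.

A step of $s$ bp is considered resolvable when its flanking pauses exceed
`min_resolvable_pause()` (~0.3 s for 4 bp at the default noise); the
corresponding rate ceiling `resolvable_rate_threshold()` is $s/\tau_{\min}$
(~13 bp/s for 4 bp at 0.3 s).

# Pause statistics and model selection

Pauses are segments above a duration threshold (default 0.14 s, the core
construct's mean pause) bounded by forward motion; the dwell histogram
accumulates every segment's duration at its bp level (1-bp bins) and
conserves total time exactly.

The kinetic step size and stepping model are selected by simulating every
(model, $n$) cell — each re-calibrated to the same mean rate — analyzing the
simulated trajectories identically to the reference, binning mean pause
durations over 5 bp, and computing the reduced chi-square per cell. Weights
combine the reference and simulation per-bin SEMs, so the statistic is ~1 at
the generating cell when cell sample sizes match; with reference-only
weights the generating cell would sit near 2 under matched noise, which is
why the combined form is used. For the scan itself every kinetic-step pause
enters (no duration threshold), keeping all cells on the same bin support —
cells evaluated on different bin subsets have incomparable reduced
chi-squares.

Salt dependence discriminates the models independently of the scan: with $A$
frozen at its reference-condition value, the simultaneous model's rate falls
roughly twice as fast between 25 and 500 mM Na⁺ as the delayed-release
model's, because it exponentiates the summed (not per-bp) energy.

The dwell-vs-stability power law ($y = Ax^P$, fitted in log–log space, with
$x$ the exponential of the 10-bp-averaged energy) is the amplification
readout: the core delayed-release model gives $P \lesssim 1$ (the
translocation floor compresses it below 1), and a constant-affinity
kinetic-competition model of accessory-domain binding — capture probability
$p = k_\mathrm{bind}/(k_\mathrm{bind} + 1/\tau_p)$, saturating at 1 — cannot
push $P$ much above 2. Strongly super-linear exponents therefore require the
accessory domain's affinity itself to grow with duplex stability; the
exploratory `hrdc_competition_baseline()` exists to make that argument
quantitative. Pause-lifetime mixtures (one vs two exponential components,
EM-fitted, BIC-compared) separate amplified from core pausing populations.

# Ensemble kinetics

Single-turnover unwinding is a branching chain: a productive fraction $f_P$
traverses $n$ irreversible steps (uniform rate $k$, or sequence-dependent
rates $1/\tau_p(i)$ over the fork duplex); the non-productive fraction
rebinds at $k_\mathrm{rebind}$ and re-partitions with the same $f_P$ (an
always-productive-on-rebind alternative sits behind a flag). Transients are
matrix exponentials of the chain generator, cross-checked against an
event-driven stochastic oracle. Identifiability caveats the tests
demonstrate: $n$ is carried almost entirely by the early lag, so sparse
early sampling (or a single substrate with a free rate) leaves the
chi-square scan flat in $n$, and even with three GC contents and dense early
sampling $n = 4$ and $n = 5$ are nearly equivalent. Fit weights are
per-point SEMs over replicates.

# Mechano-chemical coupling

With $\tau = mP/k_\mathrm{off} + 1/k_\mathrm{step}$ and $v = n/\tau$ (the
rate form; a product would be dimensionally inconsistent), the observables
depend on $C = m/n$ and $k_\mathrm{off}$ only through their ratio, so the
pair is not jointly identifiable from $(\tau, v)$ data. `fit_coupling()`
therefore holds $k_\mathrm{off}$ at the independently measured analog
release rate (2.5/s, i.e. the ~0.4 s pause-escape time at saturating analog)
and fits $(C, k_\mathrm{ratio}, k_\mathrm{step})$ by joint weighted least
squares. At the study conditions (six analog fractions 5–50% of 1 mM total,
5% noise) single-dataset recovery is $C = 1.0 \pm 0.12$ and
$k_\mathrm{ratio} = 1.2 \pm 0.24$; headline values are reported as medians
over 200 replicate datasets. The binomial occupancy simulation confirms the
model's neglect of repeated analog binding: fewer than one analog
incorporation per bp even at a 50% fraction. A validity flag fires if the
user-supplied analog hydrolysis bound (default 0.2/s) is not well below
$k_\mathrm{off}$.

# The synthetic-data generator

The default hairpin is 174 bp with 10-bp GC-rich clusters (GC fraction 0.9,
placed by exact count) centered at 55, 90 and 120 bp on a 0.35-GC
background — a parameterized stand-in reproducing the length and
strong-pause-cluster positions of the experimental substrate, not its
sequence. Forks carry a 33-bp duplex with an exact GC count (12/16/26 for
36/48/79%) and 21-nt arms. Everything is seeded and bit-reproducible, and
every rendered trace carries its ground-truth trajectory for oracle checks.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: correlated bead noise and drift, enzyme
backsliding and strand-switching, force fluctuations, heterogeneous enzyme
populations, and any mismatch thermodynamics beyond the zero-cost override.

# Numerical choices and problem sizes

Seeded determinism everywhere (`derive_seeds()` splits one master seed per
stage); constructors save and restore the caller's RNG state. The WLC
fractional extension is solved by `uniroot` to 1e-12. Degenerate inputs are
handled explicitly: flat profiles give zero Gaussian components, noiseless
staircases collapse the detectors' noise estimates (guarded against
floating-point cancellation by scale-aware floors on the t statistics), and
exact regression fits floor the residual scale. Default problem sizes keep
the full test suite under ~30 s and the acceptance script under ~10 s on one
core: 100-trace calibration checks, 60–80 traces per chi-square cell,
20 noisy traces for step sizing, 200 replicate coupling fits, 10⁴–2×10⁴
molecules for stochastic ensemble oracles.

# Known limitations

* The step-size pipeline is detection-limited at the default noise model, as
  analyzed above; its centers are reproducible but sit above the generating
  step size.
* $n$-selection from ensemble transients is shallow between adjacent $n$.
* Mismatch energetics are a zero-cost override, not a thermodynamic model.
* The constant-affinity competition model is deliberately a baseline; no
  mechanistic model of stability-dependent accessory-domain binding is
  fitted.
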