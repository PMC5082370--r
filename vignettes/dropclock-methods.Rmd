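---
title: "Models and methods behind dropclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dropclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dropclock` analyzes — and generates — single-cell fluorescence
trajectories of circadian oscillators measured in microfluidic droplets.
This vignette explains the models, the estimators, the numerical choices,
and the limits of what the synthetic data can demonstrate.

## The stochastic clock network

The within-cell clock is a transcription–translation negative-feedback
loop with explicit stochastic gene states, simulated exactly with the
Gillespie direct method:

* WC-1 is transcribed from a constitutively toggling locus and dimerizes
  with constitutively produced WC-2 into the activating complex WCC.
* WCC switches the *frq* locus on through a steep activation function
  (Hill coefficient 8, reflecting cooperative multimer binding); FRQ
  protein inactivates WCC catalytically, closing the negative loop.
* WCC likewise switches the *ccg-2* locus on (Hill coefficient 6); the
  CCG-2 protein is the observable, standing in for a fluorescent recorder
  driven by the *ccg-2* promoter.

All loci toggle on/off stochastically, so transcription is bursty; with
roughly 10^2 mRNA molecules per cell this bursting is the dominant noise
source and produces the cell-to-cell phase dispersion the package is built
to quantify.  The published network this emulates is not fully available,
so this topology is a documented stand-in: its structure (WCC activation,
FRQ feedback, bursting loci) follows the biology, but its rate constants
are the package's own calibration, versioned in
`inst/extdata/clock_default.yaml`.

**Calibration.**  The deterministic (mean-field) limit of the network was
tuned into a stable limit cycle, then all rate constants were scaled by a
common factor — an exact symmetry of both the rate equations and the
stochastic process — to set the period.  Molecule counts were then scaled
(transcription rates and Hill constants up, bimolecular rates down, another
exact mean-field symmetry) so that time-averaged *ccg-2* mRNA is ~127
molecules/cell and CCG-2 protein ~252.  Gene-switching rates were chosen
fast enough (~0.6–3 /h) that switching delays do not stretch the stochastic
period away from the deterministic one, while still slow enough to give
strong bursts.  On the default analysis grid the ensemble-averaged
periodogram peaks at 21.25 h, the observable grid period closest to 21 h.
The calibration was fixed once, against these anchors only.

**Seeding.**  Every ensemble cell draws from its own counter-derived
random stream (`splitmix64`-seeded `xoshiro256++`), so ensembles are
bit-reproducible and independent of evaluation order, and cell *i* of a
larger ensemble equals cell *i* of a smaller one.

## Synthetic experiments and the detection model

`synthesize_experiment()` composes the full measurement chain:

    raw(t) = E(t) · B(t) · (gain · signal(t) + background) + ε(t)

* `E(t)`: multiplicative excitation fluctuations shared by the whole
  field, i.i.d. log-normal with unit mean; the same factor multiplies the
  recorded Rhodamine-B reference series, so reference normalization
  cancels it exactly.  The magnitude is a free configuration value
  (default CV 0.05) — no published estimate exists to pin it.
* `B(t) = exp(−bleach_rate · t)`: photobleaching.  The default rate
  (8×10⁻⁴ /h) keeps total decay below 20% over 240 h, a "slight negative
  trend".
* `ε(t) ~ N(0, σ²(I))` with `σ²(I) = c0 + c1 I + c2 I²` evaluated at the
  noise-free intensity: offset, shot-like, and multiplicative detector
  noise.  Bead controls (constant-signal particles run through the same
  chain) identify the three coefficients by regressing per-bead variance
  on per-bead mean intensity; at least three distinct intensity levels are
  required for the quadratic to be identifiable.  The per-bead variance is
  corrected by the exact deflation factor `1 − 2 w₀ + Σ w²` that
  subtracting a moving average imposes on white noise.

Droplet occupancy is truncated-Poisson on [1, `max_a`] — the standard
flow-focusing encapsulation model; empty droplets are unobserved.

What the generator does *not* emulate: cell division/fusion (the
experimental media suppress both), drift or mistracking artifacts beyond
simple spikes, spatial structure within droplets, and day-scale drifts in
detector gain.  Tests passing on these synthetics therefore validate the
estimators under the stated noise model, not the imaging stack itself.

## Preprocessing

Fluorescence is divided frame-wise by the shared reference series, then
detrended by subtracting a centered 24-h moving average (48 frames at
0.5 h).  For an even window the package uses the symmetric 49-tap kernel
with half weights at the ends, `(½, 1, …, 1, ½)/48`: it is the only
sampled kernel of 24-h span that is exactly symmetric, reproduces linear
trends exactly, and has the real transfer function
`H(f) = sin(48πf)·cos(πf) / (48·sin(πf))` (frequency in cycles/frame), so
the detrending response `1 − H(f)` is a pure real gain.  Edge frames where
the window does not fit are dropped rather than shrunk, keeping the
operator's weights uniform — this is what makes the detector-noise
propagation below exact.  Whether the original analyses used a centered or
trailing average is not documented; centered was chosen and is pinned by
transfer-function tests.

The spectral window defaults to frames [60, 230), i.e. L = 170 samples
covering 85 h.  On this grid the observable frequencies are l/85 h⁻¹; the
l = 4 line (0.0471 h⁻¹) is the "21 h" period, printed as 21.25 h.  Period
is reported as 1/f at the argmax of the normalized periodogram; amplitude
as the square root of the maximal normalized power; exact ties break
toward the lower frequency and are flagged.

**Hilbert phase.**  The analytic signal is computed on the full detrended
series (pushing edge effects outside the window), its argument unwrapped
by minimizing each increment modulo 2π, and the phase reported as
`(φ(t1) − φ(t0))/2π` cycles over the window — the number of cycles a cell
completes in a fixed span of reference time (about 4 for a 21-h oscillator
over 85 h).  Note that the analytic-signal argument gives *equal* (not
negated) cycle counts for a time-reversed series over a symmetric window;
the reversed oscillation still completes the same number of cycles.

## Partitioning periodogram variance

Detector noise reaches the periodogram through a known linear operator Q
(reference-normalize → subtract moving average → window → DFT).  The
package computes, exactly, the per-frequency gain `g_l = Σ_u |(F Q)_{l,u}|²`
of this operator on white noise; detector noise of per-frame variance
σ²_det then biases the expected bare periodogram by `v_l = σ²_det g_l` and
contributes per-cell periodogram variance

    (σ_l^e)² = 2 v_l |S_l|² + v_l²,

the signal–noise cross term plus the noise–noise term, with `|S_l|²`
estimated by the bias-corrected sample-mean periodogram (population means
replaced by sample means as a first approximation).  The stochastic
component is obtained by subtraction, `(σ_l^c)² = (σ_l)² − (σ_l^e)²`,
floored at zero with a flag where sampling noise makes the difference
negative.  The route is validated against a brute-force Monte Carlo oracle
(simulate noise, detrend, transform, take variances) and by recovering
injected detector shares of 1%, 5% and 20% on synthetic experiments within
bootstrap confidence intervals.  Total variance is bootstrapped over cells
(default 5000 resamples).

The harmonic analysis of variance regresses a detrended series on sine and
cosine pairs at each model frequency (2 df per frequency, orthogonal on
the observable grid), scales all sums of squares to total 1, and reports
`F = EMS_freq / EMS_error` with error df = n − 2m — no mean-correction
term, because detrending already centers the series.

## Ensemble fitting

`metropolis_fit()` runs random-walk Metropolis over selected clock
parameters: log-normal proposals on one randomly chosen free parameter per
step, acceptance probability `min(1, exp(−Δχ²/(2T)))` with T = 1 by
default, and

    χ² = Σ_l (P̄_obs(f_l) − P̄_model(f_l; Θ))² / σ_l².

The model periodogram is itself a Monte Carlo average over `n_sim`
simulated cells, so the default denominator is the variance of the
observed mean *plus* the Monte Carlo variance of the model mean
(`var/N_c + var/n_sim`); omitting the second term freezes the chain when
`n_sim ≪ N_c`.  The noisy χ² surface is handled with common random
numbers — one fixed simulation seed per chain segment, refreshed every
`refresh_every` steps — a pragmatic, documented deviation from exact
pseudo-marginal MCMC.  Desk-scale defaults (`n_sim = 128`,
`n_steps = 2000`) replace the GPU-scale originals (1024 trajectories,
>165,000 proposals); the test suite runs a further-reduced recovery study
(two free parameters, 200 steps, `n_sim = 40`, 192-h trajectories) whose
posterior medians land within 25% of the generating values.  Degrees of
freedom are reported as the number of included frequencies minus a
configurable constraint count, since the exact published bookkeeping is
not derivable.

Because the periodogram discards phase, the per-cell phase distribution is
an independent check of a fitted model: both samples are mean-centered and
compared with a two-sample Kolmogorov–Smirnov test.

## Coupling models

**Quorum sensing (mean field).**  Each cell runs the deterministic mirror
of the clock (mean-field rate equations; gene states become occupancy
fractions).  A clock-controlled product drives synthesis of an
intracellular signal S_j that exchanges with one perfectly mixed external
pool S^e:

    dS_j/dt = k_S1 · s_scale · [CCG]_j − η (S_j − S^e) − D9 S_j
    dS^e/dt = η_ext Σ_j (S_j − S^e) − D10 S^e

with η = 100, η_ext = 1.44 (the cell-to-droplet volume ratio folded in),
D9 = 26, D10 = 4.  The signal feeds back by sequestering the white-collar
proteins: WCC formation proceeds at
`k_bind · (WC1 − C2·S)₊ · (WC2 − C4·S)₊`, the parenthetical terms clipped
at zero (C4 = 0.8; C2 defaults to the same value, and D2 = 10⁻⁴ is carried
as a basal decay of the signal-producing protein).  The exact algebraic
form of these interaction terms in the source model is not fully published;
this reconstruction is the package's own and is flagged as such.  The
production normalization `s_scale` maps molecule counts onto the signal
scale so that sequestration modulates, rather than extinguishes, WCC
formation.  Integration uses `deSolve::lsoda` with relative tolerance
1e-6; states are clipped at zero inside the right-hand side.

Initial desynchronization matters: amplitude jitter alone barely perturbs
an oscillator's phase (trajectories relax back to the limit cycle), so
`quorum_init()` starts each cell from the uncoupled limit cycle at a
random time offset (`phase_jitter_h`), plus optional log-normal amplitude
jitter.  With coupling on, within-droplet dispersion of the clock output
falls by more than half over 240 h and the model ICC surface rises along
the time axis for every droplet size ≥ 2; with coupling off it shows no
systematic rise.

**Kuramoto control.**  Each cell is a phase oscillator,
`dφ_j/dt = ω_j + (K_c/a) Σ_k sin(φ_k − φ_j)` within its droplet, plus
optional white phase noise, integrated by Euler–Maruyama at a 0.05-h
internal step.  Defaults: 21-h mean period, ω SD 0.03 rad/h, K_c
0.2 rad/h.  Two oscillators detuned by Δω lock at the offset
`arcsin(Δω/K_c)`, a closed-form anchor used in the tests.

## Synchronization measures

The central measure is the intraclass correlation from the balanced
one-way variance-components model, computed per droplet-size stratum and
per single time point: `SS_B = a Σ_i (X̄_i − X̄)²`,
`SS_W = Σ_ij (X_ij − X̄_i)²`, `EMS_B = SS_B/(n−1)`,
`EMS_W = SS_W/(n(a−1))`, and

    ICC = (EMS_B − EMS_W) / (EMS_B + (a−1) EMS_W),

the estimator obtained by equating mean squares to their expectations
`σ²(1 + (a−1)ρ)` and `σ²(1−ρ)`.  Strata are exact droplet sizes (the
estimator is balanced-only); negative values are reported as computed —
the null control relies on values scattering around zero, and the
estimator's floor is −1/(a−1).  With few replicate droplets the ratio
estimator is noticeably negatively biased, which is why the null checks in
the tests are phrased as "no systematic rise over time" rather than a
tight band around zero.

The strangers control replaces, at every time point, each cell in every
multi-cell droplet by a randomly drawn singleton value (with replacement)
and recomputes the surface, 20 times by default: any within-droplet
communication signal is destroyed while every marginal distribution is
preserved.  On coupled synthetic data the replicate-mean strangers surface
has mean |ICC| below 0.05 while the true surface's late-time two-cell
stratum exceeds 0.3.

Companion measures: the Garcia-Ojalvo ratio (variance over time of the
within-droplet mean trajectory over the mean per-cell variance; 1 for
identical cells, ~1/a for independent ones, 0 for exact antiphase
cancellation) and the Kuramoto order parameter (time-averaged modulus of
the droplet mean phasor, ~√π/(2√a) under independence).  One ICC surface
is compared with another by least squares with a common slope and
size-specific intercepts, `y = m x + b_a`, reporting R² and per-size mean
ICC with twice its standard error.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which each statistical check is decisive: 256 singleton
cells for the spectral calibration (the original experiments observed
868); 200 cells for the detector-share recovery; 300 droplets for the
strangers control; 6000 Monte Carlo replicates for the noise-propagation
oracle; 10⁴ independent stationary draws for the birth–death moment
checks (consecutive frames of one trace are autocorrelated and would need
far more samples for the same precision).  Floating-point output is
written with 17 significant digits so tables round-trip losslessly.

## Known limitations

* The clock topology and rates are a calibrated stand-in, not the
  published fitted ensemble.  It reproduces the anchor statistics (21-h
  spectral peak, ~10² mRNA/cell, negative phase–period and
  phase–amplitude correlations) but not every published feature: in
  particular its period–amplitude correlation across cells is weakly
  negative rather than positive.
* The quorum model is deterministic; it predicts synchronization of the
  mean field but not the interplay of coupling with molecular noise.
* The mean-field assumption (instantaneous, uniform mixing in a droplet)
  excludes contact- or distance-dependent communication.
* The detection model is Gaussian with intensity-dependent variance;
  non-Gaussian tails from tracking errors are handled only by the QC
  spike filter.
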