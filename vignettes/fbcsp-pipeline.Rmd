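---
title: "Decoding motor imagery with a filter bank, CSP and swarm feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery with a filter bank, CSP and swarm feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbcsp)
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, what the
synthetic data generator emulates, and the numerical decisions taken where
the design was genuinely open.

## The decoding model

A trial alternates 3 s of rest with 5 s of hand motor imagery (MI), cued on
screen, recorded from 11 electrodes (C3, C4, Cz, T3, T4, F3, F4, Fz, P3,
P4, Pz) at 256 Hz. Motor imagery suppresses band-limited sensorimotor power
(event-related desynchronization, ERD) in the mu and beta bands, so the
discriminative signal is a *variance* contrast between classes, localized
in space (a spatial projection) and in frequency (a subband).

The chain makes that contrast explicit:

* **Windows.** One 1-s REST window (1.5–2.5 s) and one 1-s MI window
  (3.5–4.5 s) per trial — intervals where the two classes separate best
  once cue reactions settle. Windows are half-open `[start, end)` in
  samples, 0-based seconds from trial onset.
* **Filter bank.** Six band-passes of 4 Hz width covering 8–32 Hz, plus a
  60 Hz band-stop applied first. All filters are even-order (30) symmetric
  FIRs, so the phase is exactly linear and the group delay is a constant
  15 samples — both classes are delayed identically and variance features
  are unaffected.
* **CSP.** Per subband, class covariances S1 (MI) and S2 (REST) are
  averages of per-window covariances, each normalized by its trace so
  window-to-window amplitude drifts cancel. The spatial filters solve
  `S1 w = λ (S1 + S2) w`, computed by whitening `S1 + S2`; eigenvalues lie
  in [0, 1] and measure the MI share of projected variance. All 11 filters
  per band are kept — 66 features — leaving the choice of useful
  projections to the selection stage rather than the conventional fixed
  first-and-last-m truncation.
* **Features.** `f_(b,j) = log(var_(b,j) / Σ_k var_(b,k))`: the log of each
  projection's share of within-band variance. The share is invariant to
  global amplitude scaling and to filter sign; the log symmetrizes the
  heavily skewed ratio distribution. Whether to log-transform is not
  determined by the variance-optimality argument itself, so `log = FALSE`
  exposes raw ratios; log is the default, following the standard CSP
  feature construction.
* **Swarm selection.** Particles move in `[0,1]^66`; coordinates ≥ 0.5
  select a feature. Masks are closed under the pairing rule (filter j pairs
  with filter 12 − j of its band: CSP filters are informative in
  eigenvalue-complementary pairs). Fitness is `2·err + nselec/66`, with
  `err` the resubstitution error of an LDA on the masked features: the
  doubled weight makes error reduction dominate subset shrinkage. The run
  stops at zero training error or after 50 generations of 50 particles.
* **LDA.** Equal priors (the design is exactly balanced: one window of each
  class per trial) and pooled covariance; `w ∝ Σ⁻¹(μ_MI − μ_REST)` with the
  boundary at the midpoint of the projected means. A decision score of
  exactly 0 resolves to REST — the conservative choice when the positive
  class drives an orthosis.
* **Validation.** 10×10-fold stratified cross-validation. The fold unit is
  the *trial*, so a trial's REST and MI windows can never straddle the
  split (sibling-window leakage); because every trial carries one window of
  each class, trial-level folds are automatically class-stratified. Spatial
  filters, mask and LDA are refit per fold from the training partition
  only. The broadband CSP baseline (8–32 Hz, first and last m = 2 columns,
  4 features) consumes identical fold assignments, making the Mann–Whitney
  comparison paired by fold.
* **Online protocol.** Six consecutive windows `[0,1) … [5,6)` s per trial
  — three REST, then the first three seconds of the MI interval, chosen for
  contiguity with the rest windows. Each window passes through the frozen
  offline parameters via the *same* filtering and feature code path, so
  replaying the offline windows online reproduces offline predictions
  bit-for-bit. The orthosis triggers iff ≥ 2 of the 3 MI windows are
  classified MI; REST windows count toward online %CA but never gate the
  trigger. Per run (20 trials), the trigger rate %CT maps to a five-step
  feedback band (≥ 90 → happiest face, < 60 → most serious). Per-window
  processing time is recorded but never asserted against — it is
  hardware-dependent.

## Chance statistics

With finitely many evaluated decisions, a random classifier's observed
accuracy fluctuates above 50%. The practical level of chance is the upper
confidence bound

\[ 100 \left( \tilde p + z_{1-\alpha/2} \sqrt{\tilde p (1 - \tilde p) / (n+4)} \right),
\qquad \tilde p = \frac{k + 2}{n + 4}, \]

with `k = n/2` expected correct decisions. At the study scale — 120 trials
per class, both classes pooled, `n = 240`, α = 0.05 — the bound evaluates
to 56.27%; only accuracies above it are treated as better than chance. The
quantile comes from `qnorm`, not a hard-coded 1.96, so any α works. Two
readings in the source material needed resolving: "significance level of
0.5" is taken as a typo for α = 0.05 (consistent with every other use),
and `n` is the pooled total (240), which is the reading that reproduces
the published bound.

## The synthetic generator

`generate_session()` emulates the paradigm's statistics, not its
physiology. Each channel is the sum of 1/f-shaped Gaussian noise (the EEG
background, default SD 10 µV, exponent 1), band-limited Gaussian
oscillators (mu 8–12 Hz SD 5 µV and beta 16–24 Hz SD 2.5 µV on all
channels), and a 60 Hz line sinusoid (default 1 µV) so the notch is
exercised. The ERD is implemented by splitting each target channel's
composite signal into its target-band component (brick-wall FFT split over
the whole trial) and scaling that component by `√(1 − depth)` from
`rest_duration + onset_latency` onwards (0.1 s raised-cosine ramp ending at
the onset, default latency 0.5 s — effects stabilize shortly after the
cue). In-band MI power is therefore `(1 − depth)` times in-band rest power
*by construction*, verified in the tests against an independent
periodogram oracle. Defaults place the effect on C3 and C4 at 8–12 Hz with
depth 0.5; no quantitative ERD magnitude is available for the original
cohort, so depth is a free simulation parameter, not a calibration.

What the generator does **not** emulate: ocular/muscular artefacts, volume
conduction (channels are independent, so real spatial correlation
structure is absent), nonstationarity across trials, and subject
idiosyncrasies. Passing tests therefore demonstrate that the chain
recovers a known variance contrast from realistic-amplitude noise — not
that it attains any particular accuracy on human EEG.

## Numerical choices

* **Filter design.** The stated constraints are only "FIR, order 30,
  linear phase". Window-based designs at 31 taps cannot keep a 4-Hz-wide
  passband flat while attenuating a tone 10 Hz outside it, and the
  available equiripple routine fails to converge on several of these
  bands, so the package designs filters by weighted least squares of the
  type-I amplitude response on a 2048-point grid with don't-care
  transitions (8 Hz each side; stopband weight 2). Coefficients are
  exactly symmetric by construction. The 18 Hz transition for the notch
  trades depth (gain 0.003 at 60 Hz) against passband flatness below
  32 Hz, where all the signal lives.
* **Band list.** The six listed edge-sharing bands (8–12 … 28–32) are
  used verbatim; the alternative "1 Hz overlap" phrasing in the source
  description is internally inconsistent with that list, so the explicit
  edges win and `bands` remains overridable.
* **Transients.** The first 31 filtered samples of each window are kept:
  variance features are robust to the onset transient, trimming is not
  part of the described procedure, and `trim_transient = TRUE` exists for
  sensitivity analysis.
* **Covariances.** Per-window trace normalization before averaging
  (the Ramoser convention). `S1 + S2` gets a relative ridge of 1e-8 times
  its mean diagonal only when its condition number exceeds 1e10 (reported
  via a message).
* **Swarm details.** The inertia schedule descends linearly 1 → 0
  (exploration → exploitation); the self-contradictory "descends from 0 to
  1" phrasing is resolved in the standard direction, with both endpoints
  configurable. Velocities are signed with magnitude clamped at 1 (a
  literal "minimum speed 0" would break the update equation). `r1`, `r2`
  are drawn per particle *and* per dimension (the more common variant;
  per-particle draws would correlate all coordinates of a move).
  Positions initialize uniform, velocities uniform(−1,1)·0.1. Fitness err
  uses resubstitution on the training set, as described — an internal
  holdout can be emulated by passing a separate `eval` table to
  `pso_fitness()`. An all-below-threshold position is repaired by forcing
  its largest coordinate on (then pair-closing), so masks are never empty.
  Fitness ties keep the first-found best, stable under particle order.
* **Zero-error stop.** Stopping immediately at zero training error means
  that on small, easily-overfit tables the swarm halts in generation 1
  with a large random mask — the size penalty never gets to act. This is
  the faithful reading of the stop criterion; feature-count shrinkage is
  observable whenever training error cannot reach zero (e.g. 400-row
  noise tables, where the median selected count falls below 33).
* **LDA singularities.** When masked features outnumber training windows
  the pooled covariance is singular; a relative diagonal ridge (1e-6,
  escalated ×100 until the Cholesky succeeds) restores solvability and is
  reported in the fitted object.
* **Seeding.** Every stochastic operation (generator, folds, swarm) is
  driven by explicit integer seeds; repetition r of a cross-validation run
  derives its folds from `base_seed + r`, which is what makes baseline and
  pipeline folds identical and the whole run reproducible.

## Problem sizes

The shipped tests exercise the study-scale configuration — 60 trials per
class, 10×10-fold cross-validation, 50×50 swarm — for the signal-detection
checks (an ERD of depth 0.7 is detected above the 56.2% chance bound;
five null sessions stay below it), and smaller configurations (12–20
trials, 5 folds, 15×10 swarms) for shape, invariance and property checks
where the full scale adds nothing.

## Known limitations

* The chain is strictly two-class and assumes the balanced
  one-window-per-class trial design in its equal-prior LDA.
* Resubstitution error inside the fitness overfits by construction;
  cross-validated accuracy is accordingly lower than the swarm's internal
  error estimate, and on synthetic sessions the 4-feature broadband CSP
  baseline is often competitive.
* The generator's channel independence makes CSP's job easier than real
  volume-conducted EEG; absolute accuracies on synthetic sessions should
  not be read as expected human performance.
* EEG interchange is a plain-text archive (wide CSV + JSON sidecar);
  amplifier-native formats are out of scope.
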