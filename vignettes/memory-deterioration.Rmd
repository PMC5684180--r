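---
title: "Modeling associative-memory deterioration under focal axonal swellings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling associative-memory deterioration under focal axonal swellings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasnet)
```

## The model

`fasnet` simulates how focal axonal swellings (FAS) — the localized axonal
enlargements that follow traumatic brain injury and accompany many
neurodegenerative diseases — degrade recall in an associative-memory
network. The substrate is a multi-state Hopfield network: N neurons, each
in one of q discrete activity levels (q = 2 reproduces the classical binary
network; q = 8 encodes shades of grey so a neuron can represent an image
pixel). Levels are embedded affinely in [-1, 1] (`level_values()`).

**Training.** `hebbian_train()` uses the outer-product rule
w_ij = sum_mu v_i v_j / (N vbar2), symmetric with zero diagonal, where
vbar2 is the mean squared embedded activity of the training set. The
activity normalisation makes the local field at a stored pattern reproduce
the pattern for any q; at q = 2 it equals 1 and the rule is the textbook
one, with the well-known storage capacity of about 0.14 N random patterns.
For *correlated* families (faces share global structure; our stand-in
families share ~65% of their positions) the plain rule fails outright: the
shared template dominates every coupling and the stored patterns stop being
fixed points — in our tests recall from the stored pattern itself collapsed
to an overlap of about 0.24. `hebbian_train(center = TRUE)` therefore
trains on *deviations*: each neuron's mean training activity vbar_i is
subtracted, the couplings are the projection (pseudo-inverse) operator onto
the span of the deviation patterns, and the mean is re-added as a bias in
the recall field, h_i = vbar_i + sum_j w_ij (v_j - vbar_j). We first tried
the simpler covariance scaling and found that with few memories the spread
of deviation norms leaves the weakest pattern with a field gain below 1, so
that whole memory decays deterministically; the projection operator gives
every stored pattern unit gain exactly (the Gram matrix is rank M-1 because
centered deviations sum to zero, hence a pseudo-inverse). With this rule
all members of a 3-pattern, 65%-overlap family are exact fixed points.

**Recall dynamics.** Asynchronous sweeps in a fresh random permutation per
sweep: each neuron computes its field from the current (partially updated)
effective outputs, adds a Gaussian perturbation of standard deviation
`noise_sigma` (a Brownian-type proxy for physiological fluctuations),
clamps to [-1, 1], and adopts the nearest activity level (exact ties go to
the lower level). Convergence is one change-free sweep when
`noise_sigma = 0`, two consecutive change-free sweeps otherwise;
`max_sweeps` defaults to 100. The sweep loop is implemented in C++ but
draws from R's RNG, so `set.seed()` makes every trajectory bit-reproducible.

**Energy.** The usual Lyapunov function is available via `energy()`. Note
that the nearest-level update provably never increases it only at q = 2,
where it reduces to the sign rule; for q > 2 a quantized step need not
minimise the local energy, so monotonicity is asserted (and holds) only for
the binary configuration.

## The injury model

Each injured neuron carries one swelling regime: unimpaired transmission,
filtering, reflection, or blockage. A pie-chart (`fas_distribution`) gives
the regime mixture among injured neurons; the injury level p is the
fraction of neurons injured at all. `sample_assignment()` injures exactly
`round(p N)` neurons (exact-count, to keep sweep variance down) and draws
each regime independently from the pie-chart.

`fas_transfer()` maps a pre-injury firing rate in [0, 1] to its post-injury
value: transmission is the identity, reflection halves the rate (a
reflected spike annihilates an oncoming one), blockage zeroes it, and
filtering applies a piecewise-linear soft cap — rates below the knee
`theta` (default 0.5) pass, rates above are compressed with slope `kappa`
(default 0.25) — capturing the preferential loss of high rates to spike
pile-up. A stochastic variant (cap applied with probability equal to the
rate) is available; the deterministic map is the default and the one used
by the dynamics. Every regime is monotone, never increases a rate, and
maps 0 to 0.

Inside the network the transfer acts on the *magnitude* of the transmitted
bipolar signal, preserving its sign (`effective_output()`). We chose this
embedding after rejecting the alternative of round-tripping through the
rate scale r = (v+1)/2: that version turns attenuation into a negative DC
bias (an active filtered neuron emits +0.25 while a silent one still emits
-1), which in binary networks made filtering *more* destructive than
blockage and inverted the deterioration ordering across pie-charts. With
the sign-preserving embedding the severity ordering is transmission >
filtering > reflection > blockage, as the biophysics requires.

Blockage is special in two ways, both following from "no signal passes the
swelling": the neuron's effective output is 0 — absence of signal,
equivalent to deleting its outgoing couplings, not inhibition — and since
the effective firing rate *is* the state of a Hopfield node, the neuron is
silenced (forced to level 0) and frozen for the whole trajectory. Silenced
blockage is what makes a blockage-heavy pie-chart the most damaging: every
blocked neuron mismatches the stored pattern wherever that pattern is
active. It also makes blockage-only injury equivalent to the classical
binary lesion model (random neuron deletion), which the test suite checks
against an independent weight-surgery oracle.

## Recognition score and sweeps

A recall trial (`run_trial()`) corrupts the cued memory at exactly
`round(noise N)` positions (`add_cue_noise()`; 20% cue noise means exactly
80% overlap), runs the dynamics under a given injury assignment, and
classifies the final state (`classify_state()`): significant iff the best
overlap reaches `theta = 0.75` and beats the runner-up by `delta = 0.10`;
significant-and-cued is *correct*, significant-and-other is *confused*,
anything else *none*. The trial score is the final overlap with the cued
memory when correct, 0 when none, minus the overlap with the wrong
attractor when confused — confusion is penalised more than
non-convergence. Cell scores are normalized by the healthy (p = 0) score
at the same noise level and clamped to [0, 1] (`aggregate_sweep()`), and
`fit_deterioration()` fits R(p) = A - B e^p by ordinary least squares on
the regressor e^p. This score is our own reconstruction — the published
study defines its score in supplementary material we treat as unavailable —
built to satisfy the documented properties (both error types enter,
normalization makes A of order 1, confusion costs more than
non-convergence). See "Known limitations" for its consequences.

`run_sweep()` crosses noise and injury grids with a fresh injury assignment
per replicate and per-cell seeds derived deterministically from one master
seed, so any cell can be recomputed independently and the whole sweep is
bit-reproducible.

## Calibrations and study conditions

Two quantities are calibrated rather than fixed a priori, both against the
*healthy* network, before any injury result is examined:

* **Dynamic noise `noise_sigma`** (`calibrate_noise_sigma()`): the
  amplitude at which the healthy network recalls noisy cues correctly ~90%
  of the time — the healthy operating point of the face task. Because the
  correct-rate response to the amplitude is steep (perturbations accumulate
  over the sweep budget and recall collapses once they reach the
  inter-level spacing), the procedure pilots a coarse log-spaced grid,
  bisects the target crossing, pools all pilots through a decreasing
  isotonic fit, and interpolates the crossing on the log scale. Useful
  amplitudes are small (~0.002–0.02); the generic default
  `noise_sigma = 0.1` in the low-level functions is suitable for
  far-below-capacity binary networks only.
* **Cue noise of the deterioration sweeps**: fixed at 0.10. At the
  capacity limit the recall basins are shallow; 10% corruption is the
  hardest denoising task the intact 900-neuron network handles at ~90%
  correct (`calibrate_cue_noise()` automates this choice).

The canned protocols (`face_recognition_experiment()`,
`deterioration_experiment()`) wire these together. Default problem sizes
are the study conditions: the face stand-in uses N = 1,080, q = 8, M = 3
correlated memories at 65% overlap with 102 measurement trials; the
random-pattern task uses N = 900, q = 2, M = 126 = 0.14 N, injury 0–50% in
steps of 0.05 with 3 replicates of a 25-memory subsample per point. The
test suite runs a reduced tier (N = 400, M = 56) of the deterioration
protocol to keep its runtime in minutes; the acceptance script runs the
full 900-neuron protocol.

## What the generators emulate — and what they do not

`generate_random_memories()` draws patterns with an exact active count per
pattern; its pairwise overlap expectation is (1-a)^2 + a^2/(q-1)
(`expected_overlap_random()`). Note that for q = 2 this is at least 0.5 —
a 20–25% overlap, as quoted for multi-state random patterns, is reachable
only with more activity states (e.g. a = 0.6, q = 8). The deterioration
protocol nevertheless uses the dense binary ensemble (a = 0.5, q = 2),
because that is the ensemble for which M = 0.14 N is the capacity limit.

`generate_correlated_family()` copies a template at a *shared* position set
of fraction c and randomizes the rest i.i.d. over the q levels, so the
expected pairwise overlap is c + (1-c)/q and c can be solved from the
target. This reproduces the overlap statistics of a face set, not its
spatial structure: real faces have smooth pixel correlations, compression
along feature dimensions, and registration error, none of which are
modelled. Passing tests on these families show the *network and injury
machinery* behave correctly at face-task overlap levels; they do not show
performance on real images.

## Numerical choices

* Level quantization uses `ceil(x - 0.5)` so exact midpoints resolve to the
  lower level — deterministic and testable.
* Fields are clamped to [-1, 1] before quantization, bounding the effect
  of any single Gaussian kick.
* Pie-chart probabilities must sum to 1 within 1e-9 in the constructor; the
  file loader normalizes instead, and warns when blockage reaches 0.5
  (experimentally derived mixtures keep blockage under half).
* Seeds are mandatory for every generator; per-cell seeds are derived by a
  fixed integer recurrence kept below 2^31.
* Degenerate inputs error early: empty memory sets, all-midpoint training
  sets, noise levels outside [0, 1], injury levels outside [0, 1],
  `max_sweeps < 1`, singular deterioration designs (a single distinct p).

## Known limitations

* **Absolute deterioration rates.** With the reconstructed score, injury
  at the capacity limit is punishing: a pie-chart with 40% blockage at
  p = 0.5 silences 20% of neurons, the effective load of the survivors
  rises above the storage transition, and the normalized score falls to
  ~0.2–0.4 rather than ~0.9. Pooled fits then give B of order 1 — the
  *ordering* of B across pie-charts (more blockage, faster deterioration)
  is robust and tested, but the absolute B values published for this
  design (0.06–0.13) are not reproduced by any outcome-gated score we
  examined; they would require a score nearly insensitive to outcome
  degradation at half-injury. We report our computed coefficients as they
  are.
* The capacity check "clean recall with overlap at least 0.97 for at least
  90% of memories at M = 0.14 N" sits exactly on the storage phase
  transition (the theoretical remanent overlap at the critical load is
  about 0.967); across generator seeds the measured fraction straddles
  0.9, so that check is inherently marginal at N = 900.
* Blocked neurons are silenced and frozen; competing readings (frozen at
  their current state, or continuing to update silently) were rejected
  because they make blockage protective, contradicting both the lesion
  literature and the severity ordering.
* One swelling regime per neuron, no axon-to-axon interactions (e.g.
  squeezing of neighbours), no synaptic plasticity during recall, and no
  spiking dynamics — injuries act only through the static transfer of
  firing rates.
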