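---
title: "Conditional causality networks of beat-to-beat cardiovascular variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional causality networks of beat-to-beat cardiovascular variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short-term cardiovascular regulation couples several beat-to-beat variability
series: heart period (H, from RR intervals), mean arterial pressure (M),
arterial compliance (C) and respiration (R). Pairwise association measures
cannot tell whether, say, respiration drives pressure directly or only through
its effect on heart period, and they are blind to direction. `ctenet`
implements *conditional* (direct) causality estimation for a small network of
such series: the information flowing from a source node's past to a target
node's present, over and above the target's own past **and** the remaining
nodes. Two estimators of the same quantity are provided:

* a **model-based (MB)** estimator — conditional Granger causality from an
  extended vector autoregression with within-beat (zero-lag) effects,
  `F = ln(lambda^2 / sigma^2)`, which for jointly Gaussian data equals twice
  the conditional transfer entropy, `T = F/2`;
* a **model-free (MF)** estimator — conditional transfer entropy via
  k-nearest-neighbour (KSG-type) entropy estimates on non-uniformly embedded
  past states, which can capture nonlinear couplings the linear model cannot.

A link that is significant under MF but not under MB points to nonlinear
dynamics on that pathway; agreement of the two estimators points to linear
coupling. That contrast is the package's central analysis device.

## The extended model and zero-lag effects

Beat-indexed sampling is coarser than some physiological interactions:
respiration influences the heart period *within* the same beat, and the same
holds along the measurement sequence R -> H -> M -> C. The MB model therefore
includes lag-0 coefficients, which are identifiable only if they form a
directed acyclic graph. The package fixes the DAG to all forward edges of the
node order (R, H, M, C): `{R->H, R->M, R->C, H->M, H->C, M->C}`
(`zero_lag_dag()`). Two consequences:

* each target equation can be fit by ordinary least squares on lagged
  regressors plus the target's zero-lag DAG *parents* (the system is
  recursive, so no simultaneous-equation machinery is needed);
* when the target is upstream (e.g. R), downstream nodes enter the
  conditioning set only through their lags — conditioning on a zero-lag
  *descendant* would open collider paths and manufacture spurious
  associations.

The restricted model for link i -> j removes every term of node i (lagged and,
where present, zero-lag) from the target-j regression. Restricted and
unrestricted fits share the same sample window (rows p+1..N) and the same
residual-variance denominator (the window length), so the restricted design is
a column subset of the unrestricted one and `F >= 0` holds on every input;
`T = F/2` holds exactly by construction. The model order is selected per
subject and condition by AIC over p in 1..10 on a common window (the MF
maximum lag is also 10, keeping the two estimators' memory comparable); the
restricted model inherits the unrestricted order.

## The model-free estimator

All series are standardized to unit variance. Candidate past states are all
(node, lag) pairs with lag up to L = 10 — lag 0 included only for zero-lag DAG
parents of the target, and the target's own present never a candidate. The
embedding is built greedily: at each step every remaining candidate is scored
by its conditional mutual information with the target's present given the
states already selected (KSG estimator, k = 10 neighbours, maximum norm,
radius fixed per sample by the k-th neighbour in the full joint space, strict
range counts in the projected spaces); the best candidate is admitted only if
its CMI exceeds the 95th percentile of 100 values obtained by independently
shuffling the candidate's and target's samples, and selection stops at the
first rejection. The transfer entropy is then the CMI between the target's
present and the selected source states, given the selected target-past and
other-node states; it is exactly 0 when no source state was admitted, and
negative values (small-sample bias of the KSG estimator) are reported
unclipped.

Numerical choices: after standardization every coordinate receives seeded
uniform jitter of amplitude 1e-10, because strict-inequality neighbour counts
are ill-defined at ties; neighbour counts are exact (no approximate search);
percentiles interpolate linearly between order statistics (R's default
quantile definition).

One property of the greedy admission deserves emphasis: the admitted candidate
is the *argmax* over roughly forty candidates, while its shuffle null
describes a single pre-specified candidate. Under a global null the maximum
therefore clears the 95th percentile far more often than 5% (we measure
roughly 90% of null runs admitting at least one state). This is inherent to
the procedure, which trades selection-level strictness for sensitivity;
type-I control of a *link* is delegated entirely to the time-shift surrogate
test, which re-runs the whole selection on every surrogate (its calibration is
discussed below). The admission primitive itself is calibrated for a single
candidate, which the test suite verifies.

## Surrogate significance

Per subject and link, the observed measure is compared with its distribution
over 100 surrogate datasets; a link is significant when the observed value
exceeds the 95th percentile:

* **MB path**: every node series is replaced by an independent iAAFT
  surrogate — a permutation of the original samples (amplitude distribution
  preserved exactly) whose spectrum matches the original's — destroying all
  cross-node structure.
* **MF path**: the target series is circularly rotated by at least 20 beats,
  leaving all other series untouched; the embedding is re-selected for every
  surrogate so the null includes selection variability. This is the dominant
  computational cost of the package.

Cohort-level evidence is summarized by the significance degree `s`, the
percentage of subjects whose link passed the test, binned into none
(s < 25), low ([25, 50), reported but not treated as relevant), medium
([50, 75)) and high ([75, 100]).

A calibration caveat we document rather than hide: with an autocorrelated null
(four independent AR(2) series, N = 300), both per-subject tests reject above
their nominal 0.05 level (MB: 0.07-0.105 across independent 200-replicate
batches, pooled ~0.09; MF: 0.10 over 40 replicates).
For the MB path the surrogate ensemble is a *constrained* null — every iAAFT
surrogate shares the observed series' exact value multiset and near-exact
spectrum — and for a non-pivotal statistic like the variance ratio the
conditional tail is slightly too narrow: an independently written reference
implementation of iAAFT shows the same rate on the same data, while replacing
the surrogates by fresh model draws restores 0.05-0.06, as does a white-noise
null (~0.07). The MF time-shift null is likewise only approximately
exchangeable (a finite set of circular rotations of a non-circular process).
Practitioners should read per-subject flags as having a true size nearer 0.1
than 0.05 on strongly autocorrelated data; cohort-level conclusions
additionally pass the paired Wilcoxon/FDR stage, which is exact.

## Cohort comparison

Paired REST-vs-HUT differences of each link's subject-wise estimates are
tested two-sided with the Wilcoxon signed rank test (exact enumeration up to
n = 25 without ties, normal approximation with continuity correction beyond),
Benjamini-Hochberg corrected within the family of one estimator's 12 links,
with direction read from the median difference. `compare_networks()` is
antisymmetric by construction: swapping the conditions flips every direction
and preserves every p-value.

## The synthetic cohort

No recordings ship with the package; a seeded generator
(`default_rest_config()`, `default_hut_config()`, `generate_cohort()`) stands
in for the cohort. It emulates what the estimators need — stationary,
mildly-coupled, four-node beat dynamics — not waveform physiology:

* R is an autonomous AR(2) oscillator near 0.25 cycles/beat (respiratory
  rhythm at typical breathing/heart-rate ratios);
* H receives respiratory drive (R -> H at lags 0 and 1 — respiratory sinus
  arrhythmia) and a baroreflex input M -> H at lag 1;
* M receives the within-beat mechanical feedforward H -> M, respiratory drive
  R -> M, and a weak C -> M effect;
* C is driven within-beat by M, H and R (M -> C, H -> C, R -> C) plus a lagged
  H -> C term;
* the HUT configuration halves the vagally-mediated couplings (R -> H, H -> C)
  and raises the sympathetically-mediated ones (M -> H to 0.4 from 0.3, R -> M,
  C -> M), giving the group comparison a known answer;
* innovations are unit-variance Gaussian; 500 burn-in beats are discarded;
  stability (companion spectral radius < 1) is verified at construction, and
  coefficient magnitudes were chosen to leave a stability margin (radius 0.90
  at REST, 0.95 at HUT) so that the 10% multiplicative between-subject
  coefficient jitter rarely needs redrawing;
* the nonlinear variant replaces the linear R -> H drive by a quadratic
  coupling (standardized source squared, lag 1, coefficient 0.6) that a linear
  model cannot see — the device used to test the MB-vs-MF contrast;
* zero-lag couplings are realized by evaluating node equations in DAG order
  within each beat with innovations drawn up front, so any topological order
  yields bit-identical output.

What passing tests on this cohort do **not** show: robustness to ectopic
beats and artifacts, non-stationarity within a window, non-Gaussian
innovations, uneven beat timing, or realistic marker levels (all series are
in innovation units, not ms or mmHg). Conclusions about real recordings
require the usual preprocessing care upstream of this package.

## Preprocessing

Slow trends are removed with an order-4 Butterworth high-pass applied forward
and backward (zero phase). The conventional 0.0156 Hz cutoff for very-low-frequency trends is converted
to cycles/beat through the subject's mean beat duration (for the synthetic
cohort, 1 s/beat, giving 0.0156 cycles/beat) — the only dimensionally
consistent reading for beat-indexed series without resampling. At so low a
cutoff the filter's slowest pole has modulus ~0.96 and its transient spans
hundreds of beats, so the implementation uses steady-state initial conditions
plus odd-reflection padding sized to the impulse-response decay (to 1e-9,
capped at N-1) rather than a fixed few filter orders; with short padding, edge
transients of order 1e-2 SD leak into the window and break even DC removal.
Zero-phase filtering is idempotent on passband content evaluated away from the
edge transient zone; this is the form in which the test suite asserts it.
Before MF estimation series are additionally scaled to unit variance.

## Problem sizes used by the tests and acceptance script

All checks run on synthetic data sized to hold statistical meaning on one
core: 300-beat series (the standard short-term window), cohorts of 20
subjects, 100 surrogates for every 95th-percentile rule, 200 replicates for
the MB calibration experiment, long-sample oracles at N = 10^5..10^6 for
regression identities and N = 10^4 for the Gaussian closed-form CMI check.
The MF surrogate path re-selects the embedding per surrogate; inside
calibration and cohort-contrast experiments the admission shuffles are reduced
to Ns = 15-40 (the admission threshold is then the 95th percentile of those
shuffles), the cohort-contrast significance uses 40 outer surrogates, and the
MF calibration uses far fewer replicates than the MB one.
These are the package's documented desk-scale settings; the constants sit at
the top of the relevant scripts for full-scale runs.

## Known limitations

* The MB iAAFT per-subject test is mildly anticonservative on strongly
  autocorrelated nulls (see above).
* KSG transfer entropy underestimates strong dependencies at N = 300 (the MF
  estimate of the strongest synthetic link sits ~0.07 nats below the MB one;
  the gap closes by N = 3000). MB and MF values should be compared as
  profiles across links, not nat-for-nat.
* The greedy embedding admission is liberal under the null by design;
  per-link inference must always go through the surrogate stage.
* Zero-lag effects are identified only up to the assumed DAG; reversing a
  zero-lag edge is observationally equivalent in-sample and must be justified
  physiologically, not statistically.
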