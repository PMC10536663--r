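---
title: "Spectral gait quality: model, parameters, and design choices"
author: "gaitspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral gait quality: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitspec)
```

## The measurement model

A wrist accelerometer reports triaxial acceleration `(x, y, z)` in g at
a nominal 25 Hz with microsecond timestamps. The device frame is
arbitrary and moves with the arm, so all analysis runs on the
acceleration magnitude `mag = sqrt(x^2 + y^2 + z^2)`, which is exactly
invariant under device rotation. Walking is quasi-periodic: the
magnitude of a healthy walk concentrates spectral power at the stepping
frequency (around 1.8 Hz) and its harmonics, riding on a large constant
gravity component.

For a walk of `N` samples at constant step `delta = 1/fs` the package
computes the unnormalized DFT (`stats::fft`), attaches the frequency
axis `s_k = k / (N * delta)`, and restricts attention to `k <= N/2`:
beyond the Nyquist index the discrete transform no longer approximates
the continuous one. Within an analysis band the squared amplitudes are
normalized to a probability distribution
`rho_k = |f(s_k)|^2 / P`, `P = sum |f(s_k)|^2`, from which the three
per-walk indices follow:

* `mu_s = sum s_k rho_k` (Hz) — the power-weighted mean frequency;
* `sigma_s^2 = sum s_k^2 rho_k - mu_s^2` (Hz²);
* `S = -sum rho_k ln rho_k` — the spectral entropy, in nats.

**Why the normalized weights.** The index definitions can be written
with raw squared amplitudes `|f|^2` as weights. Under the model's own
assumption that total band power is constant over a monitoring
campaign, raw and normalized weighting differ only by the constant `P`;
we use `rho` throughout so that `mu_s` is a true frequency in Hz,
`S` matches its own definition (whose weights are explicitly
normalized), and indices are comparable across walks whose realized `P`
fluctuates with sensor noise. A single shared implementation also backs
the HAR `pentropy` feature, so the two cannot drift apart.

**Degradation signature.** When gait degrades, the dominant peak loses
intensity and new lower-frequency modes emerge at (approximately)
constant total power. Consequently `mu_s` falls (mass moves to lower
`s_k`), `S` rises (mass spreads from a near-one-hot distribution), and
`sigma_s^2` moves only mildly, because its sensitivity carries the
factor `(s_k + s_k')/2 - mu_s`, which is small when the mean lies near
the midpoint of the exchanging frequencies. The synthetic family below
reproduces all three behaviours and the test suite asserts them.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `fs_target` | 25 | Hz | device's nominal rate; all analysis assumes a uniform grid |
| `jitter_tol` | 0.02 | fraction of `delta` | below this, timestamps are snapped; above, linear interpolation |
| band `f_min`–`f_max` | 0.3–10 | Hz | gravity dominates DC; stepping harmonics live below 10 Hz |
| `drop_dc` | TRUE | — | removes the gravity line instead of mean-subtracting |
| `window_s`, `overlap_s` | 30, 0 | s | non-overlapping 30-s HAR windows (750 samples at 25 Hz) |
| `period_days` | 7 | days | initial/final period = first/last calendar week |
| `min_walks` | 10 | walks | eligibility floor for longitudinal comparison |
| `conf` (GM-ratio CI) | 0.80 | — | small groups (5–11) make higher levels vacuous |

No windowing taper or detrending is applied before the DFT: the
analysis relies on band selection to remove DC, and the indices are
ratios of in-band powers, which a taper would only blur for the long
(≥ 60 s) records the pipeline requires. Entropy uses the natural log
and is reported unnormalized by default; `normalize = TRUE` divides by
`ln(n_bins)` when bands of different widths must be compared. Absolute
entropy values are configuration-specific: they depend on band, record
length and bin count, so they are comparable within one pipeline
configuration but not across studies with unknown settings — which is
why the packaged study tables are used only through their *variation*
column and table-level aggregates, never through absolute per-walk
entropies.

## The synthetic degradation family

`simulate_walk()` generates the spectral family the method is designed
to detect: on the gravity axis,

```
z(t) = g + sum_i A_i sqrt(1 - q) sin(2 pi i f0 t + phi_i)
         + sqrt(q * sum_i A_i^2) sin(2 pi f_new t + phi)
```

with `q = beta * rho_transfer`, white noise added per axis, and a fixed
3-D rotation applied so every axis carries signal while the magnitude —
rotation-invariant — carries the tones exactly. The harmonic amplitudes
`A_i` are scaled so their mean-square power equals `p_total`; the
emerging tone at `f_new` receives exactly the power removed from the
harmonics, so realized band power is independent of `beta`
(machine-precision exact at zero noise, ~2% with noise). Defaults:
`f0 = 1.8` Hz with harmonics `(1, 0.4)` in relative amplitude (a
typical step rate and its first overtone), `f_new = 0.7` Hz,
`p_total = 0.04` g² (oscillation amplitudes of a few tenths of g,
typical at the wrist), `noise_sd = 0.05` g per axis, 120 s at 25 Hz.
Durations are multiples of 10 s so all three tones sit exactly on DFT
bins.

**Why `rho_transfer = 0.4`.** The degradation parameter `beta` in
`[0, 1]` transfers at most the fraction `rho_transfer` of band power to
the emerging mode. With the zero-noise three-atom distribution
`((1-q) p_1, (1-q) p_2, q)`, entropy is
`S(q) = H_b(q) + (1-q) H_p` (`H_b` the binary entropy, `H_p` the
entropy of the harmonic split), which *increases* in `q` only while
`q < 1/(1 + exp(H_p))` — about 0.40 for the default harmonics — and
turns over once the emerging mode itself dominates, reaching `S = 0`
again at a full one-hot transfer. A cap of 0.4 keeps
`q = beta * rho_transfer <= 0.36` strictly below the turning point, so
entropy is strictly increasing and the weighted mean strictly
decreasing over the whole `beta` grid. This matches the modeling
assumption under which the entropy-growth result is derived in the
first place: the new mode's amplitude stays below the original one
(`rho(k) > rho(k')`). The fundamental persisting through degraded gait
is also the physiologically sensible regime — a person who still walks
still steps.

**Cohorts.** `simulate_cohort()` programs linear `beta` schedules
(improving `0.45 -> 0.15`, deteriorating `0.15 -> 0.45`, stable `0.3`)
over 21 daily 60-s walks by default. The mid-point 0.3 with ±0.15 swing
produces entropy changes of roughly ±10% — larger than the per-walk
noise scatter after weekly averaging, comparable to the changes the
method targets in practice. Per-walk RNG substreams are derived from a
counter on (participant, day), so regeneration is order-independent and
bit-reproducible from one integer seed.

**What the simulator does not emulate.** Real free-living data contain
non-walking segments, variable walk durations, missing days,
orientation changes mid-walk, amplitude drift, and spectra whose
degradation involves many emerging modes; the simulator generates none
of these (a multi-frequency variant would be a configuration extension,
not a model change). Passing tests therefore validate the *index
machinery and its monotone response to the programmed spectral family*,
not the clinical performance of the indices on real patients.

## Pipeline conventions

* **Validation**: rows with non-finite values, accelerations outside
  ±4 g (sensor saturation), or non-increasing timestamps are dropped
  with counted warnings, not clipped or imputed.
* **Resampling**: uniform input passes through (timestamps snapped);
  an integer-ratio faster uniform input is decimated (every r-th
  sample, no anti-alias filter — matching plain subsampling of a 100 Hz
  training corpus to 25 Hz, at a documented aliasing risk); anything
  else is linearly interpolated. Idempotent at fixed `fs_target`.
* **Periods**: the initial/final period is the first/last 7 *calendar
  days*; all walks inside a period contribute individually (multi-walk
  days are not collapsed).
* **Signs**: improvement = negative variation, deterioration =
  positive, exactly zero = stable; stable participants enter neither
  group's magnitude statistics.
* **GM-ratio CI**: pooled-variance t interval on log absolute
  variations (df `n1 + n2 - 2`) by default; a Welch variant is provided
  because the variance assumption is not identifiable from 5-per-group
  data — both agree to well within the reporting precision on the
  packaged tables.
* **Degenerate inputs**: a band with no bins raises a band error; a
  band holding only numerical dust (a constant signal with DC dropped)
  raises a degenerate-signal error; `0 ln 0 = 0` in the entropy;
  correlations of constant axes are reported as 0 with a degeneracy
  flag on the feature row.
* **Kinetic energy**: the spectral mean-energy formula is implemented
  and flagged gravity-contaminated — in the device frame the gravity DC
  term alone drives hour-scale estimates into the 10⁹ J class, so the
  quantity is reported for completeness, not used as an index (proper
  removal needs a gyroscope).

## HAR features and the classifier contract

Each complete 30-s window yields 39 named features: per-axis and
magnitude quantiles (linear-interpolation convention), pairwise Pearson
correlations, orientation angles — roll `atan2(y, z)`, pitch
`atan2(-x, sqrt(y^2 + z^2))`, and a horizontal-plane yaw proxy
`atan2(y, x)`, since true yaw is unobservable from an accelerometer
alone — with `*g` variants on a 0.5 Hz low-pass (gravity) component and
`avg*`/`sd*` on the full-rate angle series, and spectral features on
the gait band (`pentropy`, the two largest peaks' frequencies and
normalized powers, peak count at a 5%-of-maximum prominence threshold,
and the maximum prominence). The feature registry is exposed as a
contract; the registry's 39 names are the authoritative set.

Walking windows are isolated by any classifier exposing a deterministic
`predict(features) -> label` contract. The shipped reference
implementation is a gradient-boosted-tree model tuned by stratified
K-fold cross-validation over a small grid and trained on the package's
synthetic activity fixture (walking / sleeping / sit–stand windows that
are separable by construction). It validates the training and labeling
plumbing; it makes no claim about free-living recordings, for which an
externally trained model should be plugged in. A contiguous run of at
least two consecutive walking windows constitutes a walk — 60 s, i.e.
1500 samples, is the minimum that gives the spectrum a usable bin
resolution of 1/60 Hz.

## Problem sizes in the test suite

The suite exercises full-scale single walks (120 s at 25 Hz, N = 3000)
and validates the cohort machinery on 21 participants × 21 daily 60-s
walks; the cohort-recovery property is measured over 100 seeded
replicates of that design. Classifier tests use 30 windows per class
for held-out evaluation (below that, 10-per-class training folds let
spurious splits through on the noise features — visible, and accepted,
as small-sample behaviour). These sizes were chosen as the smallest
that leave the measured properties clearly out of the noise.

## Known limitations

* Absolute entropy levels are not comparable across analysis
  configurations or devices; only within-participant changes are
  interpreted.
* Bare decimation without an anti-alias filter can fold >12.5 Hz
  content into the band; with wrist data dominated by sub-10 Hz motion
  this is minor but real.
* The eligibility rule (≥10 walks) and the 7-day periods are
  conventions, not optimized choices; both are configurable.
* The GM-ratio CI assumes log-normal-ish magnitudes within groups; at
  n = 5 per group this is untestable, which is why the interval is
  reported at 80% confidence.
* The yaw features are a proxy with no physical yaw content; they are
  retained for registry compatibility and carry noise on real devices.
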