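# gaitspec

Spectral gait-quality indices from wrist-worn accelerometer data.

## The problem

Gait degrades with age and with neuromuscular disease (Parkinson's in
particular), and changes in gait often precede falls and loss of
independence. Wrist-worn devices are comfortable enough to wear for
months of free living, but the wrist signal is noisy and the device
orientation arbitrary, so classical gait parameters (stride length,
cadence) are hard to extract. `gaitspec` implements a
longitudinal, orientation-independent alternative: Fourier analysis of
the **acceleration magnitude**

```
mag(t) = sqrt(x(t)^2 + y(t)^2 + z(t)^2)   [g]
```

A healthy walk concentrates spectral power in a narrow peak at the
stepping frequency (~1.5–2 Hz) and its harmonics. As gait degrades, the
dominant peak loses intensity and new lower-frequency modes emerge.
Over the gait band (0.3–10 Hz by default, DC excluded, truncated at the
Nyquist index) the normalized power distribution
`rho_k = |f(s_k)|^2 / P`, with `P = sum_k |f(s_k)|^2`, yields three
per-walk indices:

* **weighted mean frequency** `mu_s = sum_k s_k rho_k` — falls with
  degradation;
* **frequency variance** `sigma_s^2 = <s_k^2> - mu_s^2` — responds only
  mildly;
* **spectral entropy** `S = -sum_k rho_k ln rho_k` — 0 for a pure tone,
  `ln(n_bins)` for a flat spectrum; rises with degradation. This is the
  headline gait-quality index.

A participant's change over a monitoring campaign is summarized as the
**percentage entropy variation** between the mean entropy of the first
and last weeks: negative = improvement, positive = deterioration.
Cohort-level statistics compare the magnitudes of deterioration and
improvement through a confidence interval for the ratio of their
geometric means (t interval on log absolute variations, endpoints
exponentiated).

The package also ships human-activity-recognition (HAR) feature
extraction over non-overlapping 30-s windows with a pluggable
walking/sleeping/sit–stand classifier (gradient-boosted trees on a
synthetic fixture; any externally trained model satisfying the
`predict` contract plugs in), so walks can be isolated from free-living
recordings, plus a synthetic walk simulator implementing a
power-conserving spectral degradation model used as ground truth
throughout the test suite.

## Worked example

```r
library(gaitspec)
library(dplyr)

# One synthetic walk with mild degradation (beta = 0.2), 120 s at 25 Hz
walk <- simulate_walk(degradation_config(beta = 0.2, seed = 42))
walk_indices(magnitude(walk))
#> # A tibble: 1 × 5
#>      mu sigma2 entropy   power n_bins
#>   <dbl>  <dbl>   <dbl>   <dbl>  <int>
#> 1  2.08   1.24    1.11 188900.   1164
```

`mu = 2.08 Hz` sits at the stepping fundamental, and `entropy = 1.11`
(out of `ln(1164) = 7.06` for a flat spectrum) reflects a dominant peak
plus the broadband sensor noise.

```r
# A small monitoring cohort: 3 improving, 3 deteriorating participants,
# one 60-s walk per day for 14 days
cohort <- simulate_cohort(n_improving = 3, n_deteriorating = 3,
                          days = 14, seed = 42)
cohort |> index_walks() |> summarize_participants() |> eligibility_filter()
#> # A tibble: 6 × 8
#>   participant n_walks min_entropy max_entropy mean_entropy initial_entropy final_entropy variation_pct
#> 1           1      14        1.04        1.24         1.14            1.19          1.09         -8.50
#> 2           2      14        1.02        1.24         1.15            1.20          1.10         -8.34
#> 3           3      14        1.04        1.23         1.14            1.19          1.09         -8.20
#> 4           4      14        1.02        1.23         1.14            1.09          1.19          9.47
#> 5           5      14        1.03        1.21         1.13            1.08          1.18          8.98
#> 6           6      14        1.01        1.25         1.14            1.10          1.19          8.16
```

The three participants programmed to improve show negative entropy
variation, the three programmed to deteriorate positive — the signs
recover the programmed trends exactly.

```r
# Cohort statistics on the packaged second-study summary table
cohort_summary(gait_study_table("second")$variation_pct)
#> Cohort of 10 participants: 5 improved, 5 deteriorated, 0 stable
#>   improved: mean |variation| 14.5% (sd 11.2), n = 5
#>   deteriorated: mean |variation| 39.2% (sd 24.9), n = 5
#>   GM ratio deterioration/improvement: 3.01 (80% CI 1.16-7.82, pooled)
```

Per-participant longitudinal trends are fitted with `trend_fit()`
(OLS of an index on days since first walk, with a pointwise confidence
band) and plotted with `autoplot()`; `tidy()` and `glance()` return the
fit as tibbles.

## Command line

A thin CLI over the same functions lives at `inst/cli/gaitspec.R`:

```sh
Rscript inst/cli/gaitspec.R simulate --n-improving 11 --n-deteriorating 10 \
    --days 21 --seed 42 --out walks/
Rscript inst/cli/gaitspec.R analyze --input walks/ --band 0.3:10 \
    --period-days 7 --min-walks 10 --out report.csv
```

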