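# qeegparam

Quantitative-EEG spectral parameterization for pharmaco-electrophysiology in
freely moving rodents.

Drugs acting on GABAergic or glutamatergic transmission shift the
excitatory–inhibitory balance of cortical circuits, and those shifts are
visible in the EEG power spectrum — but classical fixed-band analysis mixes
two very different things: genuine oscillations and the broadband 1/f-like
background they ride on. A steepening background can mask a growing gamma
oscillation entirely. `qeegparam` separates the two and carries each through
its own statistics, so that oscillatory and background effects of a compound
can be linked to its measured plasma exposure.

## The model

A decibel-scale power spectrum `P(f)` is decomposed as

    P(f) = L(f) + sum_i  a_i * exp( -(f - mu_i)^2 / (2 sigma_i^2) ) + noise

where the aperiodic background `L(f)` is chosen by goodness of fit (RMSE)
among four families:

| family | form (dB) |
|---|---|
| power law            | `b + 1/f^X`              |
| Lorentzian           | `b + 1/(f^X + k)`        |
| power law + decay    | `b + 1/f^X + c e^(-d f)` |
| Lorentzian + decay   | `b + 1/(f^X + k) + c e^(-d f)` |

with offset `b`, exponent (slope) `X`, knee `k`, and optional exponential
decay. A `log_form` switch selects the spectral-parameterization-literature
convention `b - 10 log10(f^X + k)` instead of the literal reciprocal; the
log form is what realistic EEG backgrounds (tens of dB of decay) look like.
Gaussian peaks `(a_i, mu_i, sigma_i)` form the periodic component.

Downstream, the pooled distribution of fitted peak centers per condition is
smoothed by a Gaussian KDE and oscillatory band limits are placed at the
density valleys — bands (delta, theta, beta, low/mid/high-gamma, HFO) are
derived from the data, not imposed. Per band, three metrics are extracted:
peak amplitude, modal frequency, and area under the reconstructed periodic
curve (AUC). Inference uses a paired cluster-based permutation (CBP) test on
spectra and permutation-calibrated Spearman correlations between plasma
exposure and covariate-residualized metric contrasts (compound minus
vehicle).

A first-class synthetic-data module generates ground-truthed spectra,
spectrum-shaped EEG time series with injected artifacts, locomotion traces,
and exposure-linked paired cohorts, so the entire pipeline is testable
without any recorded data.

## Worked example

Simulate one noisy spectrum (log-form Lorentzian background, theta and beta
peaks, 0.2 dB bin noise) and decompose it:

```r
library(qeegparam)
gt <- ground_truth("lorentzian", b = -20, X = 1.5, k = 1, log_form = TRUE,
                   peaks = data.frame(peak = c("theta", "beta"), a = c(2.5, 2),
                                      mu = c(7, 15), sigma = c(1.2, 2)),
                   noise_sd = 0.2)
ps  <- make_spectrum(gt, seed = 1)
fit <- parametrize(ps, family = "lorentzian", log_form = TRUE,
                   reestimate_aperiodic = TRUE)
fit
#> <spectral_fit> lorentzian aperiodic (rmse 0.4159 dB) + 2 peak(s); full rmse 0.1912 dB
#>   peak a=2.32 dB, mu=7.068 Hz, sigma=1.32 Hz
#>   peak a=2.01 dB, mu=15.04 Hz, sigma=1.85 Hz
round(fit$aperiodic$params, 3)
#>       b       X       k
#> -19.918   1.504   1.038
```

The two injected oscillations come back at 7.07 and 15.04 Hz with
amplitudes within the bin noise, and the background parameters land on the
generating values (b −20, X 1.5, k 1). Band limits from a pooled center
distribution:

```r
cents <- rep(c(2.5, 8.1, 11.3, 27.3, 55.3, 85.7, 137.1), each = 100)
derive_band_limits(kde_density(cents, bandwidth = 1), condition = "vehicle")
#> <band_scheme> [vehicle] 7 bands (minima)
#>        band lower_hz upper_hz      range
#>       delta       NA      5.3       <5.3
#>       theta      5.3      9.7    5.3-9.7
#>        beta      9.7     19.3   9.7-19.3
#>   low_gamma     19.3     41.3  19.3-41.3
#>   mid_gamma     41.3     70.5  41.3-70.5
#>  high_gamma     70.5    111.4 70.5-111.4
#>         hfo    111.4       NA     >111.4
```

A perfectly anti-monotone exposure–response contrast gives the extreme
Spearman result with the minimal two-tailed permutation p:

```r
expo <- c(12, 25, 38, 51, 70, 88, 105, 120)
sp <- spearman_perm(expo, 5 - 0.03 * expo, n_perm = 1000, seed = 1)
#> rho = -1.000, p = 0.000999
```

For a full cohort analysis, see `run_pipeline()`: it takes a
`make_cohort()` object (or a `write_cohort()` manifest directory), and
produces spectra, fits, condition-specific band schemes, tidy metric
tables, CBP cluster results and the exposure-correlation table as plain
TSV/JSON in a results directory, bit-identically for a fixed seed.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates a 12-animal paired cohort with an exposure-linked
aperiodic-slope increase and beta-amplitude increase, executes the complete
pipeline (decomposition, band delimitation, metrics, CBP, exposure
correlations), logs the headline exposure correlation, and writes the
results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
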