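---
title: "Methods: spectral parameterization and exposure-response statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral parameterization and exposure-response statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegparam)
```

`qeegparam` implements a complete pharmaco-EEG analysis chain: preprocessing
of raw single-channel EEG and video tracking, Welch spectral estimation,
decomposition of the spectrum into periodic and aperiodic components,
data-driven band delimitation, per-band metrics, and permutation statistics
linking spectral parameters to plasma exposure. This vignette explains the
models, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## 1. Preprocessing

Artifacts are detected by amplitude: every maximal run with |signal| above
0.6 mV lasting longer than 1 s is masked and padded by 1.5 s on both sides;
overlapping padded intervals merge. The threshold is applied two-sided —
the conservative reading for a bipolar EEG signal — and to the raw signal.
No interpolation or regression correction is attempted: masked data are
excluded.

Behavioral state is derived from the tracked center of mass. Positions are
smoothed with a unit-mass truncated Gaussian kernel of 166 ms total support
(SD = support/6, the common filter-design convention; edge samples use
renormalized partial kernels so constants pass through unchanged). Speed
comes from central differences of the smoothed positions. Runs faster than
1 cm/s sustained for at least 1 s are *Moving*; the complement is *Still*,
which deliberately includes both quiet wakefulness and sleep — no sleep
scoring is attempted. Spectra are computed on artifact-free Still epochs
only, dropping remnants shorter than one analysis window.

## 2. Spectral estimation

`compute_spectrum()` is an averaged modified periodogram (Welch): windows of
`fs/resolution` samples (2 s at the default 0.5 Hz resolution), 50%
overlap, pooled across epochs with equal weight per window so longer Still
periods contribute proportionally. The 0–1 `leakage` knob maps to a Kaiser
taper with `beta = 40 * (1 - leakage)`; 0.85 is a mild taper. This mapping
reproduces the stated resolution; the exact window of the original
proprietary estimator is not recoverable, so correctness is established by
recovery on synthetic data (line spectra, flatness, Parseval), not by
matching any particular spectrum. Estimates are interpolated from the FFT
bin grid onto the exact requested grid (0.1–190 Hz in 0.5 Hz steps),
converted to decibels (`10 log10`), and mains harmonics (50 Hz and
multiples) are replaced by linear interpolation across a ±1 Hz notch — an
idempotent operation.

## 3. Periodic/aperiodic decomposition

The dB spectrum is modeled as an aperiodic background plus Gaussian peaks.
Four background families are supported: power law `b + 1/f^X`, Lorentzian
`b + 1/(f^X + k)`, and either plus an additive exponential decay
`c e^(-d f)` (the minimal reading of "plus exponential decay"). Two dB
conventions exist for the core, and the package implements both:

* `log_form = FALSE` (default): the literal reciprocal form above, applied
  to the dB spectrum exactly as written.
* `log_form = TRUE`: `b - 10 log10(f^X + k)`, the spectral-parameterization
  literature convention.

The choice matters more than it looks. The literal form has dynamic range
at most `1/k` dB for `k > 0` — a fraction of a decibel for moderate knees —
concentrated in the two or three lowest bins, where it is indistinguishable
from a narrow low-frequency peak. Realistic EEG backgrounds fall by tens of
decibels and are only representable in the log form. Consequently the
synthetic cohort world and the family-selection simulations use
`log_form = TRUE`, while the literal form remains the default for direct
use of the printed formulas. Under the literal form with per-bin noise of
0.2 dB, the Cramér–Rao bound on `X` and `k` exceeds 10 % relative error for
most of the (X, k) plane; the fitting tests document this rather than hide
it.

Fitting is bounded nonlinear least squares with the linear parameters
(`b`, `c`) profiled out exactly, three fixed deterministic starts, and a
peak-robust refinement: the top residual quartile (oscillatory peaks) is
masked and the fit repeated, iterating the mask so that informative bins
wrongly masked while the fit was still contaminated are recovered. RMSE is
reported over all bins. Family selection fits every candidate and takes the
minimal RMSE; within 1e-6 dB the family with fewer parameters wins, which
resolves the nested power-law/Lorentzian case on clean data. Note that
under noise a strictly nested larger family always attains a marginally
lower raw RMSE on the same data, so selection accuracy is only a meaningful
concept between non-nested candidates.

Peaks are extracted from the residual greedily — largest maximum at or
above `min_height` (default twice the residual MAD, floored at 1e-3 dB),
one bounded Gaussian fit, subtract, repeat up to `max_peaks = 8` (enough
for seven observed bands plus slack) — followed by a joint refit of all
peaks. Width bounds default to 0.5–24 Hz. Two refinements deal with known
failure modes:

* *Edge rule*: a fitted peak whose center lies within one width of the grid
  edge is an artifact of background misfit, not an oscillation, and is
  dropped.
* *Split refinement*: two strongly overlapping oscillations sum to a
  unimodal bump that one Gaussian fits almost perfectly. Where a peak
  leaves more local residual than noise explains, the fitter tries two
  Gaussians and keeps the split only if the sum of squares drops by more
  than a BIC-style penalty plus a material floor (≈1e-3 dB RMSE), so a
  well-fit peak is never re-split. On clean data this separates exactly
  overlapping pairs; at 0.2 dB noise the component split of such a bump is
  statistically unidentifiable (truth-started least squares misses by tens
  of percent), and the package then reports the single merged peak — whose
  reconstructed curve is still accurate.

`parametrize()` chains selection (or a fixed family), the aperiodic fit,
and peak extraction. With `reestimate_aperiodic` enabled (off by default;
on in the pipeline configuration) it backfits — alternating background
re-estimation on the peak-subtracted spectrum with peak re-extraction —
and finishes with a joint polish of all parameters simultaneously.
Backfitting alone stalls a few tenths of a dB away from the joint optimum
when peaks cover half the spectrum; the final joint polish is what brings
noiseless round-trips to machine-level accuracy. The full-model RMSE can
never exceed the aperiodic-only RMSE; if the optimizer ever violated this
the peaks would be discarded.

## 4. Band delimitation and band metrics

Fitted peak centers are pooled per condition across animals and regions and
smoothed with a Gaussian KDE. Defaults: bandwidth 1 Hz on a 0.1 Hz grid.
The historically printed configuration (0.05 Hz bandwidth, 100 grid points
over 0.1–190 Hz) is reachable by argument but cannot resolve sub-Hz limits:
its grid step (~1.9 Hz) exceeds its bandwidth many times over. Boundaries
sit at density minima between modes (`method = "minima"`, default; one
boundary per valley, which is what published band tables show). An
`"inflection"` method — second-difference sign changes flanking each valley,
two boundaries per valley — is provided because the terminology is
ambiguous; the intent was not guessed. Modes below 1 % of the density
maximum are ignored as noise. Exactly seven bands receive the canonical
ascending labels delta–HFO; any other count gets neutral names, so a label
never lies about what was found.

Within a band, the periodic curve is rebuilt from the Gaussians whose
*center* falls inside the limits (the most literal membership rule; tails
of outside peaks are excluded), evaluated analytically on a fine 0.05 Hz
grid spanning exactly the band interval. Amplitude is the curve maximum;
modal frequency its location, refined continuously within the bracketing
grid step (exact for pure Gaussians); AUC is the trapezoidal integral over
the band interval only — tails beyond the limits are deliberately not
counted, and with fitted widths they are negligible. An empty band has
amplitude 0, AUC 0 and *no* modal frequency: no frequency can be measured
where there is no amplitude.

## 5. Statistics

*Cluster-based permutation test.* Per-bin paired t statistics are
thresholded two-sided at the `cluster_alpha = 0.05` t quantile (the
standard choice; no other threshold is printed anywhere authoritative).
Contiguous supra-threshold bins form clusters; the cluster mass is the
*signed* sum of t, so increase and decrease clusters keep their direction.
The null is the maximum |mass| over sign flips of the subject difference
spectra — 1000 random flips by default, or exhaustive `2^n` enumeration
with `exact = TRUE`. Monte-Carlo p-values use the +1/+1 convention and can
never be zero.

*Residualization.* Metrics are residualized on an intercept plus experiment
number and age (OLS); residuals are exactly orthogonal to the covariates.
Zero-variance covariates are dropped (residualizing on a constant is mean
centering); genuinely collinear covariates raise an error naming the
columns.

*Rank-based normalization.* Where a normality check rejects, values are
mapped through average ranks to fractional ranks `(r - 0.5)/n` and the
normal quantile function — strictly rank-preserving, so Spearman statistics
are unaffected. The normality pre-test itself is standard and delegated.

*Exposure correlations.* For amplitude, AUC and the aperiodic parameters
the contrast is residualized compound minus residualized vehicle; modal
frequencies use the compound residual alone, because a compound can create
a band that simply does not exist under vehicle, and animals without a
modal frequency are dropped pairwise. Each contrast goes through a
permutation-calibrated Spearman correlation against exposure (`y` is
shuffled; under exchangeability shuffling either side is equivalent). Rows
with fewer than `min_n = 4` animals or a degenerate constant contrast are
flagged, never silently omitted. Exposure outliers are handled by an
explicit exclusion list supplied by the analyst; no automated outlier rule
is implemented.

## 6. The synthetic world

The generator states one concrete world and the tests measure the pipeline
against it:

* *Spectra*: background plus Gaussian peaks plus i.i.d. Gaussian bin noise
  (0.2 dB by default — the scatter a few minutes of Still data yield at
  0.5 Hz resolution). With zero noise the spectrum is the exact model
  curve.
* *Time series*: inverse-FFT spectral shaping — Fourier amplitudes fixed to
  the target PSD (read as dB re 1 mV²/Hz), phases uniform. The periodogram
  equals the target exactly; windowed estimates converge as duration grows.
  Chosen precisely because it guarantees the target spectrum in
  expectation. Real EEG nonstationarity, burst structure and waveform
  asymmetry are *not* emulated, so a green test establishes estimator
  correctness, not robustness to biology.
* *Artifacts*: rectangular excursions, so expected masks are analytically
  exact. *Tracking*: straight-line bouts at stated speeds, stationary
  elsewhere.
* *Cohorts*: every animal appears in both conditions (paired design), two
  experiments with overlapping age ranges (85–125 vs 105–150 days) and a
  shared dosing scheme (exposure uniform on 20–120 ng/ml in both).
  Compound ground truths equal vehicle truths plus linear exposure slopes
  (`effect_model`) plus additive experiment/age terms on the background
  parameters. Linearity is the simplest monotone map — all the Spearman
  machinery assumes. Exposure is deliberately *not* confounded with
  experiment: residualization projects out whatever the covariates explain,
  and a confounded design would cap the attainable correlation at ~0.4
  regardless of effect size, which would test the design matrix rather
  than the pipeline. The vehicle template (`default_vehicle_truth()`) is a
  log-form Lorentzian (−20 dB, X = 1.5, k = 1) with theta, beta and three
  gamma peaks — no delta peak and no HFO, which appear only under specific
  compounds.

## 7. Known limitations

* The literal reciprocal aperiodic form is nearly unidentifiable from
  0.1–190 Hz dB data at realistic noise; its parameters should be
  interpreted qualitatively. Use `log_form = TRUE` for EEG-shaped spectra.
* Component parameters of strongly overlapping peaks (separation below
  roughly two widths) are not identifiable under noise; only their summed
  curve is reliable.
* Signals are exchanged as CSV/TSV; no EDF reader is available in the
  supported dependency set.
* No multitaper/wavelet estimators, no time-resolved spectrograms, no
  multi-channel structure, no ANOVA (tidy tables are exported for external
  ANOVA tooling).
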