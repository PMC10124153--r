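Package: qeegparam
Title: Periodic and Aperiodic Parameterization of Pharmaco-EEG Power Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-EEG analysis pipeline for pharmaco-electrophysiology in
    freely moving rodents. Decomposes power spectra into an aperiodic
    (Lorentzian-family, 1/f-like) background and a periodic component modeled as
    a sum of Gaussian oscillatory peaks; delimits oscillatory frequency bands in
    a data-driven way from the distribution of fitted peak centers by kernel
    density estimation; extracts per-band metrics (peak amplitude, modal
    frequency, area under the curve); and links spectral parameters to drug
    plasma exposure with paired cluster-based permutation tests on spectra,
    covariate residualization, rank-based normalization, and
    permutation-calibrated Spearman correlations. Includes a ground-truthed
    synthetic-data generator (spectra, shaped-noise EEG time series with
    injected artifacts, locomotion traces, exposure-linked cohorts) so the full
    pipeline is testable end to end without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
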