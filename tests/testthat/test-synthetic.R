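# Synthetic-data generators: spectra, time series, artifacts, tracking,
# cohorts. Oracle: an independent literal transcription of the model formula.

test_that("make_spectrum evaluates the model exactly when noise-free", {
  # 1/f at f = 2 with zero offset
  gt <- ground_truth("lorentzian", b = 0, X = 1, k = 0)
  ps <- make_spectrum(gt, freqs = c(1, 2, 4))
  expect_equal(ps$power[2], 0.5)

  # Gaussian maximum at its center when the aperiodic contributes ~nothing
  gt2 <- ground_truth("lorentzian", b = 0, X = 1, k = 1e9,
                      peaks = data.frame(a = 3, mu = 10, sigma = 1))
  ps2 <- make_spectrum(gt2, freqs = seq(5, 15, by = 0.5))
  expect_equal(max(ps2$power), 3, tolerance = 1e-6)
  expect_equal(ps2$freqs[which.max(ps2$power)], 10)

  # oracle equivalence at 1e-10 on the full default grid
  pk <- data.frame(a = c(4, 2), mu = c(8, 40), sigma = c(1.5, 4))
  gt3 <- ground_truth("lorentzian", b = 5, X = 1.5, k = 2, peaks = pk)
  ps3 <- make_spectrum(gt3)
  expect_equal(ps3$power,
               oracle_spectrum_model(ps3$freqs, 5, 1.5, 2, pk),
               tolerance = 1e-10)

  # log-form convention matches its oracle too
  gt4 <- ground_truth("lorentzian", b = -20, X = 1.5, k = 1, peaks = pk,
                      log_form = TRUE)
  ps4 <- make_spectrum(gt4)
  expect_equal(ps4$power,
               oracle_spectrum_model(ps4$freqs, -20, 1.5, 1, pk, log_form = TRUE),
               tolerance = 1e-10)
})

test_that("ground_truth validates its invariants", {
  expect_error(ground_truth(X = 0), "X must be")
  expect_error(ground_truth(X = -1), "X must be")
  expect_error(ground_truth(k = -0.5), "k must be")
  expect_error(ground_truth(peaks = data.frame(a = 1, mu = 10, sigma = 0)), "sigma")
  expect_error(ground_truth(peaks = data.frame(a = -1, mu = 10, sigma = 1)), "amplitudes")
  expect_error(ground_truth(peaks = data.frame(a = 1, mu = 300, sigma = 1)), "0.1-190")
  expect_error(make_spectrum(ground_truth(), freqs = c(2, 1)), "increasing")
})

test_that("make_spectrum noise is seed-deterministic", {
  gt <- ground_truth("lorentzian", b = 5, X = 1.5, k = 2, noise_sd = 0.3)
  expect_identical(make_spectrum(gt, seed = 7)$power, make_spectrum(gt, seed = 7)$power)
  expect_false(identical(make_spectrum(gt, seed = 7)$power,
                         make_spectrum(gt, seed = 8)$power))
})

test_that("make_timeseries realizes the target spectrum", {
  flat <- ground_truth("lorentzian", b = -20, X = 1, k = 1e9)  # flat -20 dB target
  sig <- make_timeseries(flat, duration = 120, fs = 1000, seed = 2)
  est <- to_decibels(compute_spectrum(sig))
  sel <- est$freqs >= 1 & est$freqs <= 190
  expect_true(all(abs(est$power[sel] + 20) < 1))

  pk <- ground_truth("lorentzian", b = -25, X = 1, k = 1e9,
                     peaks = data.frame(a = 8, mu = 10, sigma = 1))
  est2 <- to_decibels(compute_spectrum(make_timeseries(pk, 120, 1000, seed = 3)))
  expect_lt(abs(est2$freqs[which.max(est2$power)] - 10), 0.51)

  expect_error(make_timeseries(flat, duration = 0), "duration")
  expect_error(make_timeseries(flat, duration = 60, fs = 300), "Nyquist|fs")
  expect_identical(make_timeseries(flat, 30, 500, seed = 4)$signal,
                   make_timeseries(flat, 30, 500, seed = 4)$signal)
})

test_that("time-series spectra converge to the target as duration grows", {
  truth <- default_vehicle_truth()
  truth$noise_sd <- 0
  target <- function(f) qeegparam:::eval_ground_truth(truth, f)
  dev <- sapply(c(60, 240), function(dur) {
    est <- to_decibels(compute_spectrum(make_timeseries(truth, dur, 1000, seed = 11)))
    sel <- est$freqs >= 1 & est$freqs <= 185
    sqrt(mean((est$power[sel] - target(est$freqs[sel]))^2))
  })
  expect_lt(dev[2], dev[1])
})

test_that("inject_artifacts adds exact rectangles and validates events", {
  z <- numeric(20000)
  out0 <- inject_artifacts(z, data.frame(start_s = numeric(0), duration_s = numeric(0),
                                         amplitude_mv = numeric(0)), fs = 1000)
  expect_identical(out0$signal, z)

  ev <- data.frame(start_s = 5, duration_s = 2, amplitude_mv = 1)
  out <- inject_artifacts(z, ev, fs = 1000)
  tt <- (seq_along(z) - 1) / 1000
  inside <- tt >= 5 & tt < 7
  expect_true(all(out$signal[inside] == 1))
  expect_true(all(out$signal[!inside] == 0))

  ev2 <- data.frame(start_s = c(2, 10), duration_s = c(1, 3), amplitude_mv = c(0.8, 1.2))
  out2 <- inject_artifacts(z, ev2, fs = 1000)
  mask <- (tt >= 2 & tt < 3) | (tt >= 10 & tt < 13)
  expect_identical(out2$signal != 0, mask)

  expect_error(inject_artifacts(z, data.frame(start_s = c(1, 1.5), duration_s = c(1, 1),
                                              amplitude_mv = c(1, 1)), fs = 1000),
               "overlap")
  expect_error(inject_artifacts(z, data.frame(start_s = 19.5, duration_s = 2,
                                              amplitude_mv = 1), fs = 1000),
               "extent")
})

test_that("make_tracking produces straight-line bouts at stated speeds", {
  still <- make_tracking(10)
  expect_equal(length(unique(still$x_cm)), 1L)
  expect_equal(length(unique(still$y_cm)), 1L)

  trk <- make_tracking(30, data.frame(start_s = 10, duration_s = 3, speed_cm_s = 2), fs = 25)
  p0 <- trk[trk$time_s == 10, c("x_cm", "y_cm")]
  p1 <- trk[trk$time_s == 13, c("x_cm", "y_cm")]
  disp <- sqrt(sum((p1 - p0)^2))
  expect_equal(disp, 6, tolerance = 1e-9)

  # finite-difference speeds match stated bout speeds within 1%
  v <- sqrt(diff(trk$x_cm)^2 + diff(trk$y_cm)^2) / diff(trk$time_s)
  mid <- trk$time_s[-1] > 10.1 & trk$time_s[-1] < 12.9
  expect_true(all(abs(v[mid] - 2) / 2 < 0.01))
  expect_error(make_tracking(30, data.frame(start_s = 1, duration_s = 2, speed_cm_s = -1)),
               "speed")
})

test_that("make_cohort builds a paired exposure-linked design deterministically", {
  em0 <- effect_model(aperiodic = c(X = 0))
  coh0 <- make_cohort(3, em0, seed = 3)
  for (id in names(coh0$truths)) {
    expect_identical(coh0$truths[[id]]$vehicle, coh0$truths[[id]]$compound)
  }

  em <- effect_model(aperiodic = c(X = 0.05))
  coh <- make_cohort(4, em, seed = 3)
  tt <- cohort_truth_table(coh)
  expo <- merge(tt[tt$condition == "compound", ], coh$exposures,
                by.x = c("animal", "condition"), by.y = c("animal", "condition"))
  veh <- tt[tt$condition == "vehicle", ]
  for (e in 1:2) {
    ids <- coh$animals$animal[coh$animals$experiment == e]
    sub <- expo[expo$animal %in% ids, ]
    dX <- sub$X - veh$X[match(sub$animal, veh$animal)]
    expect_equal(cor(sub$exposure_ng_ml, dX, method = "spearman"), 1)
  }

  c1 <- make_cohort(3, em, seed = 9)
  c2 <- make_cohort(3, em, seed = 9)
  expect_identical(cohort_truth_table(c1), cohort_truth_table(c2))
  expect_identical(c1$exposures, c2$exposures)

  expect_error(effect_model(), "empty")
  expect_error(make_cohort(2, em), "n_per_experiment")
  expect_error(effect_model(aperiodic = c(z = 1)), "unknown")
})
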