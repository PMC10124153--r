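# Artifact masking and behavioral segmentation.

test_that("detect_artifacts applies threshold, duration and padding rules", {
  z <- numeric(20000)
  expect_equal(nrow(detect_artifacts(z, fs = 1000)), 0L)

  # 1.0 mV rectangle on [5, 7) with default 0.6 mV / 1 s / 1.5 s -> [3.5, 8.5)
  sig <- inject_artifacts(z, data.frame(start_s = 5, duration_s = 2, amplitude_mv = 1),
                          fs = 1000)$signal
  m <- detect_artifacts(sig, fs = 1000)
  expect_equal(m$start_s, 3.5)
  expect_equal(m$end_s, 8.5)

  # supra-threshold but too short -> no mask
  short <- inject_artifacts(z, data.frame(start_s = 5, duration_s = 0.5, amplitude_mv = 1),
                            fs = 1000)$signal
  expect_equal(nrow(detect_artifacts(short, fs = 1000)), 0L)

  # negative excursions count too (two-sided threshold)
  neg <- inject_artifacts(z, data.frame(start_s = 2, duration_s = 2, amplitude_mv = -1),
                          fs = 1000)$signal
  expect_equal(nrow(detect_artifacts(neg, fs = 1000)), 1L)

  bad <- z
  bad[100] <- NaN
  expect_error(detect_artifacts(bad, fs = 1000), "index 100")
})

test_that("padded artifact masks merge and match injected events exactly", {
  z <- numeric(40000)
  ev <- data.frame(start_s = c(5, 9.5, 25), duration_s = c(2, 1.5, 1.2),
                   amplitude_mv = c(1, -0.9, 2))
  sig <- inject_artifacts(z, ev, fs = 1000)$signal
  m <- detect_artifacts(sig, fs = 1000)
  # first two events pad into each other: [3.5, 8.5) U [8, 12.5) -> [3.5, 12.5)
  expect_equal(m$start_s, c(3.5, 23.5))
  expect_equal(m$end_s, c(12.5, 27.7), tolerance = 1e-9)
})

test_that("smooth_tracking preserves constants, mass and step monotonicity", {
  trk <- make_tracking(10, fs = 25)
  sm <- smooth_tracking(trk)
  expect_equal(sm$x_cm, trk$x_cm, tolerance = 1e-12)
  expect_equal(sm$y_cm, trk$y_cm, tolerance = 1e-12)

  # step input: smoothed output is monotone and stays between the two levels
  n <- 100
  step <- data.frame(time_s = (0:(n - 1)) / 25,
                     x_cm = c(rep(0, n / 2), rep(10, n / 2)),
                     y_cm = 0)
  sms <- smooth_tracking(step, window_s = 0.4)
  expect_true(all(diff(sms$x_cm) >= -1e-12))
  expect_true(all(sms$x_cm >= 0 - 1e-12 & sms$x_cm <= 10 + 1e-12))

  # direct convolution oracle in the interior
  dt <- 1 / 25
  m <- floor((0.4 / dt - 1) / 2)
  kern <- dnorm(-m:m, sd = (0.4 / 6) / dt)
  kern <- kern / sum(kern)
  i <- 50
  expect_equal(sms$x_cm[i], sum(step$x_cm[(i - m):(i + m)] * kern), tolerance = 1e-12)

  expect_warning(smooth_tracking(trk, window_s = 0.01), "window")
})

test_that("classify_behavior labels supra-threshold runs as moving", {
  still <- make_tracking(20, fs = 25)
  seg0 <- classify_behavior(still)
  expect_equal(nrow(seg0$moving), 0L)
  expect_equal(qeegparam:::interval_duration(seg0$still), seg0$extent_s)

  trk <- make_tracking(30, data.frame(start_s = 10, duration_s = 3, speed_cm_s = 2), fs = 25)
  seg <- classify_behavior(smooth_tracking(trk))
  expect_equal(nrow(seg$moving), 1L)
  # within two tracking samples of the designed bout
  expect_lt(abs(seg$moving$start_s - 10), 0.1)
  expect_lt(abs(seg$moving$end_s - 13), 0.1)

  shortb <- make_tracking(30, data.frame(start_s = 10, duration_s = 0.5, speed_cm_s = 2), fs = 25)
  expect_equal(nrow(classify_behavior(smooth_tracking(shortb))$moving), 0L)

  bad <- trk
  bad$time_s[5] <- bad$time_s[7]
  expect_error(classify_behavior(bad), "increasing")
})

test_that("still and moving partition the recording for random bout layouts", {
  set.seed(4)
  for (rep in 1:5) {
    k <- sample(1:3, 1)
    starts <- sort(runif(k, 0, 50))
    starts <- starts[c(TRUE, diff(starts) > 6)]
    bouts <- data.frame(start_s = starts, duration_s = runif(length(starts), 1.5, 4),
                        speed_cm_s = runif(length(starts), 1.5, 5))
    seg <- classify_behavior(make_tracking(60, bouts, fs = 25))
    expect_equal(qeegparam:::interval_duration(seg$still) +
                 qeegparam:::interval_duration(seg$moving),
                 seg$extent_s, tolerance = 1e-9)
    ov <- qeegparam:::intersect_intervals(seg$still, seg$moving)
    expect_equal(nrow(ov), 0L)
  }
})

test_that("extract_still_epochs subtracts artifacts and drops short remnants", {
  sig <- numeric(10000)  # 10 s at 1000 Hz
  fs <- 1000
  all_still <- extract_still_epochs(sig, fs = fs, min_epoch_s = 2)
  expect_equal(length(all_still$epochs), 1L)
  expect_equal(all_still$total_s, 10)

  mask <- qeegparam:::epoch_mask(data.frame(start_s = 3.5, end_s = 8.5), "artifact", 10)
  eps <- extract_still_epochs(sig, artifacts = mask, min_epoch_s = 2, fs = fs)
  expect_equal(eps$intervals, data.frame(start_s = 0, end_s = 3.5))
  # the [8.5, 10) remnant (1.5 s) is below min_epoch and dropped
  expect_equal(length(eps$epochs), 1L)
  expect_equal(length(eps$epochs[[1]]), 3500L)

  full <- qeegparam:::epoch_mask(data.frame(start_s = 0, end_s = 10), "artifact", 10)
  expect_warning(out <- extract_still_epochs(sig, artifacts = full, min_epoch_s = 2, fs = fs),
                 "no artifact-free")
  expect_equal(length(out$epochs), 0L)
  expect_match(out$diagnostic, "no artifact-free")
})
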