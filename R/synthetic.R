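# Synthetic-data module: ground-truthed spectra, shaped-noise EEG time series,
# locomotion traces, and exposure-linked cohorts. Every downstream stage of the
# pipeline is testable against objects built here, with no recorded data.

#' Ground truth for one synthetic power spectrum
#'
#' Describes a decibel-scale spectrum as an aperiodic background plus Gaussian
#' oscillatory peaks plus independent Gaussian bin noise. The aperiodic
#' families are the four candidates used throughout the package: power law
#' `b + 1/f^X`, Lorentzian `b + 1/(f^X + k)`, and either plus an additive
#' exponential decay `c * exp(-d * f)`.
#'
#' @param family aperiodic family: one of `"powerlaw"`, `"lorentzian"`,
#'   `"powerlaw_expdecay"`, `"lorentzian_expdecay"`.
#' @param b offset (dB).
#' @param X decay exponent (dimensionless, > 0).
#' @param k knee parameter (>= 0; Lorentzian families only).
#' @param c_decay,d_decay exponential-decay amplitude (dB) and rate (per Hz);
#'   exp-decay families only.
#' @param peaks `data.frame` with columns `a` (amplitude, dB, >= 0), `mu`
#'   (center, Hz, inside the 0.1-190 Hz analysis range) and `sigma` (width,
#'   Hz, > 0); optionally a `peak` name column. `NULL` for no peaks.
#' @param noise_sd standard deviation of additive per-bin Gaussian noise (dB).
#' @param log_form if `TRUE` the aperiodic core is `b - 10*log10(f^X + k)`
#'   (the spectral-parameterization literature convention, which produces
#'   realistic tens-of-dB EEG backgrounds) instead of the literal reciprocal
#'   `b + 1/(f^X + k)`. Default `FALSE`.
#' @return an object of class `ground_truth`.
#' @examples
#' gt <- ground_truth("lorentzian", b = 5, X = 1.5, k = 2,
#'                    peaks = data.frame(a = c(4, 2), mu = c(8, 40),
#'                                       sigma = c(1.5, 4)))
#' ps <- make_spectrum(gt, seed = 1)
#' @export
ground_truth <- function(family = "lorentzian", b = 0, X = 1, k = 0,
                         c_decay = NULL, d_decay = NULL,
                         peaks = NULL, noise_sd = 0, log_form = FALSE) {
  family <- match.arg(family, aperiodic_families())
  if (!is_number(X) || X <= 0) stop_fmt("exponent X must be a positive number, got %s", format(X))
  if (!is_number(b)) stop_fmt("offset b must be a finite number")
  if (grepl("lorentzian", family)) {
    if (!is_number(k) || k < 0) stop_fmt("knee k must be >= 0, got %s", format(k))
  } else {
    k <- NULL
  }
  if (grepl("expdecay", family)) {
    if (!is_number(c_decay) || !is_number(d_decay) || d_decay < 0)
      stop_fmt("expdecay families need finite c_decay and d_decay >= 0")
  } else {
    c_decay <- NULL
    d_decay <- NULL
  }
  if (!is.null(peaks)) {
    peaks <- as.data.frame(peaks)
    need <- c("a", "mu", "sigma")
    if (!all(need %in% names(peaks)))
      stop_fmt("peaks must have columns a, mu, sigma")
    if (any(!is.finite(peaks$a)) || any(peaks$a < 0))
      stop_fmt("peak amplitudes a must be finite and >= 0")
    if (any(!is.finite(peaks$sigma)) || any(peaks$sigma <= 0))
      stop_fmt("peak widths sigma must be positive")
    if (any(peaks$mu < 0.1 | peaks$mu > 190))
      stop_fmt("peak centers mu must lie in the 0.1-190 Hz analysis range")
    if (is.null(peaks$peak)) peaks$peak <- paste0("peak", seq_len(nrow(peaks)))
  } else {
    peaks <- data.frame(a = numeric(0), mu = numeric(0), sigma = numeric(0),
                        peak = character(0))
  }
  if (!is_number(noise_sd) || noise_sd < 0) stop_fmt("noise_sd must be >= 0")
  structure(
    list(family = family, b = b, X = X, k = k,
         c_decay = c_decay, d_decay = d_decay,
         peaks = peaks, noise_sd = noise_sd, log_form = isTRUE(log_form)),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> aperiodic", x$family,
      sprintf("(b=%.3g, X=%.3g%s%s)", x$b, x$X,
              if (!is.null(x$k)) sprintf(", k=%.3g", x$k) else "",
              if (!is.null(x$c_decay)) sprintf(", c=%.3g, d=%.3g", x$c_decay, x$d_decay) else ""),
      "\n")
  cat("  peaks:", nrow(x$peaks), " noise_sd:", x$noise_sd, "dB\n")
  invisible(x)
}

# Noise-free model curve of a ground truth on a frequency grid (dB).
eval_ground_truth <- function(truth, freqs) {
  stopifnot(inherits(truth, "ground_truth"))
  y <- eval_aperiodic(truth$family, truth_aperiodic_params(truth), freqs,
                      log_form = isTRUE(truth$log_form))
  if (nrow(truth$peaks) > 0L) {
    for (i in seq_len(nrow(truth$peaks)))
      y <- y + gauss_curve(freqs, truth$peaks$a[i], truth$peaks$mu[i], truth$peaks$sigma[i])
  }
  y
}

truth_aperiodic_params <- function(truth) {
  p <- c(b = truth$b, X = truth$X)
  if (!is.null(truth$k)) p <- c(p, k = truth$k)
  if (!is.null(truth$c_decay)) p <- c(p, c = truth$c_decay, d = truth$d_decay)
  p
}

gauss_curve <- function(f, a, mu, sigma) a * exp(-(f - mu)^2 / (2 * sigma^2))

#' Simulate a power spectrum from a ground truth
#'
#' Evaluates the ground-truth model curve on a frequency grid and adds
#' independent Gaussian bin noise. With `noise_sd = 0` in the truth the result
#' is the exact model curve.
#'
#' @param truth a [ground_truth()].
#' @param freqs strictly increasing frequency grid (Hz) inside 0.1-190 Hz.
#' @param seed integer seed for the bin noise (ignored when `noise_sd = 0`).
#' @return a `power_spectrum` on the dB scale.
#' @export
make_spectrum <- function(truth, freqs = default_freq_grid(), seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(diff(freqs) <= 0)) stop_fmt("frequency grid must be strictly increasing")
  if (min(freqs) < 0.1 - 1e-9 || max(freqs) > 190 + 1e-9)
    stop_fmt("frequency grid must lie within 0.1-190 Hz")
  y <- eval_ground_truth(truth, freqs)
  if (truth$noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(freqs), 0, truth$noise_sd))
  power_spectrum(freqs, y, scale = "dB",
                 meta = list(source = "synthetic", noise_sd = truth$noise_sd))
}

#' Default analysis frequency grid
#'
#' 0.1 to 190 Hz in 0.5 Hz steps, the grid used throughout the pipeline.
#' @return numeric vector of frequencies (Hz).
#' @export
default_freq_grid <- function() seq(0.1, 190, by = 0.5)

#' Synthesize an EEG-like time series realizing a target spectrum
#'
#' Builds a real-valued signal by inverse-FFT spectral shaping: Fourier
#' amplitudes are fixed to the target power spectral density (the truth's
#' model curve, read as dB re 1 mV^2/Hz) and phases are drawn uniformly at
#' random. The periodogram of the result equals the target exactly; windowed
#' averaged estimates converge to it as the duration grows.
#'
#' @param truth a [ground_truth()].
#' @param duration seconds (>= 10).
#' @param fs sampling rate, samples/s (>= 380 so the 190 Hz analysis limit is
#'   below Nyquist).
#' @param seed integer seed for the random phases.
#' @param line_amp_mv amplitude (mV) of an optional 50 Hz mains component, for
#'   exercising line-noise removal. Default 0.
#' @return an object of class `eeg_signal`: list with `signal` (mV) and `fs`.
#' @export
make_timeseries <- function(truth, duration = 120, fs = 1000, seed = 1L,
                            line_amp_mv = 0) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is_number(duration) || duration < 10)
    stop_fmt("duration must be >= 10 s, got %s", format(duration))
  if (!is_number(fs) || fs < 2 * 190)
    stop_fmt("fs must be >= 380 samples/s (Nyquist for the 190 Hz analysis limit)")
  n <- round(duration * fs)
  half <- floor(n / 2)
  fgrid <- (1:half) * fs / n
  # PSD target: model curve, clamped below the 0.1 Hz analysis floor;
  # above 190 Hz the model itself extends naturally (peaks decay, background persists).
  feval <- pmax(fgrid, 0.1)
  s_db <- eval_ground_truth(truth, pmin(feval, 190))
  above <- fgrid > 190
  if (any(above)) {
    # continue the aperiodic background only beyond the analysis limit
    s_db[above] <- eval_aperiodic(truth$family, truth_aperiodic_params(truth),
                                  fgrid[above], log_form = isTRUE(truth$log_form))
  }
  s_lin <- 10^(s_db / 10)                      # mV^2/Hz
  amp <- sqrt(s_lin * n * fs / 2)              # |X_k| for one-sided PSD
  x <- with_seed(seed, {
    phases <- stats::runif(half, 0, 2 * pi)
    spec <- complex(modulus = 1, argument = 0) * numeric(n)
    spec <- rep(0 + 0i, n)
    spec[2:(half + 1L)] <- complex(modulus = amp, argument = phases)
    if (n %% 2 == 0) {
      # Nyquist bin must be real; two-sided PSD there is S*n*fs (no mirror)
      spec[half + 1L] <- complex(modulus = sqrt(s_lin[half] * n * fs), argument = 0) *
        sign(stats::runif(1) - 0.5)
    }
    if (n %% 2 == 0 && half >= 2) {
      spec[(half + 2L):n] <- Conj(spec[half:2L])
    } else if (n %% 2 == 1) {
      spec[(half + 2L):n] <- Conj(spec[(half + 1L):2L])
    }
    Re(stats::fft(spec, inverse = TRUE)) / n
  })
  if (line_amp_mv > 0) {
    tt <- (seq_len(n) - 1L) / fs
    x <- x + line_amp_mv * sin(2 * pi * 50 * tt)
  }
  structure(list(signal = x, fs = fs), class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %.1f s at %g Hz (sd %.3g mV)\n",
              length(x$signal) / x$fs, x$fs, stats::sd(x$signal)))
  invisible(x)
}

# Accept either an eeg_signal or a bare numeric vector + fs.
signal_vector <- function(signal, fs = NULL) {
  if (inherits(signal, "eeg_signal")) {
    list(x = signal$signal, fs = signal$fs)
  } else {
    if (is.null(fs)) stop_fmt("fs must be given when signal is a bare vector")
    list(x = as.numeric(signal), fs = fs)
  }
}

#' Inject rectangular artifacts into a signal
#'
#' Adds a constant excursion of the stated amplitude over each half-open
#' event interval `[start, start + duration)`. The exact injected intervals
#' are returned as ground truth for testing artifact detection.
#'
#' @param signal an `eeg_signal` or numeric vector.
#' @param events `data.frame` with columns `start_s`, `duration_s`,
#'   `amplitude_mv`. Events must be disjoint and inside the signal extent.
#' @param fs sampling rate; required when `signal` is a bare vector.
#' @return list with `signal` (same class as input), and `events`
#'   (`start_s`, `end_s`, `amplitude_mv`).
#' @export
inject_artifacts <- function(signal, events, fs = NULL) {
  sv <- signal_vector(signal, fs)
  dur <- length(sv$x) / sv$fs
  events <- as.data.frame(events)
  if (nrow(events) == 0L) {
    return(list(signal = signal,
                events = data.frame(start_s = numeric(0), end_s = numeric(0),
                                    amplitude_mv = numeric(0))))
  }
  need <- c("start_s", "duration_s", "amplitude_mv")
  if (!all(need %in% names(events))) stop_fmt("events needs columns %s", paste(need, collapse = ", "))
  ev <- events[order(events$start_s), , drop = FALSE]
  ev$end_s <- ev$start_s + ev$duration_s
  if (any(ev$start_s < 0) || any(ev$end_s > dur + 1e-9))
    stop_fmt("artifact events must lie within the signal extent [0, %.3f) s", dur)
  if (nrow(ev) > 1L && any(ev$start_s[-1L] < ev$end_s[-nrow(ev)]))
    stop_fmt("artifact events must not overlap")
  x <- sv$x
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$start_s[i] * sv$fs + 1e-9) + 1L
    i1 <- ceiling(ev$end_s[i] * sv$fs - 1e-9)
    x[i0:i1] <- x[i0:i1] + ev$amplitude_mv[i]
  }
  out <- if (inherits(signal, "eeg_signal")) {
    structure(list(signal = x, fs = sv$fs), class = "eeg_signal")
  } else x
  list(signal = out,
       events = data.frame(start_s = ev$start_s, end_s = ev$end_s,
                           amplitude_mv = ev$amplitude_mv))
}

#' Simulate a center-of-mass tracking trace with still/moving bouts
#'
#' The animal's center of mass is stationary except during the listed bouts,
#' in each of which it moves in a straight line at the stated speed. Bout
#' headings rotate deterministically so the trace stays inside a plausible
#' arena.
#'
#' @param duration seconds.
#' @param bouts `data.frame` with columns `start_s`, `duration_s`,
#'   `speed_cm_s`; bouts must be disjoint, speeds >= 0.
#' @param fs tracking sample rate (Hz), default 25 (typical video tracking).
#' @param origin starting position c(x, y) in cm.
#' @return `data.frame` with columns `time_s`, `x_cm`, `y_cm`.
#' @export
make_tracking <- function(duration, bouts = NULL, fs = 25, origin = c(20, 20)) {
  if (!is_number(duration) || duration <= 0) stop_fmt("duration must be positive")
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  vx <- numeric(n)
  vy <- numeric(n)
  if (!is.null(bouts) && nrow(as.data.frame(bouts)) > 0L) {
    bouts <- as.data.frame(bouts)
    need <- c("start_s", "duration_s", "speed_cm_s")
    if (!all(need %in% names(bouts))) stop_fmt("bouts needs columns %s", paste(need, collapse = ", "))
    if (any(bouts$speed_cm_s < 0)) stop_fmt("bout speeds must be >= 0")
    b <- bouts[order(bouts$start_s), , drop = FALSE]
    b$end_s <- b$start_s + b$duration_s
    if (nrow(b) > 1L && any(b$start_s[-1L] < b$end_s[-nrow(b)]))
      stop_fmt("bouts must be disjoint")
    if (any(b$end_s > duration + 1e-9)) stop_fmt("bouts must lie within the recording")
    golden <- pi * (3 - sqrt(5))
    for (i in seq_len(nrow(b))) {
      ang <- (i - 1L) * golden
      sel <- tt >= b$start_s[i] - 1e-9 & tt < b$end_s[i] - 1e-9
      vx[sel] <- b$speed_cm_s[i] * cos(ang)
      vy[sel] <- b$speed_cm_s[i] * sin(ang)
    }
  }
  x <- origin[1L] + cumsum(vx) / fs
  y <- origin[2L] + cumsum(vy) / fs
  # position at t is the integral of velocity up to t, not including it
  x <- c(origin[1L], x[-n])
  y <- c(origin[2L], y[-n])
  data.frame(time_s = tt, x_cm = x, y_cm = y)
}

#' Exposure-effect model for synthetic cohorts
#'
#' Linear slopes, per ng/ml of plasma exposure, applied to ground-truth
#' parameters when turning an animal's vehicle truth into its compound truth.
#' Monotone (here linear) exposure-parameter maps are what the downstream
#' Spearman analysis is designed to detect.
#'
#' @param aperiodic named numeric vector of slopes for `b`, `X`, `k` (dB,
#'   exponent units, knee units per ng/ml). Zero entries allowed.
#' @param peaks named list: for each named peak of the base truth, a named
#'   numeric vector of slopes for `a`, `mu`, `sigma`.
#' @return an `effect_model` object.
#' @examples
#' effect_model(aperiodic = c(X = 0.004), peaks = list(beta = c(a = 0.02)))
#' @export
effect_model <- function(aperiodic = NULL, peaks = NULL) {
  if ((is.null(aperiodic) || length(aperiodic) == 0L) &&
      (is.null(peaks) || length(peaks) == 0L))
    stop_fmt("effect model is empty: give at least one aperiodic or peak slope")
  if (!is.null(aperiodic)) {
    bad <- setdiff(names(aperiodic), c("b", "X", "k"))
    if (length(bad)) stop_fmt("unknown aperiodic slope name(s): %s", paste(bad, collapse = ", "))
  }
  if (!is.null(peaks)) {
    for (nm in names(peaks)) {
      bad <- setdiff(names(peaks[[nm]]), c("a", "mu", "sigma"))
      if (length(bad)) stop_fmt("unknown peak slope name(s) for %s: %s", nm, paste(bad, collapse = ", "))
    }
  }
  structure(list(aperiodic = aperiodic, peaks = peaks), class = "effect_model")
}

# Apply exposure and covariate shifts to a vehicle truth; clamps keep the
# result a valid ground truth.
shift_truth <- function(truth, shifts_aperiodic = NULL, shifts_peaks = NULL) {
  b <- truth$b + (shifts_aperiodic["b"] %||% 0)
  X <- max(truth$X + (shifts_aperiodic["X"] %||% 0), 0.05)
  k <- if (is.null(truth$k)) NULL else max(truth$k + (shifts_aperiodic["k"] %||% 0), 0)
  peaks <- truth$peaks
  if (!is.null(shifts_peaks) && nrow(peaks) > 0L) {
    for (nm in names(shifts_peaks)) {
      i <- which(peaks$peak == nm)
      if (!length(i)) next
      s <- shifts_peaks[[nm]]
      peaks$a[i] <- max(peaks$a[i] + (s["a"] %||% 0), 0)
      peaks$mu[i] <- min(max(peaks$mu[i] + (s["mu"] %||% 0), 0.1), 190)
      peaks$sigma[i] <- max(peaks$sigma[i] + (s["sigma"] %||% 0), 0.1)
    }
  }
  ground_truth(truth$family, b = b, X = X, k = k,
               c_decay = truth$c_decay, d_decay = truth$d_decay,
               peaks = peaks, noise_sd = truth$noise_sd,
               log_form = isTRUE(truth$log_form))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(suppressWarnings(a[1]))) b else a

#' Default vehicle-session ground truth for a rat cortical EEG spectrum
#'
#' Lorentzian-knee background in the log10 convention
#' (`-20 - 10*log10(f^1.5 + 1)` dB re 1 mV^2/Hz: ~34 dB of 1/f decay with a
#' knee near 1 Hz, the shape real rodent EEG shows in decibels) with five
#' oscillatory peaks (theta, beta, low/mid/high gamma) and 0.2 dB bin noise.
#' Parameter choices and their rationale are discussed in the methods
#' vignette; the literal reciprocal aperiodic form cannot produce a
#' realistic EEG background (its dynamic range is at most `1/k` dB), which
#' is why the cohort world uses `log_form = TRUE`.
#' @return a [ground_truth()].
#' @export
default_vehicle_truth <- function() {
  ground_truth(
    "lorentzian", b = -20, X = 1.5, k = 1, log_form = TRUE,
    peaks = data.frame(
      peak = c("theta", "beta", "low_gamma", "mid_gamma", "high_gamma"),
      a = c(2.5, 2.0, 1.5, 1.2, 1.0),
      mu = c(7, 15, 30, 55, 90),
      sigma = c(1.2, 2.0, 3.5, 5.0, 7.0)),
    noise_sd = 0.2)
}

#' Simulate a paired pharmaco-EEG cohort
#'
#' Generates a paired-design cohort: every animal is recorded under every
#' condition (vehicle and compound), in one of two experiments with distinct
#' age and exposure distributions, across one or more cortical regions. Each
#' animal/condition/region gets a ground-truth spectrum model; compound
#' parameters equal the animal's vehicle parameters plus `effect_model`
#' slopes times its plasma exposure, plus additive experiment and age
#' covariate terms. Fully determined by `seed`.
#'
#' @param n_per_experiment animals per experiment (>= 3); total 2x this.
#' @param effect_model an [effect_model()].
#' @param regions character vector of region labels.
#' @param base_truth vehicle-session [ground_truth()] template.
#' @param covariate_effects list with optional named vectors `experiment`
#'   (additive shift for experiment 2 vs 1) and `age` (slope per day of age,
#'   centered at 100 d), each naming aperiodic parameters `b`, `X`, `k`.
#' @param animal_sd named numeric: between-animal SD of `b` (dB) and `X`.
#' @param exposure_range list with numeric ranges `exp1`, `exp2` (ng/ml) for
#'   the uniform compound-exposure draws of each experiment. Both experiments
#'   share one dosing scheme by default, so plasma exposure varies between
#'   animals (pharmacokinetics) but is not confounded with the experiment
#'   regressor; covariate effects on the EEG parameters themselves are what
#'   residualization removes. A confounded design (distinct ranges) caps the
#'   attainable exposure correlation because residualization then projects
#'   out the between-experiment dose component too.
#' @param compound label for the compound condition.
#' @param seed integer; fully determines the cohort.
#' @return a `synthetic_cohort`: list with `animals` (animal, experiment,
#'   age_days), `exposures` (animal, condition, exposure_ng_ml), nested
#'   `truths[[animal]][[condition]][[region]]`, plus the generating
#'   parameters.
#' @export
make_cohort <- function(n_per_experiment = 6,
                        effect_model,
                        regions = "parietal",
                        base_truth = default_vehicle_truth(),
                        covariate_effects = list(experiment = c(b = -0.8, X = 0.05),
                                                 age = c(b = -0.005, X = 5e-4)),
                        animal_sd = c(b = 0.5, X = 0.05),
                        exposure_range = list(exp1 = c(20, 120), exp2 = c(20, 120)),
                        compound = "compound",
                        seed = 1L) {
  if (!inherits(effect_model, "effect_model"))
    stop_fmt("effect_model must be built with effect_model()")
  if (!is_number(n_per_experiment) || n_per_experiment < 3)
    stop_fmt("n_per_experiment must be >= 3")
  n_per_experiment <- as.integer(n_per_experiment)
  n <- 2L * n_per_experiment
  with_seed(seed, {
    animals <- data.frame(
      animal = sprintf("rat%02d", seq_len(n)),
      experiment = rep(1:2, each = n_per_experiment),
      age_days = c(round(stats::runif(n_per_experiment, 85, 125)),
                   round(stats::runif(n_per_experiment, 105, 150))))
    expo <- ifelse(animals$experiment == 1L,
                   stats::runif(n, exposure_range$exp1[1], exposure_range$exp1[2]),
                   stats::runif(n, exposure_range$exp2[1], exposure_range$exp2[2]))
    exposures <- rbind(
      data.frame(animal = animals$animal, condition = "vehicle", exposure_ng_ml = 0),
      data.frame(animal = animals$animal, condition = compound, exposure_ng_ml = expo))
    region_offsets <- stats::setNames(seq_along(regions) - 1, regions) * 0.6  # dB between regions
    truths <- list()
    for (i in seq_len(n)) {
      id <- animals$animal[i]
      indiv <- c(b = stats::rnorm(1, 0, animal_sd[["b"]]),
                 X = stats::rnorm(1, 0, animal_sd[["X"]]))
      cov_shift <- c(b = 0, X = 0, k = 0)
      for (p in c("b", "X", "k")) {
        e2 <- if (animals$experiment[i] == 2L) covariate_effects$experiment[p] %||% 0 else 0
        ag <- (covariate_effects$age[p] %||% 0) * (animals$age_days[i] - 100)
        cov_shift[[p]] <- as.numeric(e2) + as.numeric(ag)
      }
      truths[[id]] <- list()
      for (cond in c("vehicle", compound)) {
        truths[[id]][[cond]] <- list()
        dose <- exposures$exposure_ng_ml[exposures$animal == id & exposures$condition == cond]
        ap_shift <- cov_shift + c(b = indiv[["b"]], X = indiv[["X"]], k = 0)
        pk_shift <- NULL
        if (cond != "vehicle") {
          for (p in names(effect_model$aperiodic))
            ap_shift[[p]] <- ap_shift[[p]] + effect_model$aperiodic[[p]] * dose
          if (!is.null(effect_model$peaks))
            pk_shift <- lapply(effect_model$peaks, function(s) s * dose)
        }
        for (rg in regions) {
          ap_rg <- ap_shift
          ap_rg[["b"]] <- ap_rg[["b"]] + region_offsets[[rg]]
          truths[[id]][[cond]][[rg]] <- shift_truth(base_truth, ap_rg, pk_shift)
        }
      }
    }
    structure(
      list(animals = animals, exposures = exposures, truths = truths,
           regions = regions, conditions = c("vehicle", compound),
           compound = compound, effect_model = effect_model, seed = as.integer(seed)),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d animals (2 experiments), conditions: %s; regions: %s; seed %d\n",
              nrow(x$animals), paste(x$conditions, collapse = ", "),
              paste(x$regions, collapse = ", "), x$seed))
  invisible(x)
}

#' Per-animal true parameter table of a synthetic cohort
#'
#' Tidy view of the generating ground truths, for checking recovery.
#' @param cohort a [make_cohort()] result.
#' @return `data.frame`: animal, condition, region, b, X, k and one
#'   `a_<peak>` column per named peak.
#' @export
cohort_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- list()
  for (id in names(cohort$truths)) {
    for (cond in names(cohort$truths[[id]])) {
      for (rg in names(cohort$truths[[id]][[cond]])) {
        tr <- cohort$truths[[id]][[cond]][[rg]]
        row <- data.frame(animal = id, condition = cond, region = rg,
                          b = tr$b, X = tr$X, k = tr$k %||% NA_real_)
        for (i in seq_len(nrow(tr$peaks)))
          row[[paste0("a_", tr$peaks$peak[i])]] <- tr$peaks$a[i]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
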