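# Spectral estimation: Welch-style averaged modified periodograms on a fixed
# 0.1-190 Hz grid, decibel conversion, and mains-line notch by interpolation.
# No PSD helper exists in the installed stack, so the estimator is written on
# stats::fft and validated against Parseval / line-spectrum oracles in tests.

#' Power spectrum container
#'
#' @param freqs strictly increasing frequency grid (Hz).
#' @param power per-bin values, finite; linear power spectral density
#'   (mV^2/Hz) or decibels depending on `scale`.
#' @param scale `"linear"` or `"dB"`.
#' @param n_epochs,seconds provenance: epochs and total seconds analyzed.
#' @param meta named list of estimator metadata.
#' @return a `power_spectrum` object.
#' @export
power_spectrum <- function(freqs, power, scale = c("linear", "dB"),
                           n_epochs = NA_integer_, seconds = NA_real_,
                           meta = list()) {
  scale <- match.arg(scale)
  freqs <- as.numeric(freqs)
  power <- as.numeric(power)
  if (length(freqs) != length(power)) stop_fmt("freqs and power lengths differ")
  if (any(diff(freqs) <= 0)) stop_fmt("freqs must be strictly increasing")
  if (any(!is.finite(power))) stop_fmt("power must be finite")
  structure(list(freqs = freqs, power = power, scale = scale,
                 n_epochs = n_epochs, seconds = seconds, meta = meta),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.2f-%.1f Hz, scale %s",
              length(x$freqs), min(x$freqs), max(x$freqs), x$scale))
  if (!is.na(x$n_epochs)) cat(sprintf(" (%d epochs, %.1f s)", x$n_epochs, x$seconds))
  cat("\n")
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ..., log_freq = TRUE) {
  ylab <- if (x$scale == "dB") "power (dB)" else "PSD (mV²/Hz)"
  graphics::plot(x$freqs, x$power, type = "l", log = if (log_freq) "x" else "",
                 xlab = "frequency (Hz)", ylab = ylab, ...)
  invisible(x)
}

#' Estimate a power spectrum from Still epochs
#'
#' Averaged modified periodogram (Welch) across sliding windows pooled over
#' all epochs with equal weight per window, so longer Still periods
#' contribute proportionally. Window length is `fs / resolution` samples
#' (2 s at 0.5 Hz resolution), 50% overlap. The `leakage` knob in \[0, 1\]
#' maps to a Kaiser taper with `beta = 40 * (1 - leakage)`: 1 is a
#' rectangular window (maximal leakage), smaller values taper harder. The
#' estimate is interpolated from the FFT bin grid onto the exact requested
#' grid `seq(fmin, fmax, resolution)`.
#'
#' @param epochs a `still_epochs` object, a list of numeric vectors, a bare
#'   numeric vector, or an `eeg_signal`.
#' @param fs sampling rate; taken from the object when available.
#' @param fmin,fmax,resolution output grid (Hz); defaults 0.1, 190, 0.5.
#' @param leakage spectral-leakage knob in \[0, 1\]; default 0.85.
#' @return a linear-scale `power_spectrum` (PSD, mV^2/Hz).
#' @export
compute_spectrum <- function(epochs, fs = NULL, fmin = 0.1, fmax = 190,
                             resolution = 0.5, leakage = 0.85) {
  if (inherits(epochs, "still_epochs")) {
    fs <- epochs$fs
    epochs <- epochs$epochs
  } else if (inherits(epochs, "eeg_signal")) {
    fs <- epochs$fs
    epochs <- list(epochs$signal)
  } else if (is.numeric(epochs)) {
    epochs <- list(as.numeric(epochs))
  }
  if (is.null(fs)) stop_fmt("fs must be given")
  if (fmax > fs / 2) stop_fmt("fmax %.1f Hz exceeds Nyquist %.1f Hz", fmax, fs / 2)
  if (leakage < 0 || leakage > 1) stop_fmt("leakage must be in [0, 1]")
  nwin <- round(fs / resolution)
  w <- kaiser_window(nwin, beta = 40 * (1 - leakage))
  u <- sum(w^2)
  step <- max(1L, floor(nwin / 2))
  acc <- NULL
  nseg <- 0L
  seconds <- 0
  for (ep in epochs) {
    if (length(ep) < nwin) {
      warn_fmt("epoch of %.2f s shorter than the %.2f s analysis window; skipped",
               length(ep) / fs, nwin / fs)
      next
    }
    seconds <- seconds + length(ep) / fs
    starts <- seq(1L, length(ep) - nwin + 1L, by = step)
    for (s0 in starts) {
      seg <- ep[s0:(s0 + nwin - 1L)]
      seg <- (seg - mean(seg)) * w
      sp <- stats::fft(seg)
      half <- floor(nwin / 2)
      p <- (Mod(sp[2:(half + 1L)])^2) * 2 / (fs * u)  # one-sided PSD
      if (nwin %% 2 == 0) p[half] <- p[half] / 2      # Nyquist bin has no mirror
      acc <- if (is.null(acc)) p else acc + p
      nseg <- nseg + 1L
    }
  }
  if (nseg == 0L) stop_fmt("no epoch long enough for the %.2f s analysis window", nwin / fs)
  p <- acc / nseg
  ffft <- (1:floor(nwin / 2)) * fs / nwin
  grid <- seq(fmin, fmax, by = resolution)
  pg <- stats::approx(ffft, p, xout = grid, rule = 2)$y
  power_spectrum(grid, pg, scale = "linear", n_epochs = length(epochs),
                 seconds = seconds,
                 meta = list(leakage = leakage, kaiser_beta = 40 * (1 - leakage),
                             window_s = nwin / fs, overlap = 0.5, n_windows = nseg))
}

kaiser_window <- function(n, beta) {
  if (beta <= 0) return(rep(1, n))
  i <- seq_len(n) - 1L
  r <- 2 * i / (n - 1L) - 1
  besselI(beta * sqrt(pmax(1 - r^2, 0)), 0) / besselI(beta, 0)
}

#' Convert a linear power spectrum to decibels
#'
#' `dB = 10 * log10(power)`.
#' @param spectrum a linear-scale `power_spectrum` with strictly positive
#'   power.
#' @return the spectrum on the dB scale.
#' @export
to_decibels <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (spectrum$scale == "dB") return(spectrum)
  if (any(spectrum$power <= 0))
    stop_fmt("non-positive power at %.2f Hz: cannot convert to dB (upstream failure?)",
             spectrum$freqs[which(spectrum$power <= 0)[1L]])
  out <- spectrum
  out$power <- 10 * log10(spectrum$power)
  out$scale <- "dB"
  out
}

#' Convert a dB spectrum back to linear power
#' @param spectrum a dB-scale `power_spectrum`.
#' @return the spectrum on the linear scale.
#' @export
from_decibels <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (spectrum$scale == "linear") return(spectrum)
  out <- spectrum
  out$power <- 10^(spectrum$power / 10)
  out$scale <- "linear"
  out
}

#' Remove mains-line peaks from a dB spectrum
#'
#' Replaces bins within `halfwidth_hz` of every harmonic of `base_hz` (up to
#' the top of the grid) by linear interpolation between the nearest flanking
#' bins. Idempotent; all other bins are untouched.
#'
#' @param spectrum a dB-scale `power_spectrum`.
#' @param base_hz mains frequency; default 50.
#' @param halfwidth_hz half-width of each notch (Hz); default 1.
#' @return the notched spectrum; notched harmonics recorded in `meta`.
#' @export
remove_line_noise <- function(spectrum, base_hz = 50, halfwidth_hz = 1.0) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (spectrum$scale != "dB") stop_fmt("remove_line_noise expects a dB spectrum")
  f <- spectrum$freqs
  y <- spectrum$power
  harmonics <- seq(base_hz, max(f), by = base_hz)
  for (h in harmonics) {
    idx <- which(abs(f - h) <= halfwidth_hz + 1e-9)
    if (!length(idx)) next
    lo <- min(idx) - 1L
    hi <- max(idx) + 1L
    if (lo < 1L && hi > length(f)) next
    if (lo < 1L) {
      warn_fmt("notch at %.0f Hz touches the low grid edge; one-sided fill", h)
      y[idx] <- y[hi]
    } else if (hi > length(f)) {
      warn_fmt("notch at %.0f Hz touches the high grid edge; one-sided fill", h)
      y[idx] <- y[lo]
    } else {
      y[idx] <- y[lo] + (y[hi] - y[lo]) * (f[idx] - f[lo]) / (f[hi] - f[lo])
    }
  }
  out <- spectrum
  out$power <- y
  out$meta$line_notch <- list(base_hz = base_hz, halfwidth_hz = halfwidth_hz,
                              harmonics = harmonics)
  out
}
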