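# Preprocessing: amplitude-threshold artifact masking and speed-based
# behavioral segmentation. Spectra downstream are computed on "Still" epochs
# only (which include quiet wakefulness and sleep; no sleep scoring is done).

#' Detect high-amplitude artifacts
#'
#' Marks every maximal run of samples with `|signal| > threshold` lasting
#' longer than `min_duration`, extends each run by `padding` seconds on both
#' sides, and merges overlapping padded intervals. Defaults are the
#' conventional rodent-EEG settings: 0.6 mV threshold, 1 s minimum duration,
#' 1.5 s padding.
#'
#' @param signal an `eeg_signal` or numeric vector (mV).
#' @param fs sampling rate; required for bare vectors.
#' @param threshold_mv amplitude threshold (mV), applied two-sided.
#' @param min_duration_s minimum supra-threshold run length (s); runs must be
#'   strictly longer than this to count.
#' @param padding_s seconds added on each side of a detected run.
#' @return an `epoch_mask`: data.frame of half-open intervals
#'   (`start_s`, `end_s`) with attribute `label = "artifact"`.
#' @export
detect_artifacts <- function(signal, fs = NULL, threshold_mv = 0.6,
                             min_duration_s = 1.0, padding_s = 1.5) {
  sv <- signal_vector(signal, fs)
  if (!is_number(threshold_mv) || threshold_mv <= 0) stop_fmt("threshold must be > 0")
  bad <- which(!is.finite(sv$x))
  if (length(bad))
    stop_fmt("non-finite sample at index %d (t = %.3f s)", bad[1L], (bad[1L] - 1L) / sv$fs)
  dur <- length(sv$x) / sv$fs
  over <- abs(sv$x) > threshold_mv
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / sv$fs > min_duration_s)
  iv <- as_intervals((starts[keep] - 1L) / sv$fs, ends[keep] / sv$fs)
  if (nrow(iv)) {
    iv$start_s <- iv$start_s - padding_s
    iv$end_s <- iv$end_s + padding_s
    iv <- clip_intervals(merge_intervals(iv), 0, dur)
  }
  epoch_mask(iv, "artifact", extent = dur)
}

epoch_mask <- function(intervals, label, extent) {
  iv <- merge_intervals(intervals)
  structure(iv, label = label, extent = extent, class = c("epoch_mask", "data.frame"))
}

#' Smooth a tracking trajectory with a Gaussian kernel
#'
#' Convolves `x_cm` and `y_cm` independently with a unit-mass truncated
#' Gaussian kernel of total support `window_s` (SD = support/6, the common
#' filter-design convention). Edges use renormalized partial kernels, so a
#' constant trajectory is returned unchanged and output length equals input
#' length.
#'
#' @param trajectory data.frame with `time_s`, `x_cm`, `y_cm`, uniformly
#'   sampled.
#' @param window_s kernel support in seconds; default 0.166 (166 ms).
#' @return smoothed trajectory, same shape.
#' @export
smooth_tracking <- function(trajectory, window_s = 0.166) {
  tr <- check_trajectory(trajectory)
  dt <- stats::median(diff(tr$time_s))
  m <- floor((window_s / dt - 1) / 2)   # samples per side; total support 2m+1 <= window
  if (2 * m + 1 < 2) {
    warn_fmt("smoothing window %.3g s is shorter than 2 samples at dt %.3g s; returning input", window_s, dt)
    return(tr)
  }
  sd_samp <- (window_s / 6) / dt
  kern <- stats::dnorm(-m:m, sd = sd_samp)
  kern <- kern / sum(kern)
  tr$x_cm <- conv_renorm(tr$x_cm, kern)
  tr$y_cm <- conv_renorm(tr$y_cm, kern)
  tr
}

# Convolution with edge renormalization: at the borders the kernel is cut to
# the valid samples and rescaled to unit mass.
conv_renorm <- function(x, kern) {
  n <- length(x)
  m <- (length(kern) - 1L) / 2L
  xp <- c(rep(NA_real_, m), x, rep(NA_real_, m))
  out <- numeric(n)
  for (i in seq_len(n)) {
    seg <- xp[i:(i + 2L * m)]
    ok <- !is.na(seg)
    out[i] <- sum(seg[ok] * kern[ok]) / sum(kern[ok])
  }
  out
}

check_trajectory <- function(trajectory) {
  tr <- as.data.frame(trajectory)
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(tr))) stop_fmt("trajectory needs columns %s", paste(need, collapse = ", "))
  d <- diff(tr$time_s)
  if (any(d <= 0)) stop_fmt("trajectory timestamps must be strictly increasing")
  if (length(d) > 1 && (max(d) - min(d)) / stats::median(d) > 0.1)
    warn_fmt("trajectory sampling jitter exceeds 10%%; speeds use per-sample dt")
  tr
}

#' Classify locomotion into Moving and Still segments
#'
#' Computes instantaneous center-of-mass speed by central differences of the
#' (already smoothed) positions and labels every maximal run with speed
#' strictly above `speed_cm_s` lasting at least `min_duration_s` as Moving.
#' The complement of the recording is Still. Defaults: 1 cm/s for at least
#' 1 s. Still includes both quiet wakefulness and sleep.
#'
#' @param trajectory data.frame with `time_s`, `x_cm`, `y_cm` (smooth first
#'   with [smooth_tracking()]).
#' @param speed_cm_s speed threshold (cm/s).
#' @param min_duration_s minimum Moving run length (s).
#' @return a `behavioral_segments` object: list with interval data.frames
#'   `still` and `moving` that partition the recording, plus `speed`
#'   (per-sample cm/s) and `extent_s`.
#' @export
classify_behavior <- function(trajectory, speed_cm_s = 1.0, min_duration_s = 1.0) {
  tr <- check_trajectory(trajectory)
  n <- nrow(tr)
  dt <- stats::median(diff(tr$time_s))
  extent <- tr$time_s[n] + dt
  v <- numeric(n)
  if (n >= 3) {
    i <- 2:(n - 1L)
    v[i] <- sqrt((tr$x_cm[i + 1L] - tr$x_cm[i - 1L])^2 +
                 (tr$y_cm[i + 1L] - tr$y_cm[i - 1L])^2) /
            (tr$time_s[i + 1L] - tr$time_s[i - 1L])
  }
  if (n >= 2) {
    v[1L] <- sqrt((tr$x_cm[2L] - tr$x_cm[1L])^2 + (tr$y_cm[2L] - tr$y_cm[1L])^2) /
             (tr$time_s[2L] - tr$time_s[1L])
    v[n] <- sqrt((tr$x_cm[n] - tr$x_cm[n - 1L])^2 + (tr$y_cm[n] - tr$y_cm[n - 1L])^2) /
            (tr$time_s[n] - tr$time_s[n - 1L])
  }
  over <- v > speed_cm_s
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt >= min_duration_s)
  moving <- as_intervals(tr$time_s[starts[keep]],
                         tr$time_s[ends[keep]] + dt)
  moving <- clip_intervals(merge_intervals(moving), 0, extent)
  still <- subtract_intervals(data.frame(start_s = 0, end_s = extent), moving)
  structure(list(still = still, moving = moving, speed = v, extent_s = extent),
            class = "behavioral_segments")
}

#' @export
print.behavioral_segments <- function(x, ...) {
  cat(sprintf("<behavioral_segments> %.1f s: still %.1f s (%d), moving %.1f s (%d)\n",
              x$extent_s, interval_duration(x$still), nrow(x$still),
              interval_duration(x$moving), nrow(x$moving)))
  invisible(x)
}

#' Extract artifact-free Still signal epochs
#'
#' Restricts the signal to Still intervals minus the artifact mask and drops
#' remnants shorter than `min_epoch_s` (which must cover at least one
#' spectral analysis window downstream).
#'
#' @param signal an `eeg_signal` or numeric vector.
#' @param segments a [classify_behavior()] result, or `NULL` to treat the
#'   whole recording as Still.
#' @param artifacts an `epoch_mask` from [detect_artifacts()], or `NULL`.
#' @param min_epoch_s minimum surviving epoch length (s).
#' @param fs sampling rate for bare vectors.
#' @return a `still_epochs` object: list with `epochs` (list of numeric
#'   vectors), `intervals`, `fs`, `total_s`, and `diagnostic` (character;
#'   non-empty when nothing survived).
#' @export
extract_still_epochs <- function(signal, segments = NULL, artifacts = NULL,
                                 min_epoch_s = 2, fs = NULL) {
  sv <- signal_vector(signal, fs)
  dur <- length(sv$x) / sv$fs
  still <- if (is.null(segments)) data.frame(start_s = 0, end_s = dur) else segments$still
  still <- clip_intervals(merge_intervals(still), 0, dur)
  if (!is.null(artifacts) && nrow(artifacts) > 0L)
    still <- subtract_intervals(still, as.data.frame(artifacts))
  still <- still[still$end_s - still$start_s >= min_epoch_s, , drop = FALSE]
  diag_msg <- character(0)
  epochs <- list()
  for (i in seq_len(nrow(still))) {
    i0 <- floor(still$start_s[i] * sv$fs + 1e-9) + 1L
    i1 <- floor(still$end_s[i] * sv$fs + 1e-9)
    epochs[[i]] <- sv$x[i0:min(i1, length(sv$x))]
  }
  if (!length(epochs)) {
    diag_msg <- sprintf(
      "no artifact-free Still epoch of >= %.3g s survives (recording %.1f s)",
      min_epoch_s, dur)
    warn_fmt("%s", diag_msg)
  }
  structure(list(epochs = epochs, intervals = still, fs = sv$fs,
                 total_s = interval_duration(still), diagnostic = diag_msg),
            class = "still_epochs")
}

#' @export
print.still_epochs <- function(x, ...) {
  cat(sprintf("<still_epochs> %d epochs, %.1f s total at %g Hz\n",
              length(x$epochs), x$total_s, x$fs))
  if (length(x$diagnostic)) cat(" diagnostic:", x$diagnostic, "\n")
  invisible(x)
}
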