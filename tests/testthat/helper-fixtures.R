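# Shared fixtures and independent oracles. Oracles are deliberately written
# as literal transcriptions, independent of the package implementation paths
# they check.

# Independent pointwise evaluator of the ground-truth spectrum model.
oracle_spectrum_model <- function(f, b, X, k, peaks = NULL, c_decay = NULL,
                                  d_decay = NULL, log_form = FALSE) {
  y <- if (log_form) b - 10 * log10(f^X + k) else b + 1 / (f^X + k)
  if (!is.null(c_decay)) y <- y + c_decay * exp(-d_decay * f)
  if (!is.null(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      y <- y + peaks$a[i] * exp(-(f - peaks$mu[i])^2 / (2 * peaks$sigma[i]^2))
    }
  }
  y
}

# Independent trapezoid rule.
oracle_trapz <- function(x, y) {
  n <- length(x)
  sum((x[2:n] - x[1:(n - 1)]) * (y[2:n] + y[1:(n - 1)]) / 2)
}

# Enumerate all sign-flip max-cluster-mass statistics for a paired design;
# brute force, independent of the package's vectorized path.
oracle_signflip_null <- function(d, thr) {
  n <- nrow(d)
  out <- numeric(2^n)
  for (i in seq_len(2^n)) {
    bits <- as.integer(intToBits(i - 1L))[1:n]
    s <- ifelse(bits == 1L, -1, 1)
    dd <- d * s
    m <- colMeans(dd)
    sdv <- apply(dd, 2, stats::sd)
    t <- m / (sdv / sqrt(n))
    t[!is.finite(t)] <- 0
    over <- abs(t) > thr
    best <- 0
    j <- 1L
    while (j <= length(t)) {
      if (over[j]) {
        j2 <- j
        while (j2 < length(t) && over[j2 + 1L]) j2 <- j2 + 1L
        best <- max(best, abs(sum(t[j:j2])))
        j <- j2 + 1L
      } else j <- j + 1L
    }
    out[i] <- best
  }
  out
}

# All permutations of 1..n, built by a different construction than the
# package's (repeated column-wise selection).
oracle_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  prev <- oracle_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, prev + (prev >= i))
    out <- rbind(out, block)
  }
  out
}

# A minimal spectral_fit wrapper for metric tests with known peaks.
fixture_fit <- function(peaks, freqs = default_freq_grid()) {
  ps <- power_spectrum(freqs, oracle_spectrum_model(freqs, 0, 1, 1e6, peaks),
                       scale = "dB")
  ap <- structure(list(family = "lorentzian", params = c(b = 0, X = 1, k = 1e6),
                       rmse = 0, fitted = rep(0, length(freqs)),
                       log_form = FALSE, freqs = freqs),
                  class = "aperiodic_fit")
  structure(list(spectrum = ps, aperiodic = ap, peaks = peaks,
                 rmse = 0, reconstruction = NULL, family_table = NULL),
            class = "spectral_fit")
}

# The vehicle-condition band limits used as a recurring fixture.
vehicle_limits <- c(5.3, 9.7, 19.3, 41.3, 70.5, 111.4)

# Mode centers whose pairwise midpoints sit exactly at vehicle_limits.
vehicle_mode_centers <- function() {
  cents <- 2.5
  for (v in vehicle_limits) cents <- c(cents, 2 * v - cents[length(cents)])
  cents
}
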