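# Inferential machinery: paired cluster-based permutation (CBP) testing on
# spectra, covariate residualization, rank-based normalization, and
# permutation-calibrated Spearman exposure-response correlations.

#' Paired cluster-based permutation test on spectra
#'
#' Per-bin paired t statistics are thresholded two-sided at the
#' `cluster_alpha` t quantile; contiguous supra-threshold bins form clusters
#' whose mass is the sum of t values (signed, so increase and decrease
#' clusters keep their direction). The null distribution is the maximum
#' absolute cluster mass over random sign flips of the subject difference
#' spectra; with `exact = TRUE` all `2^n` sign patterns are enumerated
#' instead. Monte-Carlo p uses the +1/+1 convention so p is never 0.
#'
#' @param spectra_a,spectra_b numeric matrices, subjects x bins, paired by
#'   row (condition A and B of the same subjects). `power_spectrum` lists are
#'   accepted via [spectra_matrix()].
#' @param n_perm number of random sign flips; default 1000.
#' @param cluster_alpha two-sided cluster-forming alpha; default 0.05.
#' @param seed integer seed for the sign flips.
#' @param exact enumerate all `2^n` sign patterns (n <= 16) instead of
#'   sampling.
#' @param freqs optional bin frequencies carried into the result.
#' @return a `cluster_result`: list with `clusters` (data.frame: start_bin,
#'   end_bin, start_hz, end_hz, mass, p), `t` (per-bin), `threshold`,
#'   `n_perm`, `exact`, `alpha_flags`.
#' @export
cbp_paired_test <- function(spectra_a, spectra_b, n_perm = 1000,
                            cluster_alpha = 0.05, seed = 1L, exact = FALSE,
                            freqs = NULL) {
  a <- as.matrix(spectra_a)
  b <- as.matrix(spectra_b)
  if (!all(dim(a) == dim(b))) stop_fmt("paired spectra matrices must match in shape")
  n <- nrow(a)
  if (n < 5L) stop_fmt("need >= 5 subject pairs, got %d", n)
  if (!exact && n_perm < 100) warn_fmt("n_perm = %d is low; p-values will be coarse", n_perm)
  if (exact && n > 16L) stop_fmt("exact enumeration limited to n <= 16")
  d <- a - b
  nb <- ncol(d)
  ss <- colSums(d^2)
  tstat_from_mean <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    t <- m / sqrt(pmax(v, 0) / n)
    t[!is.finite(t)] <- 0
    t
  }
  tobs <- tstat_from_mean(colMeans(d))
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  obs <- find_clusters(tobs, thr)
  signs <- if (exact) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                           nrow = n_perm))
  }
  M <- (signs %*% d) / n
  null_max <- apply(M, 1L, function(m) {
    cl <- find_clusters(tstat_from_mean(m), thr)
    if (nrow(cl)) max(abs(cl$mass)) else 0
  })
  if (nrow(obs)) {
    obs$p <- if (exact) {
      vapply(obs$mass, function(ms) mean(null_max >= abs(ms) - 1e-12), numeric(1))
    } else {
      vapply(obs$mass, function(ms)
        (1 + sum(null_max >= abs(ms) - 1e-12)) / (nrow(signs) + 1), numeric(1))
    }
    obs$start_hz <- if (!is.null(freqs)) freqs[obs$start_bin] else NA_real_
    obs$end_hz <- if (!is.null(freqs)) freqs[obs$end_bin] else NA_real_
  } else {
    obs$p <- numeric(0)
    obs$start_hz <- numeric(0)
    obs$end_hz <- numeric(0)
  }
  structure(
    list(clusters = obs, t = tobs, threshold = thr, n_perm = nrow(signs),
         exact = exact, freqs = freqs,
         alpha_flags = list(sig_05 = obs$start_bin[obs$p < 0.05],
                            sig_01 = obs$start_bin[obs$p < 0.01])),
    class = "cluster_result")
}

find_clusters <- function(t, thr) {
  over <- abs(t) > thr
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start_bin = starts[keep], end_bin = ends[keep],
    mass = vapply(keep, function(i) sum(t[starts[i]:ends[i]]), numeric(1)))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), threshold |t| > %.3f, %d permutations%s\n",
              nrow(x$clusters), x$threshold, x$n_perm,
              if (x$exact) " (exact)" else ""))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Stack per-subject spectra into a matrix
#'
#' @param spectra list of `power_spectrum` objects on a common grid.
#' @return subjects x bins matrix with the grid as an attribute.
#' @export
spectra_matrix <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  f0 <- spectra[[1L]]$freqs
  for (sp in spectra)
    if (!isTRUE(all.equal(sp$freqs, f0))) stop_fmt("spectra are not on a common grid")
  m <- do.call(rbind, lapply(spectra, function(sp) sp$power))
  attr(m, "freqs") <- f0
  m
}

#' Residualize a metric on experiment/age covariates
#'
#' Ordinary least-squares residuals of `values` on an intercept plus the
#' covariate columns. Zero-variance covariates are dropped (residualizing on
#' a constant is mean-centering); genuinely collinear covariates raise an
#' error naming the offending columns. Residuals sum to zero and are exactly
#' orthogonal to every covariate column.
#'
#' @param values numeric vector (one per animal).
#' @param covariates data.frame of regressors aligned with `values` (e.g.,
#'   experiment number and age in days); factors allowed.
#' @return numeric vector of residuals.
#' @export
residualize <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(values))
    stop_fmt("covariates rows (%d) must match values length (%d)",
             nrow(covariates), length(values))
  if (any(!is.finite(values))) stop_fmt("values must be finite")
  keep <- vapply(covariates, function(col) length(unique(col)) > 1L, logical(1))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0L) return(values - mean(values))
  X <- stats::model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_fmt("collinear covariate column(s): %s", paste(bad, collapse = ", "))
  }
  stats::lm.fit(X, values)$residuals
}

#' Rank-based inverse-normal transform
#'
#' Two-step transform applied when a normality check rejects: values are
#' ranked (average ranks for ties), converted to fractional ranks
#' `(r - 0.5)/n`, and mapped through the standard normal quantile function.
#' Strictly rank-preserving, so Spearman correlations are unchanged.
#'
#' @param values numeric vector, length >= 3, not all equal.
#' @return transformed values.
#' @export
transform_to_normal <- function(values) {
  if (length(values) < 3L) stop_fmt("need >= 3 values")
  if (any(!is.finite(values))) stop_fmt("values must be finite")
  if (length(unique(values)) == 1L)
    stop_fmt("all values are equal: ranks are undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

#' Permutation-calibrated Spearman correlation
#'
#' Spearman rank correlation (average ranks for ties) with a two-tailed
#' permutation p-value: `y` is shuffled `n_perm` times and p is the +1/+1
#' adjusted fraction of permuted `|rho|` at or above the observed `|rho|`.
#' With `exact = TRUE` all `n!` permutations are enumerated (n <= 8).
#'
#' @param x,y numeric vectors of equal length >= 4, neither constant.
#' @param n_perm number of random permutations; default 1000.
#' @param seed integer seed.
#' @param exact enumerate all permutations instead of sampling.
#' @return list with `rho`, `p`, `n`, `n_perm`, `exact`.
#' @export
spearman_perm <- function(x, y, n_perm = 1000, seed = 1L, exact = FALSE) {
  if (length(x) != length(y)) stop_fmt("x and y lengths differ")
  n <- length(x)
  if (n < 4L) stop_fmt("need >= 4 paired observations, got %d", n)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop_fmt("constant input: Spearman correlation undefined")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  perm_rhos <- if (exact) {
    if (n > 8L) stop_fmt("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    apply(perms, 1L, function(ix) stats::cor(rx, ry[ix]))
  } else {
    with_seed(seed, replicate(n_perm, stats::cor(rx, sample(ry))))
  }
  p <- if (exact) {
    mean(abs(perm_rhos) >= abs(rho) - 1e-12)
  } else {
    (1 + sum(abs(perm_rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  list(rho = rho, p = p, n = n, n_perm = length(perm_rhos), exact = exact)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- setdiff(seq_len(n), first)
    cbind(first, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Exposure-response correlation table
#'
#' For every spectral parameter (band amplitude, band AUC, band modal
#' frequency, and the aperiodic offset/exponent/knee), per region, computes
#' the permutation-calibrated Spearman correlation between plasma exposure
#' and the covariate-residualized parameter contrast. Amplitude, AUC and
#' aperiodic parameters use the difference of residuals, compound minus
#' vehicle; modal frequencies use the compound residual alone (a compound
#' can create a band absent under vehicle), dropping animals with no modal
#' frequency. Rows with too few animals or a degenerate (constant) contrast
#' are flagged, never silently omitted.
#'
#' @param metrics tidy band-metrics table from [band_metrics()] covering both
#'   conditions (columns animal, region, condition, band, amplitude_db,
#'   modal_freq_hz, auc_db_hz).
#' @param aperiodic optional data.frame with columns animal, region,
#'   condition, b, X, k.
#' @param exposures data.frame: animal, condition, exposure_ng_ml.
#' @param covariates data.frame: animal, plus regressor columns (experiment,
#'   age_days).
#' @param compound,vehicle condition labels.
#' @param n_perm,seed permutation settings; default 1000 permutations.
#' @param min_n minimum animals for a reported correlation; default 4.
#' @param exclude animal ids excluded up front (the accepted exclusion-list
#'   replacement for automated exposure-outlier detection).
#' @return `data.frame`: parameter, band, region, rho, p, n, contrast,
#'   flag ("" when computed; "insufficient_n" or "degenerate" otherwise).
#' @export
exposure_correlation <- function(metrics, aperiodic = NULL, exposures,
                                 covariates, compound, vehicle = "vehicle",
                                 n_perm = 1000, seed = 1L, min_n = 4,
                                 exclude = NULL) {
  metrics <- as.data.frame(metrics)
  exposures <- as.data.frame(exposures)
  covariates <- as.data.frame(covariates)
  if (!is.null(exclude)) {
    metrics <- metrics[!metrics$animal %in% exclude, , drop = FALSE]
    if (!is.null(aperiodic)) aperiodic <- aperiodic[!aperiodic$animal %in% exclude, , drop = FALSE]
  }
  expo <- exposures[exposures$condition == compound, c("animal", "exposure_ng_ml")]
  cov_cols <- setdiff(names(covariates), "animal")
  out <- list()
  irow <- 0L
  add_row <- function(parameter, band, region, res) {
    irow <<- irow + 1L
    out[[irow]] <<- data.frame(parameter = parameter, band = band,
                               region = region, rho = res$rho, p = res$p,
                               n = res$n, contrast = res$contrast,
                               flag = res$flag)
  }
  run_one <- function(comp_vals, veh_vals, animals, contrast_type) {
    df <- data.frame(animal = animals, comp = comp_vals)
    if (contrast_type == "vehicle_difference") df$veh <- veh_vals
    df <- df[stats::complete.cases(df), , drop = FALSE]
    df <- merge(df, expo, by = "animal")
    df <- merge(df, covariates, by = "animal")
    if (nrow(df) < min_n) {
      return(list(rho = NA_real_, p = NA_real_, n = nrow(df),
                  contrast = contrast_type, flag = "insufficient_n"))
    }
    cv <- df[, cov_cols, drop = FALSE]
    contrast <- tryCatch({
      if (contrast_type == "vehicle_difference") {
        residualize(df$comp, cv) - residualize(df$veh, cv)
      } else {
        residualize(df$comp, cv)
      }
    }, error = function(e) NULL)
    if (is.null(contrast) || length(unique(round(contrast, 12))) == 1L) {
      return(list(rho = NA_real_, p = NA_real_, n = nrow(df),
                  contrast = contrast_type, flag = "degenerate"))
    }
    sp <- tryCatch(
      spearman_perm(df$exposure_ng_ml, contrast, n_perm = n_perm, seed = seed),
      error = function(e) NULL)
    if (is.null(sp)) {
      return(list(rho = NA_real_, p = NA_real_, n = nrow(df),
                  contrast = contrast_type, flag = "degenerate"))
    }
    list(rho = sp$rho, p = sp$p, n = sp$n, contrast = contrast_type, flag = "")
  }
  pivot <- function(df, col, region, band = NULL) {
    sel <- df$region == region
    if (!is.null(band)) sel <- sel & df$band == band
    d <- df[sel, , drop = FALSE]
    co <- d[d$condition == compound, c("animal", col)]
    ve <- d[d$condition == vehicle, c("animal", col)]
    names(co)[2L] <- "comp"
    names(ve)[2L] <- "veh"
    merge(co, ve, by = "animal", all = TRUE)
  }
  for (region in unique(metrics$region)) {
    for (band in unique(metrics$band[metrics$region == region])) {
      for (par in c("amplitude_db", "auc_db_hz")) {
        w <- pivot(metrics, par, region, band)
        add_row(sub("_db.*", "", par), band, region,
                run_one(w$comp, w$veh, w$animal, "vehicle_difference"))
      }
      w <- pivot(metrics, "modal_freq_hz", region, band)
      add_row("modal_frequency", band, region,
              run_one(w$comp, NULL, w$animal, "compound_only"))
    }
  }
  if (!is.null(aperiodic)) {
    for (region in unique(aperiodic$region)) {
      for (par in intersect(c("b", "X", "k"), names(aperiodic))) {
        w <- pivot(aperiodic, par, region)
        add_row(switch(par, b = "offset", X = "exponent", k = "knee"),
                NA_character_, region,
                run_one(w$comp, w$veh, w$animal, "vehicle_difference"))
      }
    }
  }
  do.call(rbind, out)
}
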