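# Plain-text serialization: every intermediate artifact is TSV or JSON so
# pipeline runs are diffable and individually re-runnable.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Serialize a spectral fit to JSON
#'
#' @param fit a `spectral_fit`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_spectral_fit <- function(fit, path) {
  stopifnot(inherits(fit, "spectral_fit"))
  obj <- list(
    aperiodic = c(list(family = fit$aperiodic$family),
                  as.list(fit$aperiodic$params),
                  list(rmse = fit$aperiodic$rmse, log_form = fit$aperiodic$log_form)),
    peaks = fit$peaks,
    rmse = fit$rmse)
  if (!is.null(fit$family_table)) obj$family_table <- fit$family_table
  write_json(obj, path)
}

#' Serialize a band scheme to JSON and TSV
#'
#' Writes `<stem>.json` (limits, labels, KDE metadata) and `<stem>.tsv`
#' (the band-limits table from [format_band_scheme()]).
#'
#' @param scheme a `band_scheme`.
#' @param stem output path without extension.
#' @return the JSON path, invisibly.
#' @export
write_band_scheme <- function(scheme, stem) {
  stopifnot(inherits(scheme, "band_scheme"))
  write_tsv(format_band_scheme(scheme), paste0(stem, ".tsv"))
  write_json(list(condition = scheme$condition, limits = scheme$limits,
                  labels = scheme$labels, method = scheme$method,
                  kde = if (!is.null(scheme$kde))
                    list(bandwidth = scheme$kde$bandwidth, n = scheme$kde$n)),
             paste0(stem, ".json"))
}

#' Write a power spectrum as TSV
#' @param spectrum a `power_spectrum`.
#' @param path output file; columns `freq_hz` and `power_db` or
#'   `power_linear`.
#' @return the path, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  col <- if (spectrum$scale == "dB") "power_db" else "power_linear"
  df <- stats::setNames(data.frame(spectrum$freqs, spectrum$power),
                        c("freq_hz", col))
  write_tsv(df, path)
}

#' Read a power spectrum from TSV
#' @param path a file written by [write_spectrum()].
#' @return a `power_spectrum`.
#' @export
read_spectrum <- function(path) {
  df <- read_tsv(path)
  scale <- if ("power_db" %in% names(df)) "dB" else "linear"
  power_spectrum(df$freq_hz, df[[2L]], scale = scale)
}
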