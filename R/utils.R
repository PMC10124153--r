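# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded generators never perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

# Deterministic fan-out of one pipeline seed into per-stage seeds.
# Kept strictly below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, stage, index = 0L) {
  base <- as.numeric(seed) %% 1000003
  as.integer((base * 1009 + as.numeric(stage) * 101 + as.numeric(index) * 7) %% 2147483587)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
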