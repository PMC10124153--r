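# Half-open interval algebra on data.frames with columns start_s, end_s.
# All preprocessing masks and behavioral segments are represented this way:
# [start_s, end_s), seconds from recording onset.

empty_intervals <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0))
}

as_intervals <- function(start_s, end_s) {
  stopifnot(length(start_s) == length(end_s))
  iv <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
  iv[iv$end_s > iv$start_s, , drop = FALSE]
}

# Sort and merge overlapping or touching intervals.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(empty_intervals())
  iv <- iv[order(iv$start_s, iv$end_s), , drop = FALSE]
  out_s <- iv$start_s[1L]
  out_e <- iv$end_s[1L]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      if (iv$start_s[i] <= out_e[length(out_e)]) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end_s[i])
      } else {
        out_s <- c(out_s, iv$start_s[i])
        out_e <- c(out_e, iv$end_s[i])
      }
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}

# Set difference a \ b for merged interval sets.
subtract_intervals <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  if (nrow(a) == 0L) return(empty_intervals())
  if (nrow(b) == 0L) return(a)
  res_s <- numeric(0)
  res_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    s <- a$start_s[i]
    e <- a$end_s[i]
    cur <- s
    for (j in seq_len(nrow(b))) {
      bs <- b$start_s[j]
      be <- b$end_s[j]
      if (be <= cur || bs >= e) next
      if (bs > cur) {
        res_s <- c(res_s, cur)
        res_e <- c(res_e, bs)
      }
      cur <- max(cur, be)
      if (cur >= e) break
    }
    if (cur < e) {
      res_s <- c(res_s, cur)
      res_e <- c(res_e, e)
    }
  }
  data.frame(start_s = res_s, end_s = res_e)
}

# Intersection a & b for merged interval sets.
intersect_intervals <- function(a, b) {
  a <- merge_intervals(a)
  subtract_intervals(a, subtract_intervals(a, b))
}

# Clip intervals to [lo, hi).
clip_intervals <- function(iv, lo, hi) {
  iv$start_s <- pmax(iv$start_s, lo)
  iv$end_s <- pmin(iv$end_s, hi)
  iv[iv$end_s > iv$start_s, , drop = FALSE]
}

interval_duration <- function(iv) sum(iv$end_s - iv$start_s)
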