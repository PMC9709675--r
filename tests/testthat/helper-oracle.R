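# Independent brute-force oracle for the two-pass smoothing algorithm:
# literal nested loops over windows and days, character vectors throughout,
# no sliding counts or integer coding. Deliberately kept naive so it shares
# no code path with the package implementation.

oracle_smooth <- function(values, wt) {
  n <- length(values)
  wl <- min(wt, n)
  n_win <- n - wl + 1L

  # pass 1: one assignment per window, ties carry the previous window forward
  assignments <- character(n_win)
  for (k in seq_len(n_win)) {
    win <- values[k:(k + wl - 1L)]
    distinct <- unique(win)
    counts <- vapply(distinct, function(d) sum(win == d), integer(1))
    tied <- distinct[counts == max(counts)]
    if (length(tied) == 1L) {
      assignments[k] <- tied
    } else if (k > 1L) {
      assignments[k] <- assignments[k - 1L]
    } else {
      first_pos <- vapply(tied, function(d) which(win == d)[1L], integer(1))
      assignments[k] <- tied[which.min(first_pos)]
    }
  }

  # pass 2: per-day vote over every window covering the day
  out <- character(n)
  for (i in seq_len(n)) {
    cands <- character(0)
    for (k in seq_len(n_win)) {
      if (k <= i && i <= k + wl - 1L) cands <- c(cands, assignments[k])
    }
    distinct <- unique(cands)
    counts <- vapply(distinct, function(d) sum(cands == d), integer(1))
    tied <- distinct[counts == max(counts)]
    if (length(tied) == 1L) {
      out[i] <- tied
    } else if (i > 1L && out[i - 1L] %in% tied) {
      out[i] <- out[i - 1L]
    } else {
      out[i] <- cands[cands %in% tied][1L]
    }
  }
  out
}
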