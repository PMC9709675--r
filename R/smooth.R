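#' Most frequent combination in a window, with tie carry-forward
#'
#' The elementary step of pass 1: given the combinations observed in one
#' window, return the combination occupying the most days. When two or more
#' combinations tie for the maximum, the previously assigned treatment is
#' carried forward; in the first window, where no previous assignment exists,
#' the tied combination whose first occurrence in the window is earliest wins
#' (prefer what was already happening).
#'
#' @param window character vector of canonical combination strings (the days
#'   of one window, in order). Must be non-empty.
#' @param previous the previous window's assignment (length-1 character), or
#'   `NULL` for the first window.
#' @return a length-1 canonical combination string.
#' @examples
#' window_mode(rep(c("A", "B"), c(6, 4)), previous = "B")  # "A"
#' window_mode(rep(c("A", "B"), c(5, 5)), previous = "B")  # tie -> "B"
#' window_mode(rep(c("A", "B"), c(5, 5)))                  # tie, no previous -> "A"
#' @export
window_mode <- function(window, previous = NULL) {
  if (length(window) == 0L) stop("window must be non-empty")
  lev <- unique(window)
  counts <- tabulate(match(window, lev), nbins = length(lev))
  mx <- max(counts)
  tied <- lev[counts == mx]
  if (length(tied) == 1L) return(tied)
  if (!is.null(previous)) return(as.character(previous))
  tied[which.min(match(tied, window))[1L]]  # lev is in first-occurrence order
}

#' Pass 1: window-mode candidates for every day
#'
#' Slides a window of `wt` days across the series one day at a time (start
#' positions day 0 to day N - wt; only full-length windows are used) and
#' assigns to each window its most frequent combination via [window_mode()],
#' carrying the previous window's assignment forward on ties. Each window's
#' assignment is recorded as a candidate for every day it covers, so interior
#' days accrue up to `wt` candidates while days near either edge accrue
#' fewer. When the series is shorter than `wt`, a single window spanning the
#' whole series is used.
#'
#' @param series an [exposure_series()]; must be non-empty.
#' @param wt positive integer window length in days.
#' @return a `candidate_matrix` object: the per-window assignments plus the
#'   effective window length, from which the per-day candidate multisets are
#'   read with [day_candidates()].
#' @export
pass1_candidates <- function(series, wt) {
  stopifnot(inherits(series, "exposure_series"))
  n <- length(series)
  if (n == 0L) stop("series must be non-empty")
  wt <- check_wt(wt)
  lev <- unique(series$values)
  codes <- match(series$values, lev)
  m <- length(lev)
  wl <- min(wt, n)
  k <- n - wl + 1L
  assign <- integer(k)
  counts <- tabulate(codes[seq_len(wl)], nbins = m)
  for (w in seq_len(k)) {
    if (w > 1L) {
      counts[codes[w - 1L]] <- counts[codes[w - 1L]] - 1L
      counts[codes[w + wl - 1L]] <- counts[codes[w + wl - 1L]] + 1L
    }
    mx <- max(counts)
    tied <- which(counts == mx)
    if (length(tied) == 1L) {
      assign[w] <- tied
    } else if (w > 1L) {
      assign[w] <- assign[w - 1L]  # carry the previous treatment forward
    } else {
      win <- codes[seq_len(wl)]
      assign[w] <- win[which(win %in% tied)[1L]]
    }
  }
  structure(
    list(assignments = assign, levels = lev, window = wl, n_days = n),
    class = "candidate_matrix"
  )
}

#' @rdname pass1_candidates
#' @param candidates a `candidate_matrix`.
#' @param day 1-based day index.
#' @return for `day_candidates()`, the character vector of candidates for
#'   that day, ordered by the window that produced them (earliest first).
#' @export
day_candidates <- function(candidates, day) {
  stopifnot(inherits(candidates, "candidate_matrix"))
  k <- length(candidates$assignments)
  wl <- candidates$window
  stopifnot(day >= 1L, day <= candidates$n_days)
  lo <- max(1L, day - wl + 1L)
  hi <- min(k, day)
  candidates$levels[candidates$assignments[lo:hi]]
}

#' @export
print.candidate_matrix <- function(x, ...) {
  cat(sprintf("<candidate_matrix> %d day(s), %d window(s) of length %d\n",
              x$n_days, length(x$assignments), x$window))
  invisible(x)
}

#' Pass 2: per-day majority vote over candidates
#'
#' For each day, chooses the candidate with the highest multiplicity among
#' the assignments of all windows covering that day. Ties are broken first by
#' the previous day's final choice when it is among the tied candidates, and
#' otherwise by the tied candidate produced by the earliest window --
#' continuity first, then precedence.
#'
#' @param candidates a `candidate_matrix` from [pass1_candidates()].
#' @return character vector of final per-day combinations.
#' @export
pass2_vote <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_matrix"))
  assign <- candidates$assignments
  k <- length(assign)
  wl <- candidates$window
  n <- candidates$n_days
  m <- length(candidates$levels)
  out <- integer(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - wl + 1L)
    hi <- min(k, i)
    cand <- assign[lo:hi]
    counts <- tabulate(cand, nbins = m)
    mx <- max(counts)
    tied <- which(counts == mx)
    if (length(tied) == 1L) {
      out[i] <- tied
    } else if (i > 1L && out[i - 1L] %in% tied) {
      out[i] <- out[i - 1L]
    } else {
      out[i] <- cand[which(cand %in% tied)[1L]]
    }
  }
  candidates$levels[out]
}

#' Smooth a daily exposure series
#'
#' The two-pass smoothing algorithm for noisy categorical treatment series:
#' pass 1 slides a window of `wt` days across the series and assigns each
#' window its most frequent combination (ties carry the previous window's
#' treatment forward); pass 2 then picks, for every day, the candidate most
#' frequently proposed by the windows covering it. The result is the most
#' likely therapy per day, with short spurious runs absorbed into the
#' surrounding regimen.
#'
#' `wt` is the only parameter. With `wt = 1` the data are unchanged; as `wt`
#' grows towards the follow-up length the series collapses towards its single
#' most frequent combination. Untreated gaps (`"NONE"`) are an ordinary
#' category: they can survive smoothing or be smoothed away like any other
#' combination. The algorithm is fully deterministic.
#'
#' @param series an [exposure_series()]; must be non-empty.
#' @param wt positive integer window length in days; values larger than the
#'   series length behave like `wt = length(series)`.
#' @return an [exposure_series()] of identical length, origin and patient id;
#'   every output combination occurs somewhere in the input.
#' @examples
#' s <- exposure_series("p1", as.Date("2019-01-01"),
#'                      rep(c("A", "A+B", "A"), c(20, 3, 20)))
#' smooth_series(s, wt = 10)   # the 3-day A+B blip is smoothed to A
#' @export
smooth_series <- function(series, wt) {
  cm <- pass1_candidates(series, wt)
  exposure_series(series$patient_id, series$origin, pass2_vote(cm))
}

check_wt <- function(wt) {
  if (length(wt) != 1L || is.na(wt) || wt < 1 || wt != as.integer(wt)) {
    stop("'wt' must be a single positive integer number of days")
  }
  as.integer(wt)
}
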