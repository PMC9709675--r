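#' Persistence-threshold comparator ("traditional" method)
#'
#' The simple approach commonly used to de-noise electronic drug records: the
#' series starts with the first treatment observed and a change of treatment
#' is accepted only when the new combination persists at least `min_duration`
#' days; shorter runs are rewritten to the incumbent treatment. Typical
#' thresholds are 60 days for chronic medication and 15 days for short-term
#' drugs such as systemic antibiotics.
#'
#' Runs are of exact combinations: a 20-day run of B interrupted by one day
#' of C counts as two separate short runs, each judged on its own. A terminal
#' run cut short by the end of follow-up is accepted as a change even when
#' shorter than `min_duration` -- rewriting it would fabricate exposure beyond
#' the observed data -- and is flagged via the `censored` attribute of the
#' result.
#'
#' @param series an [exposure_series()].
#' @param min_duration positive integer: minimum persistence, in days, for a
#'   new combination to be accepted (default 60).
#' @return an [exposure_series()] of the same length; attribute `censored` is
#'   `TRUE` when the last run was accepted without reaching `min_duration`.
#' @examples
#' s <- exposure_series("p", as.Date("2019-01-01"),
#'                      rep(c("A", "B", "A"), c(30, 20, 50)))
#' traditional_series(s, min_duration = 60)  # the 20-day B run is rewritten
#' @export
traditional_series <- function(series, min_duration = 60L) {
  stopifnot(inherits(series, "exposure_series"))
  if (length(min_duration) != 1L || is.na(min_duration) || min_duration < 1 ||
      min_duration != as.integer(min_duration)) {
    stop("'min_duration' must be a single positive integer")
  }
  n <- length(series)
  if (n == 0L) {
    out <- series
    attr(out, "censored") <- FALSE
    return(out)
  }
  r <- rle(series$values)
  vals <- r$values
  accepted <- vals[1L]
  censored <- FALSE
  nruns <- length(vals)
  for (j in seq_len(nruns)[-1L]) {
    if (vals[j] == accepted) next
    if (r$lengths[j] >= min_duration) {
      accepted <- vals[j]
    } else if (j == nruns) {
      # run truncated by end of follow-up: accept, but flag as censored
      accepted <- vals[j]
      censored <- TRUE
    } else {
      vals[j] <- accepted
    }
  }
  out <- exposure_series(series$patient_id, series$origin,
                         rep(vals, r$lengths))
  attr(out, "censored") <- censored
  out
}
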