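#' Smoothing-impact statistics for one patient
#'
#' Compares an original daily series with its transformed (smoothed or
#' threshold-filtered) version and reports the per-patient impact: the number
#' of days whose combination changed and the percent smoothed, defined as
#' 100 x (days changed) / (days under active prescription in the original
#' series). Changes the algorithm makes to untreated gap days count in the
#' numerator; the denominator counts only days with a non-empty combination,
#' so the percentage can exceed 100 when many gap days are rewritten.
#'
#' @param original,transformed [exposure_series()] objects of equal length
#'   and origin.
#' @return one-row data.frame: `patient_id`, `days_changed`, `active_days`,
#'   `percent_smoothed`, `changed_flag`.
#' @export
compare_series <- function(original, transformed) {
  stopifnot(inherits(original, "exposure_series"),
            inherits(transformed, "exposure_series"))
  if (length(original) != length(transformed) ||
      original$origin != transformed$origin) {
    stop("series must have equal length and origin to be compared")
  }
  days_changed <- sum(original$values != transformed$values)
  active_days <- sum(original$values != NONE_LABEL)
  data.frame(
    patient_id = original$patient_id,
    days_changed = days_changed,
    active_days = active_days,
    percent_smoothed = if (active_days > 0L) 100 * days_changed / active_days
                       else NA_real_,
    changed_flag = days_changed >= 1L,
    stringsAsFactors = FALSE
  )
}

#' Window-size simulation over a cohort
#'
#' Runs the smoothing algorithm on every patient of a cohort for each window
#' length in `wt_grid` and aggregates the impact: how many patients saw at
#' least one day changed, and the median and interquartile range of the
#' percent smoothed among those changed patients. This is the harness for
#' studying how the choice of `wt` drives the level of smoothing; the default
#' grid is 10, 20, 30, 45, 60 and 90 days.
#'
#' @param cohort a list of [exposure_series()] objects (non-empty).
#' @param wt_grid vector of positive integer window lengths.
#' @return data.frame with one row per `wt`: `wt`, `n_patients`, `n_changed`,
#'   `prop_changed`, `pct_smoothed_median`, `pct_smoothed_q1`,
#'   `pct_smoothed_q3` (quartiles over changed patients, type-7 linear
#'   interpolation; `NA` when no patient changed).
#' @export
run_simulation <- function(cohort, wt_grid = c(10L, 20L, 30L, 45L, 60L, 90L)) {
  stopifnot(length(cohort) > 0L, length(wt_grid) > 0L)
  wt_grid <- vapply(wt_grid, check_wt, integer(1))
  rows <- lapply(wt_grid, function(wt) {
    reports <- do.call(rbind, lapply(cohort, function(s) {
      compare_series(s, smooth_series(s, wt))
    }))
    pct <- reports$percent_smoothed[reports$changed_flag]
    q <- if (length(pct) > 0L) stats::quantile(pct, c(.25, .5, .75),
                                               type = 7, names = FALSE)
         else rep(NA_real_, 3L)
    data.frame(
      wt = wt,
      n_patients = nrow(reports),
      n_changed = sum(reports$changed_flag),
      prop_changed = mean(reports$changed_flag),
      pct_smoothed_median = q[2L],
      pct_smoothed_q1 = q[1L],
      pct_smoothed_q3 = q[3L]
    )
  })
  do.call(rbind, rows)
}

#' Power of the chi-square test for a given effect size
#'
#' Computes the power of Pearson's chi-square test at significance level
#' `alpha` with `df` degrees of freedom, sample size `n` and Cohen's effect
#' size `w`: the probability that a noncentral chi-square variable with
#' noncentrality n * w^2 exceeds the central critical value. Used for the
#' sample-size determination of validation studies that compare two
#' data-cleaning methods on the same patients.
#'
#' @param w positive effect size (Cohen's w); `w = 0` returns `alpha`.
#' @param df positive integer degrees of freedom.
#' @param alpha significance level in (0, 1).
#' @param n positive integer sample size.
#' @return the power, a probability.
#' @examples
#' chi_square_power(w = 0.3062, df = 2, alpha = 0.05, n = 400)
#' @export
chi_square_power <- function(w, df, alpha, n) {
  if (length(w) != 1L || is.na(w) || w < 0) stop("'w' must be >= 0")
  if (length(df) != 1L || is.na(df) || df < 1 || df != as.integer(df)) {
    stop("'df' must be a positive integer")
  }
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)")
  }
  if (length(n) != 1L || is.na(n) || n < 1) stop("'n' must be >= 1")
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = n * w^2, lower.tail = FALSE)
}

#' @rdname chi_square_power
#' @param power target power in (0, 1).
#' @return for `chi_square_min_n()`, the smallest integer sample size whose
#'   power reaches `power`.
#' @export
chi_square_min_n <- function(w, df, alpha, power = 0.8) {
  if (w <= 0) stop("'w' must be positive to reach any power above alpha")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)")
  n <- 1L
  while (chi_square_power(w, df, alpha, n) < power) {
    n <- n + 1L
    if (n > 1e7) stop("no feasible n below 1e7")
  }
  n
}
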