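#' Daily drug-exposure series
#'
#' An `exposure_series` is the day-indexed record of one patient's treatment:
#' one canonical combination string (see [combination()]) per consecutive
#' calendar day, starting at `origin` (day index 0). It is the central object
#' of the package: raw prescription intervals are expanded into it
#' ([expand_to_daily()]), the smoothing and persistence-threshold methods
#' transform it ([smooth_series()], [traditional_series()]), and
#' [collapse_to_episodes()] turns it back into analysis-ready episodes.
#'
#' Interior days with no covering prescription carry the explicit `"NONE"`
#' combination, so untreated gaps are a first-class category that participates
#' in smoothing. Days before the first and after the last active day are
#' outside the series.
#'
#' @param patient_id length-1 character, opaque patient identifier.
#' @param origin a `Date`: the calendar date of day index 0.
#' @param values character vector of canonical combination strings, one per
#'   day. May be empty (the empty-series sentinel).
#' @return an object of class `exposure_series`.
#' @export
exposure_series <- function(patient_id, origin, values) {
  stopifnot(length(patient_id) == 1L, !is.na(patient_id))
  origin <- as.Date(origin)
  stopifnot(length(origin) == 1L)
  values <- as.character(values)
  if (anyNA(values)) stop("series values must not contain NA")
  structure(
    list(patient_id = as.character(patient_id), origin = origin,
         values = values),
    class = "exposure_series"
  )
}

#' @export
length.exposure_series <- function(x) length(x$values)

#' @export
print.exposure_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<exposure_series> patient %s: %d day(s)", x$patient_id, n))
  if (n > 0L) {
    cat(sprintf(" from %s to %s\n", format(x$origin),
                format(x$origin + n - 1L)))
    ep <- collapse_to_episodes(x)
    cat(sprintf("  %d episode(s): %s\n", nrow(ep),
                paste(utils::head(ep$combination, 6L), collapse = " | ")))
  } else cat(" (empty)\n")
  invisible(x)
}

#' @export
as.data.frame.exposure_series <- function(x, ...) {
  n <- length(x)
  data.frame(
    patient_id = rep(x$patient_id, n),
    date = if (n > 0L) x$origin + seq_len(n) - 1L else as.Date(character()),
    combination = x$values,
    stringsAsFactors = FALSE
  )
}

#' @export
`==.exposure_series` <- function(e1, e2) {
  identical(e1$patient_id, e2$patient_id) &&
    identical(e1$origin, e2$origin) && identical(e1$values, e2$values)
}

#' Resolve dispensation records into date intervals
#'
#' Dispensation (invoice) records give only the month a package was collected
#' and how many packages, not an end date. The end of treatment is inferred
#' from the package count: the interval starts on the first day of the
#' dispensation month and covers `packages * days_per_package` days.
#'
#' @param records a data.frame of prescription records in dispensation form:
#'   columns `patient_id`, `drug_code`, `month` (a `Date` pointing anywhere in
#'   the dispensation month) and `packages` (positive integer). Rows already
#'   in interval form (non-missing `end`) are a misuse and raise an error;
#'   use [normalize_records()] on mixed tables.
#' @param days_per_package positive integer, assumed coverage per package
#'   (default 30). `per_drug` supplies per-drug overrides.
#' @param per_drug optional named integer vector of drug-code-specific
#'   `days_per_package` values.
#' @return the records in interval form (`start`, `end` `Date` columns,
#'   both inclusive).
#' @examples
#' r <- data.frame(patient_id = "p1", drug_code = "J01CA04",
#'                 month = as.Date("2019-03-01"), packages = 3L)
#' resolve_dispensation(r, days_per_package = 30)  # 2019-03-01 .. 2019-05-29
#' @export
resolve_dispensation <- function(records, days_per_package = 30L,
                                 per_drug = NULL) {
  if (length(days_per_package) != 1L || is.na(days_per_package) ||
      days_per_package < 1) {
    stop("'days_per_package' must be a single positive integer")
  }
  if (!is.null(per_drug) && (is.null(names(per_drug)) || any(per_drug < 1))) {
    stop("'per_drug' must be a named vector of positive integers")
  }
  if (nrow(records) == 0L) return(interval_records(records))
  if (!is.null(records$end) && any(!is.na(records$end))) {
    stop("records already in interval form; resolve_dispensation() expects ",
         "dispensation-form records only")
  }
  if (is.null(records$month) || is.null(records$packages) ||
      anyNA(records$month) || anyNA(records$packages)) {
    stop("dispensation-form records need non-missing 'month' and 'packages'")
  }
  if (any(records$packages < 1)) stop("'packages' must be >= 1")
  dpp <- rep(as.integer(days_per_package), nrow(records))
  if (!is.null(per_drug)) {
    hit <- match(records$drug_code, names(per_drug))
    dpp[!is.na(hit)] <- as.integer(per_drug[hit[!is.na(hit)]])
  }
  month <- as.Date(records$month)
  start <- as.Date(format(month, "%Y-%m-01"))
  out <- data.frame(
    patient_id = as.character(records$patient_id),
    drug_code = as.character(records$drug_code),
    start = start,
    end = start + records$packages * dpp - 1L,
    stringsAsFactors = FALSE
  )
  out
}

#' Normalize a mixed record table to interval form
#'
#' Convenience wrapper used by the pipeline: rows with a non-missing `end`
#' pass through unchanged; rows in dispensation form go through
#' [resolve_dispensation()].
#'
#' @inheritParams resolve_dispensation
#' @export
normalize_records <- function(records, days_per_package = 30L,
                              per_drug = NULL) {
  if (nrow(records) == 0L) return(interval_records(records))
  has_end <- !is.null(records$end) & if (is.null(records$end)) FALSE else
    !is.na(records$end)
  iv <- interval_records(records[has_end, , drop = FALSE])
  dp <- records[!has_end, , drop = FALSE]
  if (nrow(dp) > 0L) {
    dp$end <- NULL
    dp <- resolve_dispensation(dp, days_per_package, per_drug)
  } else dp <- interval_records(dp)
  out <- rbind(iv, dp)
  out[order(out$patient_id, out$start, out$drug_code), , drop = FALSE]
}

# coerce to the canonical interval-form column set
interval_records <- function(records) {
  data.frame(
    patient_id = as.character(records$patient_id),
    drug_code = as.character(records$drug_code),
    start = as.Date(if (is.null(records$start)) character() else
      records$start),
    end = as.Date(if (is.null(records$end)) character() else records$end),
    stringsAsFactors = FALSE
  )
}

#' Expand prescription intervals into a daily exposure series
#'
#' The data-mining step preceding any smoothing: for every calendar day from
#' the patient's earliest prescription start to the latest end, collect the
#' set of drug codes whose interval covers that day. Overlapping or duplicate
#' records of the same drug contribute that drug once; days covered by no
#' record become the explicit `"NONE"` combination.
#'
#' @param records data.frame of interval-form records (columns `patient_id`,
#'   `drug_code`, `start`, `end`, dates inclusive) for a single patient.
#' @return an [exposure_series()]; the empty-series sentinel when `records`
#'   has no rows.
#' @examples
#' r <- data.frame(patient_id = "p1",
#'                 drug_code = c("A", "B"),
#'                 start = as.Date(c("2019-01-01", "2019-01-05")),
#'                 end   = as.Date(c("2019-01-10", "2019-01-15")))
#' expand_to_daily(r)
#' @export
expand_to_daily <- function(records) {
  if (nrow(records) == 0L) {
    return(exposure_series("<empty>", as.Date("1970-01-01"), character()))
  }
  pid <- unique(as.character(records$patient_id))
  if (length(pid) != 1L) {
    stop("expand_to_daily() takes records for a single patient; got ids: ",
         paste(pid, collapse = ", "))
  }
  start <- as.Date(records$start)
  end <- as.Date(records$end)
  if (anyNA(start) || anyNA(end)) stop("records must be in interval form")
  if (any(start > end)) stop("record start after end")
  origin <- min(start)
  n <- as.integer(max(end) - origin) + 1L
  drugs <- sort(unique(as.character(records$drug_code)))
  # coverage per drug, encoded as a bitmask per day when few enough drugs
  s <- as.integer(start - origin) + 1L
  e <- as.integer(end - origin) + 1L
  code <- match(as.character(records$drug_code), drugs)
  if (length(drugs) <= 30L) {
    mask <- integer(n)
    for (j in seq_along(drugs)) {
      cov <- logical(n)
      idx <- which(code == j)
      for (r in idx) cov[s[r]:e[r]] <- TRUE
      mask <- mask + bitwShiftL(1L, j - 1L) * as.integer(cov)
    }
    um <- sort(unique(mask))
    lab <- vapply(um, function(m) {
      combination(drugs[bitwAnd(bitwShiftR(m, seq_along(drugs) - 1L), 1L) == 1L])
    }, character(1))
    values <- lab[match(mask, um)]
  } else {
    cov <- matrix(FALSE, n, length(drugs))
    for (r in seq_along(s)) cov[s[r]:e[r], code[r]] <- TRUE
    values <- apply(cov, 1L, function(row) combination(drugs[row]))
  }
  exposure_series(pid, origin, values)
}

#' Collapse a daily series into treatment episodes
#'
#' Run-length encodes the series: each episode is a maximal run of
#' consecutive days with an identical combination. Concatenating the episodes
#' reproduces the series exactly.
#'
#' @param series an [exposure_series()].
#' @return data.frame with columns `patient_id`, `combination`, `start`,
#'   `end` (inclusive dates), ordered by `start`; zero rows for an empty
#'   series.
#' @export
collapse_to_episodes <- function(series) {
  stopifnot(inherits(series, "exposure_series"))
  n <- length(series)
  if (n == 0L) {
    return(data.frame(patient_id = character(), combination = character(),
                      start = as.Date(character()), end = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  r <- rle(series$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    patient_id = rep(series$patient_id, length(r$values)),
    combination = r$values,
    start = series$origin + starts - 1L,
    end = series$origin + ends - 1L,
    stringsAsFactors = FALSE
  )
}
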