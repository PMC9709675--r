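#' Read prescription records from a delimited file
#'
#' Expects a header with columns `patient_id, drug_code, start_date, end_date`
#' and optionally `month, packages` for dispensation rows; dates ISO-8601.
#' Malformed rows (missing identifiers, unparseable dates, start after end,
#' neither a complete interval nor a complete dispensation) are dropped with
#' a warning naming their line numbers; the read fails outright when more
#' than `max_invalid` of the rows are malformed.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @param max_invalid maximum tolerated fraction of invalid rows (default
#'   0.25).
#' @return data.frame of validated records with `Date` columns `start`,
#'   `end` and, when present in the file, `month`/`packages`.
#' @export
read_prescriptions <- function(path, sep = ",", max_invalid = 0.25) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("patient_id", "drug_code", "start_date", "end_date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  has_disp <- all(c("month", "packages") %in% names(raw))
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path)
    return(interval_records(data.frame(patient_id = character(),
                                       drug_code = character())))
  }
  parse_date <- function(x) {
    x[is.na(x) | !nzchar(x)] <- NA
    suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  }
  start <- parse_date(raw$start_date)
  end <- parse_date(raw$end_date)
  month <- if (has_disp) parse_date(raw$month) else as.Date(rep(NA, nrow(raw)))
  packages <- if (has_disp) suppressWarnings(as.integer(raw$packages))
              else rep(NA_integer_, nrow(raw))

  bad_id <- is.na(raw$patient_id) | !nzchar(raw$patient_id) |
    is.na(raw$drug_code) | !nzchar(raw$drug_code)
  interval_ok <- !is.na(start) & !is.na(end) & start <= end
  disp_ok <- !is.na(month) & !is.na(packages) & packages >= 1 &
    is.na(start) & is.na(end)
  bad <- bad_id | (!interval_ok & !disp_ok)
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    warning(sum(bad), " malformed row(s) dropped (file line ",
            paste(utils::head(lines, 20L), collapse = ", "),
            if (sum(bad) > 20L) ", ..." else "", ")")
    if (mean(bad) > max_invalid) {
      stop("more than ", round(100 * max_invalid), "% of rows invalid in ",
           path)
    }
  }
  keep <- which(!bad)
  out <- data.frame(
    patient_id = raw$patient_id[keep],
    drug_code = raw$drug_code[keep],
    start = start[keep],
    end = end[keep],
    stringsAsFactors = FALSE
  )
  if (has_disp) {
    out$month <- month[keep]
    out$packages <- packages[keep]
  }
  out
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE)
  data.frame(
    patient_id = raw$patient_id,
    combination = raw$combination,
    start = as.Date(raw$start_date),
    end = as.Date(raw$end_date),
    stringsAsFactors = FALSE
  )
}

#' Write / read treatment episodes as CSV
#'
#' Columns `patient_id, combination, start_date, end_date`, combinations in
#' canonical `"+"`-joined form, dates ISO-8601. Writing then reading
#' reproduces the episodes exactly.
#'
#' @param episodes data.frame as returned by [collapse_to_episodes()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_episodes <- function(episodes, path, sep = ",") {
  out <- data.frame(
    patient_id = episodes$patient_id,
    combination = episodes$combination,
    start_date = format(episodes$start, "%Y-%m-%d"),
    end_date = format(episodes$end, "%Y-%m-%d"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write prescription records as CSV
#'
#' @param records data.frame of records (interval and/or dispensation form).
#' @param path output file path.
#' @export
write_prescriptions <- function(records, path) {
  fmt <- function(x) ifelse(is.na(x), "", format(x, "%Y-%m-%d"))
  out <- data.frame(
    patient_id = records$patient_id,
    drug_code = records$drug_code,
    start_date = fmt(records$start),
    end_date = fmt(records$end),
    stringsAsFactors = FALSE
  )
  if (!is.null(records$month)) {
    out$month <- fmt(records$month)
    out$packages <- ifelse(is.na(records$packages), "", records$packages)
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on a prescription file
#'
#' Reads records, resolves dispensation rows, expands each patient to a
#' daily series, applies the requested method(s), and writes the result.
#' Patients are processed independently and output rows are sorted by
#' patient id and start date, so the output is byte-identical across runs on
#' the same input.
#'
#' @param input path to a prescription CSV (see [read_prescriptions()]).
#' @param output path for the result CSV.
#' @param method `"smooth"`, `"traditional"` or `"none"` (raw expansion).
#' @param wt window length for the smoothing method.
#' @param min_duration persistence threshold for the traditional method.
#' @param emit `"episodes"` (default) or `"daily"`.
#' @param days_per_package coverage assumed per dispensation package.
#' @return invisibly, the output path.
#' @export
run_pipeline <- function(input, output,
                         method = c("smooth", "traditional", "none"),
                         wt = 60L, min_duration = 60L,
                         emit = c("episodes", "daily"),
                         days_per_package = 30L) {
  method <- match.arg(method)
  emit <- match.arg(emit)
  records <- read_prescriptions(input)
  records <- normalize_records(records, days_per_package)
  by_patient <- split(records, records$patient_id)
  by_patient <- by_patient[order(names(by_patient))]
  series <- lapply(by_patient, expand_to_daily)
  series <- lapply(series, function(s) {
    switch(method,
           smooth = smooth_series(s, wt),
           traditional = traditional_series(s, min_duration),
           none = s)
  })
  if (emit == "episodes") {
    eps <- do.call(rbind, lapply(series, collapse_to_episodes))
    eps <- eps[order(eps$patient_id, eps$start), , drop = FALSE]
    write_episodes(eps, output)
  } else {
    daily <- do.call(rbind, lapply(series, as.data.frame))
    daily <- daily[order(daily$patient_id, daily$date), , drop = FALSE]
    daily$date <- format(daily$date, "%Y-%m-%d")
    utils::write.table(daily, output, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(output)
}
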