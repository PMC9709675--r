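# quick constructors for daily series used across the tests

D0 <- as.Date("2019-01-01")

series_of <- function(values, patient_id = "p1", origin = D0) {
  exposure_series(patient_id, origin, values)
}

# run-structured random categorical series: random-length runs over a small
# combination alphabet, truncated to `len` days; first/last day kept active
random_values <- function(len, alphabet = c("A", "B", "A+B", "NONE"),
                          max_run = 10L) {
  vals <- character(0)
  while (length(vals) < len) {
    vals <- c(vals, rep(sample(alphabet, 1L),
                        sample.int(max_run, 1L)))
  }
  vals <- vals[seq_len(len)]
  active <- setdiff(alphabet, "NONE")
  if (vals[1L] == "NONE") vals[1L] <- active[1L]
  if (vals[len] == "NONE") vals[len] <- active[1L]
  vals
}

random_series <- function(max_len = 60L, ...) {
  series_of(random_values(sample.int(max_len, 1L), ...))
}
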