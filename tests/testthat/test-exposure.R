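test_that("combination strings are canonical: sorted, deduplicated, NONE for empty", {
  expect_identical(combination(c("C07AB", "B01AC", "B01AC")), "B01AC+C07AB")
  expect_identical(combination("A"), "A")
  expect_identical(combination(character()), "NONE")
  expect_identical(combination_drugs("B01AC+C07AB"), c("B01AC", "C07AB"))
  expect_identical(combination_drugs("NONE"), character())
  # round trip
  expect_identical(combination(combination_drugs("A+B+C")), "A+B+C")
})

test_that("dispensation records resolve to package-count intervals", {
  rec <- function(month, packages) {
    data.frame(patient_id = "p1", drug_code = "J01CA04",
               month = as.Date(month), packages = packages)
  }
  r1 <- resolve_dispensation(rec("2019-03-01", 1L), days_per_package = 30)
  expect_equal(r1$start, as.Date("2019-03-01"))
  expect_equal(r1$end, as.Date("2019-03-30"))

  # three 30-day packages cover 90 consecutive days from March 1st
  r3 <- resolve_dispensation(rec("2019-03-15", 3L), days_per_package = 30)
  expect_equal(r3$start, as.Date("2019-03-01"))
  expect_equal(r3$end, as.Date("2019-05-29"))
  expect_equal(as.integer(r3$end - r3$start) + 1L, 90L)

  # a 28-day package dispensed in February spans exactly the month
  r28 <- resolve_dispensation(rec("2019-02-01", 1L), days_per_package = 28)
  expect_equal(r28$end, as.Date("2019-02-28"))

  # per-drug override takes precedence over the default
  ro <- resolve_dispensation(rec("2019-03-01", 1L), days_per_package = 30,
                             per_drug = c(J01CA04 = 10L))
  expect_equal(ro$end, as.Date("2019-03-10"))
})

test_that("resolve_dispensation rejects misuse and invalid config", {
  iv <- data.frame(patient_id = "p1", drug_code = "A",
                   start = as.Date("2019-01-01"), end = as.Date("2019-01-10"))
  expect_error(resolve_dispensation(iv), "interval form")
  disp <- data.frame(patient_id = "p1", drug_code = "A",
                     month = as.Date("2019-01-01"), packages = 1L)
  expect_error(resolve_dispensation(disp, days_per_package = 0), "positive")
  disp$packages <- 0L
  expect_error(resolve_dispensation(disp), ">= 1")
})

test_that("daily expansion takes the per-day union of covering prescriptions", {
  recs <- function(drug, s, e) {
    data.frame(patient_id = "p1", drug_code = drug, start = D0 + s - 1L,
               end = D0 + e - 1L, stringsAsFactors = FALSE)
  }
  # single record
  s1 <- expand_to_daily(recs("A", 1, 10))
  expect_length(s1, 10L)
  expect_identical(s1$values, rep("A", 10))
  expect_equal(s1$origin, D0)

  # overlap: A day1-10, B day5-15
  s2 <- expand_to_daily(rbind(recs("A", 1, 10), recs("B", 5, 15)))
  expect_identical(s2$values, rep(c("A", "A+B", "B"), c(4, 6, 5)))

  # duplicates / overlapping same-drug records collapse
  s3 <- expand_to_daily(rbind(recs("A", 1, 10), recs("A", 5, 12)))
  expect_identical(s3$values, rep("A", 12))

  # uncovered interior days become explicit NONE
  s4 <- expand_to_daily(rbind(recs("A", 1, 5), recs("A", 10, 12)))
  expect_identical(s4$values, rep(c("A", "NONE", "A"), c(5, 4, 3)))

  # empty collection -> empty-series sentinel
  expect_length(expand_to_daily(recs("A", 1, 1)[0, ]), 0L)

  # mixed patients rejected
  two <- rbind(recs("A", 1, 5), recs("A", 1, 5))
  two$patient_id <- c("p1", "p2")
  expect_error(expand_to_daily(two), "single patient")
})

test_that("expansion is invariant under record duplication and splitting", {
  set.seed(41)
  for (rep_i in 1:25) {
    n_rec <- sample(2:6, 1)
    recs <- data.frame(
      patient_id = "p1",
      drug_code = sample(LETTERS[1:3], n_rec, replace = TRUE),
      start = D0 + sample(0:20, n_rec, replace = TRUE),
      stringsAsFactors = FALSE
    )
    recs$end <- recs$start + sample(0:15, n_rec, replace = TRUE)
    base <- expand_to_daily(recs)

    # duplication changes nothing
    expect_identical(expand_to_daily(rbind(recs, recs))$values, base$values)

    # splitting one multi-day interval into two adjacent halves changes nothing
    long <- which(recs$end > recs$start)
    if (length(long) > 0L) {
      j <- long[1L]
      cut <- recs$start[j] + (as.integer(recs$end[j] - recs$start[j]) %/% 2)
      split_rec <- rbind(recs[-j, ],
                         data.frame(patient_id = "p1",
                                    drug_code = recs$drug_code[j],
                                    start = c(recs$start[j], cut + 1L),
                                    end = c(cut, recs$end[j])))
      expect_identical(expand_to_daily(split_rec)$values, base$values)
    }

    # series spans first to last covered day; alphabet within the power set
    expect_length(base, as.integer(max(recs$end) - min(recs$start)) + 1L)
    drugs_seen <- unique(unlist(lapply(unique(base$values),
                                       combination_drugs)))
    expect_true(all(drugs_seen %in% recs$drug_code))
  }
})

test_that("episode collapse is maximal-run encoding and round-trips", {
  e1 <- collapse_to_episodes(series_of(rep("A", 30)))
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$start, D0)
  expect_equal(e1$end, D0 + 29L)

  e2 <- collapse_to_episodes(series_of(rep(c("A", "A+B"), c(5, 5))))
  expect_equal(nrow(e2), 2L)
  expect_identical(e2$combination, c("A", "A+B"))

  e3 <- collapse_to_episodes(series_of(rep(c("A", "B"), 3)))
  expect_equal(nrow(e3), 6L)

  expect_equal(nrow(collapse_to_episodes(series_of(character(0)))), 0L)

  # round trip: re-expanding the episodes reproduces the series
  set.seed(7)
  for (i in 1:20) {
    s <- random_series()
    ep <- collapse_to_episodes(s)
    expect_identical(rep(ep$combination, as.integer(ep$end - ep$start) + 1L),
                     s$values)
    # consecutive episodes are date-adjacent with different combinations
    if (nrow(ep) > 1L) {
      expect_true(all(ep$start[-1L] == ep$end[-nrow(ep)] + 1L))
      expect_true(all(ep$combination[-1L] != ep$combination[-nrow(ep)]))
    }
  }
})
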