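#' Noise model for synthetic prescription records
#'
#' Describes the record-level noise layered on top of a clean regimen, in the
#' style of primary-care prescription databases: short spurious prescriptions,
#' refill gaps punched into true treatment, duplicated rows, and refills
#' collected early so that consecutive intervals overlap. All mechanisms are
#' mutually independent Poisson/Bernoulli processes.
#'
#' @param spurious_rate expected number per patient of short extra
#'   prescriptions (Poisson mean).
#' @param spurious_duration length-2 integer vector, min/max days of a
#'   spurious prescription.
#' @param gap_rate expected number per patient of refill gaps (Poisson mean).
#' @param gap_duration length-2 integer vector, min/max days of a gap.
#' @param duplicate_rate probability that a record row is emitted twice.
#' @param overlap_jitter maximum days by which a refill may start before the
#'   previous one ends (0 = refills abut exactly).
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(spurious_rate = 1, spurious_duration = c(1L, 7L),
                       gap_rate = 2, gap_duration = c(1L, 7L),
                       duplicate_rate = 0.1, overlap_jitter = 5L) {
  stopifnot(spurious_rate >= 0, gap_rate >= 0,
            duplicate_rate >= 0, duplicate_rate <= 1, overlap_jitter >= 0,
            length(spurious_duration) == 2L, all(spurious_duration >= 1),
            length(gap_duration) == 2L, all(gap_duration >= 1),
            spurious_duration[1] <= spurious_duration[2],
            gap_duration[1] <= gap_duration[2])
  structure(list(spurious_rate = spurious_rate,
                 spurious_duration = as.integer(spurious_duration),
                 gap_rate = gap_rate,
                 gap_duration = as.integer(gap_duration),
                 duplicate_rate = duplicate_rate,
                 overlap_jitter = as.integer(overlap_jitter)),
            class = "noise_spec")
}

#' Specification of a synthetic prescription cohort
#'
#' Defines a cohort of patients on a known ground-truth regimen -- a sequence
#' of treatment segments, each a drug combination held for a duration drawn
#' from a range -- plus the noise applied to the emitted prescription records.
#' The defaults emulate a chronic cardiovascular polytherapy cohort: three
#' years of follow-up, 30-day refills, and a regimen that escalates from
#' monotherapy to a three-drug combination.
#'
#' @param n_patients positive integer.
#' @param follow_up_days positive integer; segment durations must fit inside
#'   it.
#' @param drug_alphabet character vector of drug codes; spurious
#'   prescriptions draw from it.
#' @param regimen_plan list of segments, each `list(drugs = <codes>,
#'   duration = c(min, max))`; every patient realises the plan with segment
#'   durations sampled independently from the ranges.
#' @param noise a [noise_spec()].
#' @param seed integer master seed; per-patient substreams are derived from
#'   it so each patient's data are invariant to cohort size.
#' @param origin `Date` of day 1 of follow-up.
#' @param refill_days refill (package) length in days used when splitting
#'   clean treatment segments into individual prescription rows.
#' @param dispensation_fraction fraction of emitted rows converted to
#'   dispensation form (month + package count instead of an end date), for
#'   exercising [resolve_dispensation()].
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients,
                        follow_up_days = 1000L,
                        drug_alphabet = c("B01AC06", "C07AB03", "C09AA02",
                                          "C10AA05"),
                        regimen_plan = default_regimen_plan(drug_alphabet),
                        noise = noise_spec(),
                        seed = 1L,
                        origin = as.Date("2018-01-01"),
                        refill_days = 30L,
                        dispensation_fraction = 0) {
  stopifnot(n_patients >= 1, follow_up_days >= 1, length(drug_alphabet) >= 1,
            length(regimen_plan) >= 1, inherits(noise, "noise_spec"),
            refill_days >= 1, dispensation_fraction >= 0,
            dispensation_fraction <= 1)
  for (seg in regimen_plan) {
    stopifnot(is.character(seg$drugs), length(seg$duration) == 2L,
              seg$duration[1] >= 1, seg$duration[1] <= seg$duration[2])
  }
  max_total <- sum(vapply(regimen_plan, function(s) s$duration[2], numeric(1)))
  if (max_total > follow_up_days) {
    stop("regimen durations can total ", max_total,
         " days, exceeding follow_up_days = ", follow_up_days)
  }
  structure(list(n_patients = as.integer(n_patients),
                 follow_up_days = as.integer(follow_up_days),
                 drug_alphabet = drug_alphabet,
                 regimen_plan = regimen_plan,
                 noise = noise, seed = as.integer(seed),
                 origin = as.Date(origin),
                 refill_days = as.integer(refill_days),
                 dispensation_fraction = dispensation_fraction),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_regimen_plan <- function(drug_alphabet) {
  a <- drug_alphabet
  list(
    list(drugs = a[1L], duration = c(150L, 250L)),
    list(drugs = a[seq_len(min(2L, length(a)))], duration = c(250L, 350L)),
    list(drugs = a[seq_len(min(3L, length(a)))], duration = c(300L, 400L))
  )
}

#' Generate a synthetic prescription cohort with known ground truth
#'
#' Realises the regimen plan of `spec` for every patient as clean
#' prescription intervals, records the resulting clean daily series as the
#' ground truth, then perturbs the emitted rows with the cohort's noise
#' model. With all noise rates at zero the emitted records expand to exactly
#' the truth. Fully reproducible: the same spec and seed give identical
#' output, and each patient's draw depends only on the master seed and the
#' patient's index.
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (a data.frame of noisy prescription rows in
#'   interval and/or dispensation form) and `truth` (a named list of clean
#'   [exposure_series()], one per patient).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ns <- spec$noise
  all_records <- vector("list", spec$n_patients)
  truth <- vector("list", spec$n_patients)
  ids <- sprintf("P%05d", seq_len(spec$n_patients))
  for (i in seq_len(spec$n_patients)) {
    set.seed(patient_seed(spec$seed, i))
    pid <- ids[i]

    durations <- vapply(spec$regimen_plan, function(seg) {
      if (seg$duration[1] == seg$duration[2]) seg$duration[1]
      else sample(seq(seg$duration[1], seg$duration[2]), 1L)
    }, integer(1))
    seg_end <- cumsum(durations)
    seg_start <- seg_end - durations + 1L

    clean <- do.call(rbind, lapply(seq_along(spec$regimen_plan), function(j) {
      drugs <- spec$regimen_plan[[j]]$drugs
      data.frame(patient_id = pid, drug_code = drugs,
                 start = spec$origin + seg_start[j] - 1L,
                 end = spec$origin + seg_end[j] - 1L,
                 stringsAsFactors = FALSE)
    }))
    truth[[i]] <- expand_to_daily(clean)

    rec <- split_refills(clean, spec$refill_days)

    # refill gaps: delay the start of randomly chosen refills
    n_gaps <- stats::rpois(1L, ns$gap_rate)
    for (g in seq_len(n_gaps)) {
      r <- sample.int(nrow(rec), 1L)
      gd <- sample(seq(ns$gap_duration[1], ns$gap_duration[2]), 1L)
      rec$start[r] <- rec$start[r] + gd
    }
    rec <- rec[rec$start <= rec$end, , drop = FALSE]

    # early refill collection: a refill may start before the previous abutting
    # refill of the same drug has ended (total span is preserved)
    if (ns$overlap_jitter > 0L && nrow(rec) > 1L) {
      rec <- rec[order(rec$drug_code, rec$start), , drop = FALSE]
      nr <- nrow(rec)
      follows <- c(FALSE,
                   rec$drug_code[-1L] == rec$drug_code[-nr] &
                     rec$start[-1L] == rec$end[-nr] + 1L)
      jit <- sample(0:ns$overlap_jitter, nr, replace = TRUE)
      rec$start[follows] <- rec$start[follows] - jit[follows]
    }

    # short spurious prescriptions anywhere in follow-up
    n_sp <- stats::rpois(1L, ns$spurious_rate)
    if (n_sp > 0L) {
      sp <- do.call(rbind, lapply(seq_len(n_sp), function(k) {
        dur <- sample(seq(ns$spurious_duration[1], ns$spurious_duration[2]),
                      1L)
        s0 <- sample.int(max(1L, spec$follow_up_days - dur + 1L), 1L)
        data.frame(patient_id = pid,
                   drug_code = sample(spec$drug_alphabet, 1L),
                   start = spec$origin + s0 - 1L,
                   end = spec$origin + s0 + dur - 2L,
                   stringsAsFactors = FALSE)
      }))
      rec <- rbind(rec, sp)
    }

    # duplicate rows
    if (ns$duplicate_rate > 0 && nrow(rec) > 0L) {
      dup <- stats::runif(nrow(rec)) < ns$duplicate_rate
      rec <- rbind(rec, rec[dup, , drop = FALSE])
    }

    rec <- rec[order(rec$start, rec$drug_code), , drop = FALSE]

    # optionally recast a fraction of rows as dispensation records
    if (spec$dispensation_fraction > 0 && nrow(rec) > 0L) {
      as_disp <- stats::runif(nrow(rec)) < spec$dispensation_fraction
      rec$month <- as.Date(rep(NA, nrow(rec)))
      rec$packages <- rep(NA_integer_, nrow(rec))
      ndays <- as.integer(rec$end - rec$start) + 1L
      rec$month[as_disp] <- as.Date(format(rec$start[as_disp], "%Y-%m-01"))
      rec$packages[as_disp] <- pmax(1L, as.integer(
        round(ndays[as_disp] / spec$refill_days)))
      rec$start[as_disp] <- as.Date(NA)
      rec$end[as_disp] <- as.Date(NA)
    }
    all_records[[i]] <- rec
  }
  names(truth) <- ids
  list(records = do.call(rbind, all_records), truth = truth)
}

# stable per-patient substream: patient i's draws depend only on (seed, i)
patient_seed <- function(seed, i) {
  m <- 2147483647
  as.integer((abs(as.numeric(seed)) %% m * 48271 + i * 16807) %% m)
}

split_refills <- function(records, refill_days) {
  pieces <- lapply(seq_len(nrow(records)), function(r) {
    starts <- seq(records$start[r], records$end[r], by = refill_days)
    data.frame(patient_id = records$patient_id[r],
               drug_code = records$drug_code[r],
               start = starts,
               end = pmin(starts + refill_days - 1L, records$end[r]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Day-wise recovery of a ground-truth series
#'
#' Fraction of days on which the estimated series assigns the same
#' combination as the truth. With `align = FALSE` (the strict contract) the
#' two series must share origin and length. With `align = TRUE` the series
#' are compared over the union of their date ranges, days outside either
#' series counting as `"NONE"` -- useful when noise has shifted the observed
#' first or last active day away from the truth's.
#'
#' @param truth,estimate [exposure_series()] objects.
#' @param align logical; see Details.
#' @return a fraction in `[0, 1]`.
#' @export
recovery_score <- function(truth, estimate, align = FALSE) {
  stopifnot(inherits(truth, "exposure_series"),
            inherits(estimate, "exposure_series"))
  if (!align) {
    if (length(truth) != length(estimate) || truth$origin != estimate$origin) {
      stop("series differ in length or origin; use align = TRUE to compare ",
           "over the union of their date ranges")
    }
    if (length(truth) == 0L) return(1)
    return(mean(truth$values == estimate$values))
  }
  lo <- min(truth$origin, estimate$origin)
  hi <- max(truth$origin + max(length(truth) - 1L, 0L),
            estimate$origin + max(length(estimate) - 1L, 0L))
  n <- as.integer(hi - lo) + 1L
  pad <- function(s) {
    v <- rep(NONE_LABEL, n)
    if (length(s) > 0L) {
      off <- as.integer(s$origin - lo)
      v[off + seq_len(length(s))] <- s$values
    }
    v
  }
  mean(pad(truth) == pad(estimate))
}
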