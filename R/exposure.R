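#' Build continuous exposure episodes from prescriptions
#'
#' Merges a patient's prescriptions of one drug into maximal runs of
#' continuous use. Prescriptions are sorted by date; a prescription joins the
#' current episode when the gap between its start and the episode's running
#' coverage end (date + period, half-open) is smaller than `gap_days`;
#' overlapping or abutting refills merge. An episode qualifies as exposure
#' when its total span (`end - start`) strictly exceeds `min_duration_days`.
#'
#' @param prescriptions Valid prescription rows (any mix of patients/drugs;
#'   grouped internally by patient_id + drug_code). Requires columns
#'   `patient_id, drug_code, prescription_date, period_days`.
#' @param gap_days Gaps of `gap_days` or more start a new episode (default 31:
#'   an interval of less than one month preserves continuity).
#' @param min_duration_days An episode qualifies only when strictly longer
#'   than this span (default 31 days, i.e. exceeding one month).
#' @param gap_basis `"coverage_end"` (default) measures the gap from the
#'   previous coverage end to the next start; `"start"` measures it between
#'   successive prescription start dates.
#' @return data.frame `patient_id, drug_code, start, end, duration_days,
#'   qualifying`, ordered by patient, drug, start; `end` is exclusive.
#' @export
#' @examples
#' rx <- data.frame(patient_id = "A", drug_code = "fexofenadine",
#'                  prescription_date = c(0, 25), period_days = c(20, 20))
#' build_episodes(rx) # one episode [0, 45), qualifying
build_episodes <- function(prescriptions, gap_days = 31L,
                           min_duration_days = 31L,
                           gap_basis = c("coverage_end", "start")) {
  gap_basis <- match.arg(gap_basis)
  if (gap_days < 0 || min_duration_days < 0) {
    stop("gap_days and min_duration_days must be non-negative", call. = FALSE)
  }
  empty <- data.frame(patient_id = character(), drug_code = character(),
                      start = integer(), end = integer(),
                      duration_days = integer(), qualifying = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(prescriptions)) return(empty)
  rx <- data.table::as.data.table(
    prescriptions[, c("patient_id", "drug_code", "prescription_date", "period_days")]
  )
  if (anyNA(rx$period_days) || anyNA(rx$prescription_date)) {
    stop("build_episodes requires valid prescriptions (no missing dates/periods)",
         call. = FALSE)
  }
  data.table::setorder(rx, patient_id, drug_code, prescription_date, period_days)
  rx[, coverage_end := prescription_date + period_days]
  # running coverage end within patient+drug; a new episode starts when the
  # next prescription begins gap_days or more after it
  rx[, new_episode := {
    if (gap_basis == "coverage_end") {
      run_end <- shift(cummax(as.numeric(coverage_end)), fill = -Inf)
      prescription_date - run_end >= gap_days
    } else {
      prescription_date - shift(as.numeric(prescription_date), fill = -Inf) >= gap_days
    }
  }, by = .(patient_id, drug_code)]
  rx[, episode_id := cumsum(new_episode), by = .(patient_id, drug_code)]
  ep <- rx[, .(start = min(prescription_date), end = max(coverage_end)),
           by = .(patient_id, drug_code, episode_id)]
  ep[, duration_days := end - start]
  ep[, qualifying := duration_days > min_duration_days]
  ep[, episode_id := NULL]
  data.table::setorder(ep, patient_id, drug_code, start)
  as.data.frame(ep)
}

#' Classify patients into exposure groups
#'
#' A patient is `exposed` when they have at least one qualifying episode and
#' exactly one distinct antihistamine drug code across *all* their
#' antihistamine prescriptions (single-agent criterion);
#' `excluded_multi_type` when they have a qualifying episode but took two or
#' more distinct antihistamines; all remaining retained patients are
#' `unexposed`.
#'
#' @param patients Retained patient data.frame.
#' @param episodes Episode table from [build_episodes()] run on the
#'   antihistamine prescriptions.
#' @param ah_prescriptions All antihistamine prescription rows of the retained
#'   patients (used for the distinct-agent count).
#' @return data.frame `patient_id, group, exposed_drug` with one row per
#'   retained patient (a partition).
#' @export
classify_patients <- function(patients, episodes, ah_prescriptions) {
  qual <- episodes[episodes$qualifying, , drop = FALSE]
  n_drugs <- tapply(ah_prescriptions$drug_code, ah_prescriptions$patient_id,
                    function(d) length(unique(d)))
  has_qual <- unique(qual$patient_id)
  group <- rep("unexposed", nrow(patients))
  exposed_drug <- rep(NA_character_, nrow(patients))
  idx <- match(patients$patient_id, names(n_drugs))
  nd <- ifelse(is.na(idx), 0L, unname(n_drugs)[idx])
  q <- patients$patient_id %in% has_qual
  group[q & nd == 1L] <- "exposed"
  group[q & nd >= 2L] <- "excluded_multi_type"
  first_drug <- qual$drug_code[match(patients$patient_id, qual$patient_id)]
  exposed_drug[group == "exposed"] <- first_drug[group == "exposed"]
  data.frame(patient_id = patients$patient_id, group = group,
             exposed_drug = exposed_drug, stringsAsFactors = FALSE)
}

# index date candidates for exposed patients: start of the first qualifying
# episode (default) or literal first antihistamine prescription ever
exposed_index_dates <- function(assignments, episodes, ah_prescriptions,
                                index_mode = c("first_qualifying", "first_ever")) {
  index_mode <- match.arg(index_mode)
  exp_ids <- assignments$patient_id[assignments$group == "exposed"]
  if (index_mode == "first_qualifying") {
    qual <- episodes[episodes$qualifying, , drop = FALSE]
    qual <- qual[order(qual$patient_id, qual$start), , drop = FALSE]
    first <- qual[!duplicated(qual$patient_id), , drop = FALSE]
    idx <- first$start[match(exp_ids, first$patient_id)]
  } else {
    ord <- order(ah_prescriptions$patient_id, ah_prescriptions$prescription_date)
    rx <- ah_prescriptions[ord, , drop = FALSE]
    first <- rx[!duplicated(rx$patient_id), , drop = FALSE]
    idx <- first$prescription_date[match(exp_ids, first$patient_id)]
  }
  data.frame(patient_id = exp_ids, index_date = as.integer(idx),
             stringsAsFactors = FALSE)
}

#' Median diagnosis-to-exposure interval
#'
#' Median of `index_date - pd_diagnosis_date` over exposed patients; for even
#' counts, the mean of the two central values.
#'
#' @param intervals Numeric vector of per-patient intervals in days.
#' @return Median interval in days.
#' @export
compute_median_interval <- function(intervals) {
  intervals <- intervals[!is.na(intervals)]
  if (!length(intervals)) {
    stop("no exposed patients: median interval undefined", call. = FALSE)
  }
  stats::median(intervals)
}

#' Assign index dates to a classified cohort
#'
#' Exposed patients are anchored at the start of their first qualifying
#' antihistamine episode (or their literal first antihistamine prescription,
#' see `index_mode`); unexposed patients at
#' `pd_diagnosis_date + median_interval`, transferring the exposed group's
#' median diagnosis-to-exposure timeframe. Patients whose before/after
#' windows would extend outside the observed horizon are flagged.
#'
#' @param assignments Output of [classify_patients()].
#' @param patients Patient table (for diagnosis dates).
#' @param episodes,ah_prescriptions As in [classify_patients()].
#' @param median_interval Days; if `NULL`, computed from the exposed group.
#' @param window_days Analysis window length used for the horizon flag.
#' @param horizon Observed data horizon in days.
#' @param index_mode See [build_episodes()] discussion; default
#'   `"first_qualifying"`.
#' @return `assignments` with columns `index_date`, `interval_days`
#'   (exposed only) and `window_ok`, plus attribute `median_interval`.
#' @export
assign_index_dates <- function(assignments, patients, episodes,
                               ah_prescriptions, median_interval = NULL,
                               window_days = 90L, horizon = NULL,
                               index_mode = "first_qualifying") {
  diag <- patients$pd_diagnosis_date[match(assignments$patient_id,
                                           patients$patient_id)]
  exp_idx <- exposed_index_dates(assignments, episodes, ah_prescriptions,
                                 index_mode)
  index <- rep(NA_integer_, nrow(assignments))
  pos <- match(exp_idx$patient_id, assignments$patient_id)
  index[pos] <- exp_idx$index_date
  interval <- rep(NA_integer_, nrow(assignments))
  interval[pos] <- exp_idx$index_date - diag[pos]
  if (is.null(median_interval)) {
    median_interval <- compute_median_interval(interval[assignments$group == "exposed"])
  }
  unexp <- assignments$group == "unexposed"
  index[unexp] <- as.integer(round(diag[unexp] + median_interval))
  assignments$index_date <- index
  assignments$interval_days <- interval
  if (is.null(horizon)) horizon <- Inf
  assignments$window_ok <- !is.na(index) &
    (index - window_days) >= 0 & (index + window_days) <= horizon
  attr(assignments, "median_interval") <- median_interval
  assignments
}
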