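#' Claims CSV schemas
#'
#' Patient CSV: `patient_id,sex,pd_diagnosis_date,age_at_diagnosis`.
#' Prescription CSV:
#' `patient_id,drug_code,drug_class,prescription_date,period_days,daily_dose,single_dose`.
#' Drug table CSV: `drug_code,name,class,generation,rule_type,parameter`.
#' All dates are integer day offsets from the study epoch (day 0); a
#' prescription covers the half-open interval
#' `[prescription_date, prescription_date + period_days)`.
#' @name claims-schemas
#' @keywords internal
NULL

#' Antihistamine codes shipped with the package
#'
#' The 15 H1-antihistamine agents screened by default.
#' @return Character vector of drug codes.
#' @export
antihistamine_codes <- function() {
  c("azelastine", "bepotastine", "cetirizine", "chlorpheniramine",
    "clemastine", "desloratadine", "dimenhydrinate", "ebastine",
    "fexofenadine", "hydroxyzine", "ketotifen", "levocetirizine",
    "loratadine", "mizolastine", "olopatadine")
}

#' Default drug table
#'
#' Reads the packaged drug table: the nine PD drugs with their
#' levodopa-equivalent dose (LED) conversion rules and the fifteen
#' antihistamines with their generation (1st/2nd). LED factors follow the
#' standard published conversion reference (immediate-release levodopa 1.0,
#' pramipexole 100, ropinirole 20, rasagiline 100, selegiline 10,
#' amantadine 1.0); entacapone is an adjunct contributing 0.33 x the
#' concurrent levodopa LED; benserazide and carbidopa are peripheral
#' decarboxylase inhibitors with no LED contribution.
#'
#' @return data.frame with columns `drug_code,name,class,generation,rule_type,parameter`.
#' @export
default_drug_table <- function() {
  path <- system.file("extdata", "drug_table.csv", package = "leddscreen",
                      mustWork = TRUE)
  read_drug_table(path)
}

#' Read and validate a drug table CSV
#' @param path CSV with columns `drug_code,name,class,generation,rule_type,parameter`.
#' @return Validated data.frame.
#' @export
read_drug_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_code", "name", "class", "generation", "rule_type", "parameter")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("drug table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$drug_code)) {
    stop("duplicate drug_code in drug table: ",
         paste(unique(tab$drug_code[duplicated(tab$drug_code)]), collapse = ", "),
         call. = FALSE)
  }
  bad_rule <- !tab$rule_type %in% c("factor", "levodopa_fraction", "none")
  if (any(bad_rule)) {
    stop("unknown rule_type for drug(s): ",
         paste(tab$drug_code[bad_rule], collapse = ", "), call. = FALSE)
  }
  bad_par <- tab$rule_type != "none" & (is.na(tab$parameter) | tab$parameter <= 0)
  if (any(bad_par)) {
    stop("conversion parameter must be > 0 for drug(s): ",
         paste(tab$drug_code[bad_par], collapse = ", "), call. = FALSE)
  }
  tab
}

# parse a character column to numeric/integer, reporting 1-based data line
# numbers of unparseable (non-empty) entries
parse_num_col <- function(x, col, file, allow_missing = FALSE) {
  x <- trimws(x)
  empty <- is.na(x) | x == "" | x == "NA"
  val <- suppressWarnings(as.numeric(x))
  bad <- !empty & is.na(val)
  if (any(bad)) {
    stop(sprintf("%s: column '%s' unparseable at line(s) %s", file, col,
                 paste(head(which(bad), 5L), collapse = ", ")), call. = FALSE)
  }
  if (!allow_missing && any(empty)) {
    stop(sprintf("%s: column '%s' missing at line(s) %s", file, col,
                 paste(head(which(empty), 5L), collapse = ", ")), call. = FALSE)
  }
  val
}

#' Read a claims extract from CSV files
#'
#' Loads and type-checks the patient, prescription, and drug tables. Malformed
#' values are reported with their column and line number; prescription rows
#' with a *missing* (as opposed to malformed) period, daily dose, or single
#' dose are loaded and flagged `valid = FALSE`, never silently dropped.
#'
#' @param patient_file,prescription_file CSV paths (see [claims-schemas]).
#' @param drug_table_file Optional drug-table CSV; defaults to the packaged table.
#' @return list(patients, prescriptions, drug_table); `prescriptions` carries
#'   a logical `valid` column.
#' @export
read_claims <- function(patient_file, prescription_file, drug_table_file = NULL) {
  pat <- read.csv(patient_file, stringsAsFactors = FALSE,
                  colClasses = "character")
  need_p <- c("patient_id", "sex", "pd_diagnosis_date", "age_at_diagnosis")
  miss <- setdiff(need_p, names(pat))
  if (length(miss)) {
    stop(patient_file, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pat$patient_id)) {
    stop(patient_file, ": duplicate patient_id at line(s) ",
         paste(head(which(duplicated(pat$patient_id)), 5L), collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- !pat$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop(patient_file, ": column 'sex' must be male/female at line(s) ",
         paste(head(which(bad_sex), 5L), collapse = ", "), call. = FALSE)
  }
  patients <- data.frame(
    patient_id = pat$patient_id, sex = pat$sex,
    pd_diagnosis_date = as.integer(parse_num_col(pat$pd_diagnosis_date,
                                                 "pd_diagnosis_date", patient_file)),
    age_at_diagnosis = parse_num_col(pat$age_at_diagnosis, "age_at_diagnosis",
                                     patient_file),
    stringsAsFactors = FALSE
  )

  rx <- read.csv(prescription_file, stringsAsFactors = FALSE,
                 colClasses = "character")
  need_r <- c("patient_id", "drug_code", "drug_class", "prescription_date",
              "period_days", "daily_dose", "single_dose")
  miss <- setdiff(need_r, names(rx))
  if (length(miss)) {
    stop(prescription_file, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_class <- !rx$drug_class %in% c("pd_drug", "antihistamine", "other")
  if (any(bad_class)) {
    stop(prescription_file, ": column 'drug_class' invalid at line(s) ",
         paste(head(which(bad_class), 5L), collapse = ", "), call. = FALSE)
  }
  prescriptions <- data.frame(
    patient_id = rx$patient_id, drug_code = rx$drug_code,
    drug_class = rx$drug_class,
    prescription_date = as.integer(parse_num_col(rx$prescription_date,
                                                 "prescription_date",
                                                 prescription_file)),
    period_days = parse_num_col(rx$period_days, "period_days",
                                prescription_file, allow_missing = TRUE),
    daily_dose = parse_num_col(rx$daily_dose, "daily_dose",
                               prescription_file, allow_missing = TRUE),
    single_dose = parse_num_col(rx$single_dose, "single_dose",
                                prescription_file, allow_missing = TRUE),
    stringsAsFactors = FALSE
  )
  prescriptions <- flag_prescriptions(prescriptions)

  drug_table <- if (is.null(drug_table_file)) default_drug_table() else
    read_drug_table(drug_table_file)
  list(patients = patients, prescriptions = prescriptions,
       drug_table = drug_table)
}

#' Flag invalid prescription rows
#'
#' A row is invalid when any of period_days / daily_dose / single_dose is
#' missing, or when period_days < 1 or a dose is <= 0.
#' @param prescriptions Prescription data.frame.
#' @return Same data.frame with a logical `valid` column (re)computed.
#' @export
flag_prescriptions <- function(prescriptions) {
  v <- !is.na(prescriptions$period_days) & prescriptions$period_days >= 1 &
    !is.na(prescriptions$daily_dose) & prescriptions$daily_dose > 0 &
    !is.na(prescriptions$single_dose) & prescriptions$single_dose > 0
  prescriptions$valid <- v
  prescriptions
}

#' Apply the cohort inclusion/exclusion rules
#'
#' Removes, in order: (1) patients not diagnosed with PD after age 40;
#' (2) patients with neither a PD-drug nor an antihistamine prescription;
#' (3) patients having any invalid prescription row (missing period, daily
#' dose, or single dose — exclusion is patient-level). Every step is recorded
#' in an attrition log whose running totals reconcile exactly.
#'
#' @param patients Patient data.frame.
#' @param prescriptions Prescription data.frame (a `valid` column is computed
#'   if absent).
#' @return list(patients = retained patients, prescriptions = their rows,
#'   attrition = data.frame(rule, n_removed, n_remaining)).
#' @export
apply_exclusions <- function(patients, prescriptions) {
  if (is.null(prescriptions$valid)) {
    prescriptions <- flag_prescriptions(prescriptions)
  }
  log <- data.frame(rule = "input", n_removed = 0L,
                    n_remaining = nrow(patients), stringsAsFactors = FALSE)
  step <- function(keep, rule) {
    removed <- sum(!keep)
    patients <<- patients[keep, , drop = FALSE]
    log <<- rbind(log, data.frame(rule = rule, n_removed = removed,
                                  n_remaining = nrow(patients),
                                  stringsAsFactors = FALSE))
  }
  step(!is.na(patients$age_at_diagnosis) & patients$age_at_diagnosis >= 40,
       "diagnosed_at_or_after_age_40")
  relevant <- prescriptions$drug_class %in% c("pd_drug", "antihistamine")
  has_rx <- patients$patient_id %in% prescriptions$patient_id[relevant]
  step(has_rx, "has_pd_drug_or_antihistamine_rx")
  bad_pat <- unique(prescriptions$patient_id[!prescriptions$valid])
  step(!(patients$patient_id %in% bad_pat), "no_missing_prescription_fields")

  rx_keep <- prescriptions[prescriptions$patient_id %in% patients$patient_id, ,
                           drop = FALSE]
  rownames(rx_keep) <- NULL
  list(patients = patients, prescriptions = rx_keep, attrition = log)
}

#' Write the three claims tables to a directory
#' @param claims list(patients, prescriptions, ...) as from [generate_population()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_claims <- function(claims, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             prescriptions = file.path(dir, "prescriptions.csv"))
  rx <- claims$prescriptions
  rx$valid <- NULL
  write.csv(claims$patients, paths["patients"], row.names = FALSE, quote = FALSE)
  write.csv(rx, paths["prescriptions"], row.names = FALSE, quote = FALSE)
  if (!is.null(claims$truth)) {
    paths["truth"] <- file.path(dir, "truth.csv")
    write.csv(claims$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
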