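#' Per-patient LEDD increment ratio
#'
#' The screen's outcome statistic: for each patient,
#' \eqn{100 (LEDD_{after} - LEDD_{before}) / LEDD_{before}}, averaged over
#' the N contributing patients. Patients with a zero pre-index LEDD are
#' excluded (the ratio is undefined for them) and counted. This
#' mean-of-per-patient-ratios is *not* the ratio of group means; see
#' [aggregate_ratio()] for the latter.
#'
#' @param before,after Numeric vectors of window-averaged LEDD (mg/day),
#'   aligned by patient.
#' @return List of class `increment_ratio_result`: `n`, `per_patient_ratios`
#'   (percent), `mean_ratio` (percent), `n_excluded_zero_baseline`.
#' @export
#' @examples
#' increment_ratio(c(100, 200), c(110, 210))$mean_ratio # 7.5
increment_ratio <- function(before, after) {
  stopifnot(length(before) == length(after))
  keep <- !is.na(before) & !is.na(after) & before > 0
  n_zero <- sum(!is.na(before) & !is.na(after) & before == 0)
  if (!sum(keep)) {
    stop("no patients with positive pre-index LEDD: increment ratio undefined",
         call. = FALSE)
  }
  r <- 100 * (after[keep] - before[keep]) / before[keep]
  structure(list(n = sum(keep), per_patient_ratios = r, mean_ratio = mean(r),
                 n_excluded_zero_baseline = n_zero),
            class = "increment_ratio_result")
}

#' Aggregate (ratio-of-means) LEDD change
#'
#' `100 * (mean(after) - mean(before)) / mean(before)` — the percent change
#' of the group-mean LEDD. Kept as a distinct code path from
#' [increment_ratio()] because the two definitions agree only when all
#' baselines are equal.
#' @inheritParams increment_ratio
#' @return Percent change of the group mean.
#' @export
aggregate_ratio <- function(before, after) {
  keep <- !is.na(before) & !is.na(after)
  100 * (mean(after[keep]) - mean(before[keep])) / mean(before[keep])
}

#' Compare increment ratios between two groups
#'
#' Two-sided unpaired t-test on the per-patient increment ratios (Welch by
#' default; Student's pooled-variance test optional). Degenerate inputs are
#' handled explicitly: two identical constant samples give t = 0, p = 1.
#'
#' @param exposed,unexposed `increment_ratio_result` objects or numeric
#'   vectors of per-patient ratios.
#' @param method `"welch"` (default) or `"student"`.
#' @return List `t, df, p, mean_exposed, mean_unexposed, method`.
#' @export
compare_groups <- function(exposed, unexposed, method = c("welch", "student")) {
  method <- match.arg(method)
  x <- if (inherits(exposed, "increment_ratio_result"))
    exposed$per_patient_ratios else as.numeric(exposed)
  y <- if (inherits(unexposed, "increment_ratio_result"))
    unexposed$per_patient_ratios else as.numeric(unexposed)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 per-patient ratios", call. = FALSE)
  }
  if (sd(x) == 0 && sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2,
                p = if (same) 1 else 0,
                mean_exposed = mean(x), mean_unexposed = mean(y),
                method = method))
  }
  tt <- stats::t.test(x, y, var.equal = (method == "student"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_exposed = mean(x), mean_unexposed = mean(y),
       method = method)
}

#' Benjamini-Hochberg adjustment of a screen report
#'
#' Appends a `p_adjusted` column to the report using the BH step-up rule
#' over the non-missing p-values. The default for [run_screen()] is no
#' adjustment (each drug's raw p-value is reported).
#'
#' @param report A `screen_report` data.frame with a `p_value` column.
#' @param method `"none"` or `"benjamini_hochberg"`.
#' @return The report, with `p_adjusted` appended unless `method = "none"`.
#' @export
adjust_pvalues <- function(report, method = c("none", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (method == "none") return(report)
  report$p_adjusted <- p.adjust(report$p_value, method = "BH")
  report
}

# covariates used for propensity matching: sex, age at diagnosis, cumulative
# pre-index days of PD-drug coverage, and pre-index window LEDD
matching_covariates <- function(patients, prescriptions, index_tab,
                                window_days, drug_table) {
  rx <- data.table::as.data.table(prescriptions)
  rx <- rx[drug_class == "pd_drug",
           .(patient_id, prescription_date, period_days)]
  it <- data.table::as.data.table(index_tab)
  rx <- rx[it, on = "patient_id", nomatch = NULL]
  rx[, overlap_days := pmax(0, pmin(prescription_date + period_days,
                                    index_date) - prescription_date)]
  cum <- rx[, .(levodopa_rx_period = sum(overlap_days)), by = patient_id]
  pre <- ledd_windows_cohort(prescriptions, index_tab, "before",
                             window_days, drug_table)
  cov <- data.frame(patient_id = index_tab$patient_id, stringsAsFactors = FALSE)
  cov$sex <- as.integer(patients$sex[match(cov$patient_id,
                                           patients$patient_id)] == "male")
  cov$age_at_diagnosis <- patients$age_at_diagnosis[match(cov$patient_id,
                                                          patients$patient_id)]
  cov$levodopa_rx_period <-
    cum$levodopa_rx_period[match(cov$patient_id, cum$patient_id)]
  cov$levodopa_rx_period[is.na(cov$levodopa_rx_period)] <- 0
  cov$pre_index_ledd <- pre$ledd_before[match(cov$patient_id, pre$patient_id)]
  cov
}

# one exposed-vs-unexposed comparison: index dates, covariates, matching,
# windows, increment ratios, t-test. `exp_ids` selects the exposed subset
# under analysis; all unexposed patients form the control pool.
screen_one <- function(label, exp_ids, assignments, patients, prescriptions,
                       episodes, ah_rx, drug_table, params) {
  res <- list(drug = label, exposed_n = length(exp_ids))
  if (length(exp_ids) < params$min_group) {
    res$note <- "skipped: too few exposed patients"
    return(res)
  }
  sub <- assignments[assignments$group == "unexposed" |
                       assignments$patient_id %in% exp_ids, , drop = FALSE]
  sub <- assign_index_dates(sub, patients, episodes, ah_rx,
                            median_interval = NULL,
                            window_days = params$window_days,
                            horizon = params$horizon,
                            index_mode = params$index_mode)
  res$median_interval_days <- attr(sub, "median_interval")
  sub <- sub[sub$window_ok, , drop = FALSE]
  is_exp <- sub$patient_id %in% exp_ids
  if (sum(is_exp) < params$min_group || sum(!is_exp) < params$min_group) {
    res$note <- "skipped: too few patients with complete windows"
    return(res)
  }
  index_tab <- data.frame(patient_id = sub$patient_id,
                          index_date = sub$index_date,
                          stringsAsFactors = FALSE)
  cov <- matching_covariates(patients, prescriptions, index_tab,
                             params$window_days, drug_table)
  ps <- fit_propensity(cov, is_exp)
  mc <- nearest_neighbor_match(ps, is_exp, sub$patient_id,
                               ratio = params$ratio, caliper = params$caliper,
                               caliper_units = params$caliper_units,
                               strict = params$strict, covariates = cov)
  res$exposed_n_matched <- length(mc$matched_exposed)
  res$controls_n_matched <- length(mc$matched_controls)
  res$max_smd_post <- suppressWarnings(max(mc$balance$smd_post, na.rm = TRUE))
  res$max_smd_pre <- max(mc$balance$smd_pre, na.rm = TRUE)
  res$balance <- mc$balance
  if (res$exposed_n_matched < params$min_group) {
    res$note <- "skipped: too few matched exposed patients"
    return(res)
  }
  keep_ids <- c(mc$matched_exposed, mc$matched_controls)
  mt <- index_tab[index_tab$patient_id %in% keep_ids, , drop = FALSE]
  before <- ledd_windows_cohort(prescriptions, mt, "before",
                                params$window_days, drug_table)
  after <- ledd_windows_cohort(prescriptions, mt, "after",
                               params$window_days, drug_table)
  w <- data.frame(patient_id = mt$patient_id,
                  ledd_before = before$ledd_before,
                  ledd_after = after$ledd_after,
                  exposed = mt$patient_id %in% mc$matched_exposed,
                  stringsAsFactors = FALSE)
  grp <- function(e) {
    d <- w[w$exposed == e, , drop = FALSE]
    ir <- increment_ratio(d$ledd_before, d$ledd_after)
    contrib <- d$ledd_before > 0
    list(ir = ir,
         before = mean(d$ledd_before[contrib]),
         after = mean(d$ledd_after[contrib]),
         n_zero = ir$n_excluded_zero_baseline)
  }
  ge <- grp(TRUE); gu <- grp(FALSE)
  cmp <- compare_groups(ge$ir, gu$ir, method = params$ttest)
  res <- c(res, list(
    unexposed_ledd_before = gu$before, unexposed_ledd_after = gu$after,
    unexposed_difference = ledd_difference(gu$before, gu$after),
    unexposed_ratio = gu$ir$mean_ratio, unexposed_n = gu$ir$n,
    exposed_ledd_before = ge$before, exposed_ledd_after = ge$after,
    exposed_difference = ledd_difference(ge$before, ge$after),
    exposed_ratio = ge$ir$mean_ratio, exposed_contrib_n = ge$ir$n,
    n_excluded_zero_baseline = ge$n_zero + gu$n_zero,
    t = cmp$t, p_value = cmp$p
  ))
  res
}

#' Run the drug-repurposing screen
#'
#' Full pipeline on a claims extract: exclusion rules, antihistamine exposure
#' episodes, single-agent classification, per-scope median-interval index
#' dates, pre-index covariates, 1:`ratio` propensity matching, before/after
#' window LEDDs, per-patient increment ratios and the two-group t-test. One
#' report row per requested scope: `overall` pools all exposed patients,
#' `generation` pools 1st- and 2nd-generation antihistamine users, `drug`
#' screens each agent separately. Each scope recomputes its own median
#' interval from its own exposed patients.
#'
#' @param claims list(patients, prescriptions) or the output of
#'   [generate_population()] / [read_claims()].
#' @param drug_table LED conversion / drug-class table.
#' @param scope Character subset of `c("overall", "generation", "drug")`.
#' @param drugs Antihistamine codes to screen (default: all in the drug table).
#' @param window_days,gap_days,min_duration_days,ratio,caliper,caliper_units,strict,ttest,adjust,index_mode,gap_basis
#'   Pipeline parameters; defaults follow the study design (90-day windows,
#'   31-day continuity gap, episodes qualifying beyond 31 days, 1:3 matching
#'   with a 0.25-SD caliper, Welch test, no multiplicity adjustment).
#' @param horizon Observed data horizon in days; `NULL` infers the maximum
#'   prescription coverage end.
#' @param min_group Minimum exposed/unexposed patients for a scope to be
#'   analysed rather than skipped (default 10).
#' @param verbose Log per-stage cohort counts to stderr.
#' @return Object of class `screen_report`: a data.frame with one row per
#'   scope (n's, before/after/difference/ratio per group, t, p), with
#'   attributes `attrition` (the exclusion log), `assignments`, and `details`
#'   (per-row balance tables and notes).
#' @export
run_screen <- function(claims, drug_table = default_drug_table(),
                       scope = c("overall", "generation", "drug"),
                       drugs = NULL,
                       window_days = 90L, gap_days = 31L,
                       min_duration_days = 31L, ratio = 3L, caliper = 0.25,
                       caliper_units = "sd", strict = TRUE,
                       ttest = "welch", adjust = "none",
                       index_mode = "first_qualifying",
                       gap_basis = "coverage_end",
                       horizon = NULL, min_group = 10L, verbose = FALSE) {
  scope <- match.arg(scope, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  patients <- claims$patients
  prescriptions <- flag_prescriptions(claims$prescriptions)
  if (is.null(horizon)) {
    ok <- prescriptions$valid
    horizon <- max(prescriptions$prescription_date[ok] +
                     prescriptions$period_days[ok])
  }
  say("input: %d patients, %d prescription rows", nrow(patients),
      nrow(prescriptions))
  excl <- apply_exclusions(patients, prescriptions)
  patients <- excl$patients
  prescriptions <- excl$prescriptions
  for (i in seq_len(nrow(excl$attrition))) {
    say("  %-36s removed %6d remaining %6d", excl$attrition$rule[i],
        excl$attrition$n_removed[i], excl$attrition$n_remaining[i])
  }
  ah_rx <- prescriptions[prescriptions$drug_class == "antihistamine", ,
                         drop = FALSE]
  episodes <- build_episodes(ah_rx, gap_days = gap_days,
                             min_duration_days = min_duration_days,
                             gap_basis = gap_basis)
  assignments <- classify_patients(patients, episodes, ah_rx)
  say("groups: %d exposed, %d unexposed, %d multi-antihistamine excluded",
      sum(assignments$group == "exposed"),
      sum(assignments$group == "unexposed"),
      sum(assignments$group == "excluded_multi_type"))

  params <- list(window_days = window_days, ratio = ratio, caliper = caliper,
                 caliper_units = caliper_units, strict = strict,
                 ttest = ttest, index_mode = index_mode, horizon = horizon,
                 min_group = min_group)
  exp_mask <- assignments$group == "exposed"
  rows <- list()
  if ("overall" %in% scope) {
    rows[["Overall"]] <- screen_one("Overall", assignments$patient_id[exp_mask],
                                    assignments, patients, prescriptions,
                                    episodes, ah_rx, drug_table, params)
  }
  gen_of <- drug_table$generation[match(assignments$exposed_drug,
                                        drug_table$drug_code)]
  if ("generation" %in% scope) {
    for (g in c(1, 2)) {
      lbl <- sprintf("%s generation", c("1st", "2nd")[g])
      ids <- assignments$patient_id[exp_mask & !is.na(gen_of) & gen_of == g]
      rows[[lbl]] <- screen_one(lbl, ids, assignments, patients, prescriptions,
                                episodes, ah_rx, drug_table, params)
    }
  }
  if ("drug" %in% scope) {
    if (is.null(drugs)) {
      drugs <- drug_table$drug_code[drug_table$class == "antihistamine"]
    }
    for (g in c(1, 2)) {
      gd <- sort(intersect(drugs, drug_table$drug_code[
        drug_table$class == "antihistamine" &
          !is.na(drug_table$generation) & drug_table$generation == g]))
      for (d in gd) {
        ids <- assignments$patient_id[exp_mask & assignments$exposed_drug == d &
                                        !is.na(assignments$exposed_drug)]
        rows[[d]] <- screen_one(d, ids, assignments, patients, prescriptions,
                                episodes, ah_rx, drug_table, params)
      }
    }
  }

  num_cols <- c("exposed_n", "median_interval_days", "exposed_n_matched",
                "controls_n_matched", "unexposed_n", "exposed_contrib_n",
                "unexposed_ledd_before", "unexposed_ledd_after",
                "unexposed_difference", "unexposed_ratio",
                "exposed_ledd_before", "exposed_ledd_after",
                "exposed_difference", "exposed_ratio",
                "n_excluded_zero_baseline", "t", "p_value",
                "max_smd_pre", "max_smd_post")
  report <- do.call(rbind, lapply(rows, function(r) {
    v <- lapply(num_cols, function(cn) if (is.null(r[[cn]])) NA_real_ else r[[cn]])
    names(v) <- num_cols
    cbind(data.frame(drug = r$drug, stringsAsFactors = FALSE),
          as.data.frame(v),
          data.frame(note = if (is.null(r$note)) "" else r$note,
                     stringsAsFactors = FALSE))
  }))
  rownames(report) <- NULL
  report <- adjust_pvalues(report, method = adjust)
  class(report) <- c("screen_report", class(report))
  attr(report, "attrition") <- excl$attrition
  attr(report, "assignments") <- assignments
  attr(report, "details") <- lapply(rows, function(r)
    r[intersect(c("balance", "note"), names(r))])
  report
}

#' @exportS3Method base::print
print.screen_report <- function(x, digits = 3, ...) {
  cat("LEDD increment-ratio screen\n")
  df <- as.data.frame(x)
  show <- c("drug", "exposed_n", "exposed_n_matched",
            "unexposed_ledd_before", "unexposed_ledd_after",
            "unexposed_difference", "unexposed_ratio",
            "exposed_ledd_before", "exposed_ledd_after",
            "exposed_difference", "exposed_ratio", "p_value")
  if ("p_adjusted" %in% names(df)) show <- c(show, "p_adjusted")
  out <- df[, show]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  print(out, row.names = FALSE, ...)
  invisible(x)
}
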