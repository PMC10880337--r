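#' Levodopa-equivalent dose of one prescription
#'
#' Converts a PD-drug prescription's daily dose to mg/day of levodopa
#' equivalents using the drug table's conversion rule. `factor` rules return
#' `parameter * daily_dose`; `levodopa_fraction` rules (adjuncts such as
#' entacapone) need the concurrent levodopa LED and are therefore evaluated
#' inside [ledd_window()]; `none` rules (decarboxylase inhibitors) contribute 0.
#'
#' @param record One prescription row (list/data.frame with `drug_code`,
#'   `daily_dose`).
#' @param drug_table Drug table (see [default_drug_table()]).
#' @return LED in mg/day of levodopa equivalents.
#' @export
#' @examples
#' led_of(list(drug_code = "pramipexole", daily_dose = 1), default_drug_table())
led_of <- function(record, drug_table) {
  i <- match(record$drug_code, drug_table$drug_code)
  if (anyNA(i)) {
    stop("drug_code not in conversion table: ",
         paste(unique(record$drug_code[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  rule <- drug_table$rule_type[i]
  if (any(rule == "levodopa_fraction")) {
    stop("adjunct drug(s) ",
         paste(unique(record$drug_code[rule == "levodopa_fraction"]), collapse = ", "),
         " need the concurrent levodopa dose; use ledd_window()", call. = FALSE)
  }
  ifelse(rule == "factor", drug_table$parameter[i] * record$daily_dose, 0)
}

# vectorised window LEDD for a whole cohort: time-averaged daily LED over the
# half-open window [index - window_days, index) or [index, index + window_days).
# `index_tab` is data.frame(patient_id, index_date). Adjunct
# (levodopa_fraction) rows contribute parameter x the concurrent levodopa LED
# on each shared covered day, evaluated day-by-day on the window only.
ledd_windows_cohort <- function(prescriptions, index_tab, side,
                                window_days = 90L, drug_table,
                                cumulative = FALSE) {
  stopifnot(side %in% c("before", "after"))
  rx <- data.table::as.data.table(prescriptions)
  rx <- rx[drug_class == "pd_drug"]
  out <- data.table::data.table(patient_id = index_tab$patient_id,
                                index_date = index_tab$index_date)
  if (!nrow(rx)) {
    res <- data.frame(patient_id = out$patient_id, value = 0)
    names(res)[2] <- paste0("ledd_", side)
    return(res)
  }
  i <- match(rx$drug_code, drug_table$drug_code)
  if (anyNA(i)) {
    stop("drug_code not in conversion table: ",
         paste(unique(rx$drug_code[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  rx[, `:=`(rule = drug_table$rule_type[i], par = drug_table$parameter[i])]
  rx <- rx[out, on = "patient_id", nomatch = NULL]
  if (side == "before") {
    rx[, `:=`(win_start = index_date - as.integer(window_days),
              win_end = index_date)]
  } else {
    rx[, `:=`(win_start = index_date,
              win_end = index_date + as.integer(window_days))]
  }
  rx[, rx_end := prescription_date + period_days]
  rx[, overlap_days := pmax(0, pmin(rx_end, win_end) -
                              pmax(prescription_date, win_start))]
  rx <- rx[overlap_days > 0]

  simple <- rx[rule == "factor",
               .(led_days = sum(par * daily_dose * overlap_days)),
               by = patient_id]
  adj <- rx[rule == "levodopa_fraction"]
  if (nrow(adj)) {
    # day-by-day: adjunct LED on a day = par x levodopa LED that day
    ldopa <- rx[drug_code == "levodopa"]
    adj_days <- adj[, {
      days <- seq(max(prescription_date, win_start),
                  min(rx_end, win_end) - 1L)
      .(day = days, par = rep(par, length(days)))
    }, by = .(patient_id, seq_len(nrow(adj)))]
    if (nrow(ldopa)) {
      ldopa_days <- ldopa[, {
        days <- seq(max(prescription_date, win_start),
                    min(rx_end, win_end) - 1L)
        .(day = days, led = rep(par * daily_dose, length(days)))
      }, by = .(patient_id, seq_len(nrow(ldopa)))]
      ldopa_days <- ldopa_days[, .(led = sum(led)), by = .(patient_id, day)]
      adj_days <- ldopa_days[adj_days, on = c("patient_id", "day")]
      adj_days[is.na(led), led := 0]
    } else {
      adj_days[, led := 0]
    }
    adj_sum <- adj_days[, .(led_days = sum(par * led)), by = patient_id]
    simple <- data.table::rbindlist(list(simple, adj_sum))
    simple <- simple[, .(led_days = sum(led_days)), by = patient_id]
  }
  out <- simple[out, on = "patient_id"]
  out[is.na(led_days), led_days := 0]
  val <- if (cumulative) out$led_days else out$led_days / window_days
  res <- data.frame(patient_id = out$patient_id, value = val,
                    stringsAsFactors = FALSE)
  names(res)[2] <- paste0("ledd_", side)
  res
}

#' Window-averaged LEDD for one patient
#'
#' Time-averaged daily levodopa-equivalent dose over the 90-day (by default)
#' window before or after the index date: the sum over PD-drug prescriptions
#' of LED x (days of the prescription's half-open coverage interval that fall
#' inside the half-open window), divided by `window_days`. Prescriptions
#' spanning a window edge contribute pro-rata. With `cumulative = TRUE` the
#' raw LED-days sum is returned instead.
#'
#' @param prescriptions The patient's prescription rows (pd_drug rows used).
#' @param index Index date (day offset).
#' @param side `"before"` for `[index - window_days, index)`, `"after"` for
#'   `[index, index + window_days)`.
#' @param window_days Window length in days (default 90, i.e. 3 months).
#' @param drug_table LED conversion table.
#' @param cumulative Report cumulative LED-days instead of the daily average.
#' @param horizon Optional observed horizon; a window extending outside
#'   `[0, horizon]` gets attribute `flagged = TRUE`.
#' @return mg/day (or mg-days if cumulative), with attribute `flagged`.
#' @export
ledd_window <- function(prescriptions, index, side = c("before", "after"),
                        window_days = 90L, drug_table = default_drug_table(),
                        cumulative = FALSE, horizon = NULL) {
  side <- match.arg(side)
  pid <- unique(prescriptions$patient_id)
  if (length(pid) > 1L) {
    stop("ledd_window() is per-patient; got ", length(pid), " patients",
         call. = FALSE)
  }
  if (!length(pid)) pid <- "patient"
  prescriptions$patient_id <- pid[1]
  res <- ledd_windows_cohort(prescriptions,
                             data.frame(patient_id = pid[1], index_date = index),
                             side, window_days, drug_table, cumulative)
  val <- res[[2]][1]
  lo <- if (side == "before") index - window_days else index
  hi <- if (side == "before") index else index + window_days
  flagged <- lo < 0 || (!is.null(horizon) && hi > horizon)
  attr(val, "flagged") <- flagged
  val
}

#' LEDD difference
#'
#' The change in window-averaged LEDD across the index date, `after - before`,
#' in mg/day.
#' @param before,after Window-averaged LEDD values (mg/day).
#' @return `after - before`.
#' @export
#' @examples
#' ledd_difference(253.307, 266.844) # 13.537
ledd_difference <- function(before, after) {
  after - before
}
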