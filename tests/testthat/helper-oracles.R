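# Brute-force reference implementations, deliberately independent of the
# package's vectorised code paths: everything here works day by day on a
# boolean calendar or by exhaustive enumeration.

# episodes via a boolean day calendar: mark covered days, find maximal runs,
# then merge consecutive runs whose gap is < gap_days
oracle_episodes_one <- function(dates, periods, gap_days = 31, min_dur = 31) {
  if (!length(dates)) return(NULL)
  maxd <- max(dates + periods)
  cal <- logical(maxd + 1)
  for (i in seq_along(dates)) {
    if (periods[i] > 0) cal[(dates[i] + 1):(dates[i] + periods[i])] <- TRUE
  }
  runs <- rle(cal)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- data.frame(start = starts[runs$values] - 1, end = ends[runs$values])
  # merge segments separated by < gap_days
  merged <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg) - 1) + 1) {
    if (seg$start[i] - merged$end[nrow(merged)] < gap_days) {
      merged$end[nrow(merged)] <- seg$end[i]
    } else {
      merged <- rbind(merged, seg[i, ])
    }
  }
  merged$duration <- merged$end - merged$start
  merged$qualifying <- merged$duration > min_dur
  merged
}

# day-by-day window LEDD: average daily levodopa-equivalent dose over the
# half-open window, evaluating adjunct (levodopa_fraction) rules against the
# concurrent levodopa LED on each single day
oracle_ledd_window <- function(rx, index, side, window_days, drug_table) {
  days <- if (side == "before") {
    seq(index - window_days, index - 1)
  } else {
    seq(index, index + window_days - 1)
  }
  rx <- rx[rx$drug_class == "pd_drug", , drop = FALSE]
  total <- 0
  for (d in days) {
    on_d <- rx$prescription_date <= d & d < rx$prescription_date + rx$period_days
    led_d <- 0
    ldopa_d <- 0
    for (i in which(on_d)) {
      j <- match(rx$drug_code[i], drug_table$drug_code)
      if (drug_table$rule_type[j] == "factor") {
        contrib <- drug_table$parameter[j] * rx$daily_dose[i]
        led_d <- led_d + contrib
        if (rx$drug_code[i] == "levodopa") ldopa_d <- ldopa_d + contrib
      }
    }
    for (i in which(on_d)) {
      j <- match(rx$drug_code[i], drug_table$drug_code)
      if (drug_table$rule_type[j] == "levodopa_fraction") {
        led_d <- led_d + drug_table$parameter[j] * ldopa_d
      }
    }
    total <- total + led_d
  }
  total / window_days
}

# increment ratio by explicit loop
oracle_increment_ratio <- function(before, after) {
  rs <- c()
  for (i in seq_along(before)) {
    if (before[i] > 0) rs <- c(rs, 100 * (after[i] - before[i]) / before[i])
  }
  mean(rs)
}

# greedy 1:k matching by exhaustive subset enumeration: exposed in descending
# score order; each unit takes the k-subset of available controls (within the
# absolute caliper) minimising total distance
oracle_match <- function(scores, exposed, ids, ratio, caliper_abs,
                         strict = TRUE) {
  e <- which(exposed)
  e <- e[order(-scores[e], ids[e])]
  avail <- which(!exposed)
  out <- list()
  for (i in e) {
    d <- abs(scores[avail] - scores[i])
    inc <- avail[d <= caliper_abs]
    if (length(inc) >= ratio) {
      subs <- utils::combn(seq_along(inc), ratio)
      tot <- colSums(matrix(abs(scores[inc[subs]] - scores[i]), nrow = ratio))
      pick <- inc[subs[, which.min(tot)]]
      out[[ids[i]]] <- sort(ids[pick])
      avail <- setdiff(avail, pick)
    } else if (!strict && length(inc) > 0) {
      out[[ids[i]]] <- sort(ids[inc])
      avail <- setdiff(avail, inc)
    }
  }
  out
}

# random small prescription set for property tests
random_rx <- function(n, pid = "X", drug = "ah1", max_day = 200) {
  data.frame(
    patient_id = pid,
    drug_code = drug,
    drug_class = "antihistamine",
    prescription_date = sample.int(max_day, n, replace = TRUE) - 1L,
    period_days = sample.int(40, n, replace = TRUE),
    daily_dose = 1, single_dose = 1,
    stringsAsFactors = FALSE
  )
}
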