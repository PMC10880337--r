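#' Configuration for the synthetic claims generator
#'
#' Bundles and validates every knob of the synthetic claims simulator. The
#' defaults describe a cohort that looks like a national-registry Parkinson's
#' disease (PD) extract at desk scale: baseline levodopa-equivalent daily dose
#' (LEDD) around 250 mg/day, dose progression of about 9% per 90-day window,
#' a quarter of patients exposed to an antihistamine, and a median
#' diagnosis-to-first-antihistamine interval of roughly 750 days.
#'
#' @param n_patients Number of patients to simulate (>= 1).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output tables.
#' @param baseline_ledd_mean,baseline_ledd_sd Mean and SD (mg/day) of the
#'   latent baseline LEDD, i.e. the dose level in the 90 days just before a
#'   patient's exposure anchor date.
#' @param progression_per_window_mean,progression_per_window_sd Mean and SD of
#'   the per-patient dose progression, in percent per 90-day window. Draws may
#'   be negative (dose reductions happen in practice).
#' @param exposure_effect Fraction in \[0, 1\] by which exposure multiplies the
#'   progression increment after the anchor date: 0 = no effect, 1 = full
#'   suppression of progression.
#' @param exposure_prevalence Baseline fraction of patients assigned to
#'   antihistamine exposure.
#' @param confounding_strength Log-odds of exposure per SD of latent baseline
#'   severity. Positive values make sicker (higher-LEDD, faster-progressing)
#'   patients more likely to be exposed, so propensity matching has real work
#'   to do.
#' @param multi_drug_fraction Fraction of antihistamine users additionally
#'   given a second, distinct antihistamine (these patients fail the
#'   single-agent exposure criterion downstream).
#' @param missing_field_fraction Fraction of prescription rows with one of
#'   period/daily-dose/single-dose deliberately blanked.
#' @param gap_days_distribution List describing the mixture of
#'   inter-prescription gaps for antihistamine refills: `p_short` is the
#'   probability of a short (continuity-preserving) gap drawn uniformly from
#'   `short`, otherwise a long gap from `long` (episode break).
#' @param study_horizon_days Length of the observation period in days; all
#'   dates are integer day offsets from day 0.
#' @param invalid_patient_fraction Fraction of patients deliberately generated
#'   invalid (half diagnosed before age 40, half with no prescriptions at
#'   all), to exercise the exclusion rules.
#' @param severity_progression_cor Correlation between latent baseline
#'   severity and the per-patient progression percent; with
#'   `confounding_strength > 0` this makes naive exposed/unexposed
#'   comparisons genuinely confounded.
#'
#' @return A validated list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_patients = 100, seed = 1)
simulation_config <- function(n_patients,
                              seed = 1L,
                              baseline_ledd_mean = 250,
                              baseline_ledd_sd = 50,
                              progression_per_window_mean = 9,
                              progression_per_window_sd = 15,
                              exposure_effect = 0,
                              exposure_prevalence = 0.25,
                              confounding_strength = 0,
                              multi_drug_fraction = 0.05,
                              missing_field_fraction = 0.02,
                              gap_days_distribution = list(
                                p_short = 0.75, short = c(1L, 25L),
                                long = c(40L, 200L)
                              ),
                              study_horizon_days = 1825L,
                              invalid_patient_fraction = 0.01,
                              severity_progression_cor = 0.3) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    baseline_ledd_mean = baseline_ledd_mean,
    baseline_ledd_sd = baseline_ledd_sd,
    progression_per_window_mean = progression_per_window_mean,
    progression_per_window_sd = progression_per_window_sd,
    exposure_effect = exposure_effect,
    exposure_prevalence = exposure_prevalence,
    confounding_strength = confounding_strength,
    multi_drug_fraction = multi_drug_fraction,
    missing_field_fraction = missing_field_fraction,
    gap_days_distribution = gap_days_distribution,
    study_horizon_days = as.integer(study_horizon_days),
    invalid_patient_fraction = invalid_patient_fraction,
    severity_progression_cor = severity_progression_cor
  )
  check_scalar <- function(field, lo = -Inf, hi = Inf) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      stop(sprintf("invalid simulation_config field '%s': must be a number in [%s, %s]",
                   field, format(lo), format(hi)), call. = FALSE)
    }
  }
  check_scalar("n_patients", lo = 1)
  check_scalar("baseline_ledd_mean", lo = .Machine$double.eps)
  check_scalar("baseline_ledd_sd", lo = 0)
  check_scalar("progression_per_window_mean")
  check_scalar("progression_per_window_sd", lo = 0)
  for (f in c("exposure_effect", "exposure_prevalence", "multi_drug_fraction",
              "missing_field_fraction", "invalid_patient_fraction")) {
    check_scalar(f, lo = 0, hi = 1)
  }
  check_scalar("confounding_strength")
  check_scalar("study_horizon_days", lo = 1)
  check_scalar("severity_progression_cor", lo = -1, hi = 1)
  g <- cfg$gap_days_distribution
  if (!is.list(g) || !all(c("p_short", "short", "long") %in% names(g)) ||
      g$p_short < 0 || g$p_short > 1 || length(g$short) != 2L || length(g$long) != 2L) {
    stop("invalid simulation_config field 'gap_days_distribution'", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Piecewise-constant daily LEDD trajectory
#'
#' The latent dose-need model: daily levodopa-equivalent need is constant
#' within 90-day blocks and each successive block exceeds the previous by
#' `progression_pct * (1 - effect)` percent (compounded), starting from
#' `baseline` in the first block. Values are floored at zero.
#'
#' @param baseline Starting daily dose, mg/day (> 0).
#' @param progression_pct Percent increase per 90-day block; may be negative.
#' @param effect Fraction in \[0, 1\] suppressing the progression increment.
#' @param horizon Number of days to generate (>= 1).
#' @param block_days Block length in days (default 90).
#' @return Numeric vector of length `horizon`: mg/day on each day.
#' @export
#' @examples
#' generate_trajectory(100, 10, 0, 180)[c(1, 91)] # 100, 110
generate_trajectory <- function(baseline, progression_pct, effect = 0,
                                horizon, block_days = 90L) {
  if (!is.numeric(baseline) || baseline <= 0) {
    stop("baseline must be a positive dose (mg/day)", call. = FALSE)
  }
  if (!is.numeric(horizon) || horizon < 1) {
    stop("horizon must be >= 1 day", call. = FALSE)
  }
  if (effect < 0 || effect > 1) stop("effect must be in [0, 1]", call. = FALSE)
  g <- 1 + progression_pct * (1 - effect) / 100
  block <- floor((seq_len(horizon) - 1) / block_days)
  pmax(0, baseline * g^block)
}

# block value of the latent trajectory relative to a patient's anchor date.
# Block m = floor((day - anchor)/90). The block just before the anchor
# (m = -1) sits at the baseline; post-anchor blocks compound with the
# (possibly exposure-attenuated) factor g_post, pre-anchor blocks unwind with
# the untreated factor g_pre. Vectorised over days/patients.
anchored_dose <- function(day, anchor, baseline, g_pre, g_post) {
  m <- floor((day - anchor) / 90)
  expo <- m + 1
  ifelse(expo <= 0, baseline * g_pre^expo, baseline * g_post^expo)
}

#' Generate a synthetic claims extract
#'
#' Produces a patient table, a prescription table, and a latent truth table
#' with the statistical structure the downstream screen assumes: PD drug
#' dispensings in ~30-day periods realising an upward-drifting LEDD
#' trajectory, antihistamine refill runs with realistic gaps, confounded
#' exposure assignment, multi-antihistamine users, deliberately missing
#' prescription fields, and a small fraction of invalid patients.
#'
#' Each patient has a latent severity \eqn{z \sim N(0,1)} driving baseline
#' LEDD, (partially) the progression rate, and — via a logistic link with
#' slope `confounding_strength` — the probability of antihistamine exposure.
#' Exposure-assigned patients start their first antihistamine refill run at an
#' anchor date `pd_diagnosis_date + interval`, with intervals drawn
#' log-normally (median ~752 days); from the anchor on, their progression
#' increment is multiplied by `1 - exposure_effect`. The first run always
#' spans more than 31 days (two refills separated by a short gap), so assigned
#' exposure qualifies under the episode rules unless it is truncated by the
#' study horizon.
#'
#' The latent dose trajectory of each patient is anchored where the screen
#' will measure it: exposure-assigned patients carry `baseline_ledd` in the 90
#' days before their own anchor, while unexposed patients carry it in the 90
#' days before `pd_diagnosis_date + m`, with `m` the median interval of the
#' qualifying single-agent exposed patients (the index date the median-
#' transfer strategy will assign them). The `baseline_ledd_*` parameters
#' therefore describe dose levels at the index date, the scale on which a
#' screen report states group means.
#'
#' @param config A [simulation_config()].
#' @return A list with `patients`, `prescriptions` (both data.frames in the
#'   claims schema) and `truth`, the per-patient latent values: severity,
#'   baseline LEDD, progression percent, assigned exposure, qualification,
#'   multi-antihistamine flag, drug, anchor date, and the true per-patient
#'   increment ratio (percent) at the index date.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_patients
  horizon <- config$study_horizon_days

  ids <- sprintf("P%06d", seq_len(n))
  sex <- ifelse(runif(n) < 0.6, "male", "female")
  age <- pmax(40L, as.integer(round(rnorm(n, 67, 9))))
  diag_date <- as.integer(floor(runif(n, 0, min(366, horizon))))

  z <- rnorm(n)
  baseline <- pmax(50, config$baseline_ledd_mean + config$baseline_ledd_sd * z)
  rho <- config$severity_progression_cor
  prog <- config$progression_per_window_mean +
    config$progression_per_window_sd * (rho * z + sqrt(1 - rho^2) * rnorm(n))
  prog <- pmax(prog, -90) # keep the multiplicative factor positive

  p_expose <- plogis(qlogis(config$exposure_prevalence) +
                       config$confounding_strength * z)
  exposed <- runif(n) < p_expose
  # latent anchor: diagnosis-to-first-antihistamine interval, median ~752 d;
  # the 182-day floor keeps the pre-index window inside the treated period
  interval <- 182L + as.integer(round(rlnorm(n, log(570), 0.6)))
  anchor <- diag_date + interval

  # deliberately invalid patients: half under-age at diagnosis, half with no
  # prescriptions at all
  n_bad <- rbinom(1, n, config$invalid_patient_fraction)
  bad <- sample.int(n, n_bad)
  bad_age <- bad[seq_len(floor(n_bad / 2))]
  bad_norx <- setdiff(bad, bad_age)
  if (length(bad_age)) {
    age[bad_age] <- sample(25:39, length(bad_age), replace = TRUE)
  }

  ## --- antihistamine plan for exposure-assigned patients ---
  ah_codes <- antihistamine_codes()
  # sampling weights shaped like a real exposed cohort (chlorpheniramine/
  # dimenhydrinate heavy, clemastine/desloratadine rare)
  ah_w <- c(azelastine = 1098, bepotastine = 2086, cetirizine = 1685,
            chlorpheniramine = 4832, clemastine = 28, desloratadine = 65,
            dimenhydrinate = 6481, ebastine = 599, fexofenadine = 1356,
            hydroxyzine = 2050, ketotifen = 147, levocetirizine = 2384,
            loratadine = 374, mizolastine = 40, olopatadine = 965)
  stopifnot(all(names(ah_w) %in% ah_codes))
  exp_idx <- which(exposed & !(seq_len(n) %in% bad_norx))
  ne <- length(exp_idx)
  multi_type <- logical(n)
  qualifies <- logical(n)
  ah_drug <- rep(NA_character_, n)
  if (ne) {
    ah_drug[exp_idx] <- sample(names(ah_w), ne, replace = TRUE, prob = ah_w)
    # first refill run: two prescriptions separated by a short gap, so the
    # run spans > 31 days unless the study horizon truncates it
    p1 <- sample(26:30, ne, replace = TRUE)
    gap1 <- sample(0:20, ne, replace = TRUE)
    p2 <- sample(26:30, ne, replace = TRUE)
    second_start <- anchor[exp_idx] + p1 + gap1
    has2 <- second_start < horizon & anchor[exp_idx] < horizon
    span <- ifelse(has2, pmin(second_start + p2, horizon),
                   pmin(anchor[exp_idx] + p1, horizon)) - anchor[exp_idx]
    qualifies[exp_idx] <- anchor[exp_idx] < horizon & span > 31
    n_multi <- rbinom(1, ne, config$multi_drug_fraction)
    mi <- if (n_multi > 0) sample.int(ne, n_multi) else integer(0)
    multi_type[exp_idx[mi]] <- TRUE
  }

  # reference anchor for unexposed trajectories: the median interval of the
  # patients the screen will classify as exposed (qualifying, single-agent).
  # Patients whose assigned exposure never qualifies in the observed data
  # (horizon truncation) are anchored like the unexposed and carry no
  # exposure effect: their exposure is unobservable.
  med_pool <- interval[exposed & qualifies & !multi_type &
                         !(seq_len(n) %in% bad_age)]
  anchor_ref <- if (length(med_pool)) stats::median(med_pool) else 752
  eff_seen <- exposed & qualifies
  anchor_used <- ifelse(eff_seen, anchor, diag_date + anchor_ref)

  g_pre <- 1 + prog / 100
  g_post <- 1 + prog * (1 - ifelse(eff_seen, config$exposure_effect, 0)) / 100

  ## --- PD prescriptions: ~monthly dispensings with a per-patient therapy
  ## start delay (0-90 d after diagnosis), small Poisson refill slippage and,
  ## for about 60% of patients, one longer therapy interruption, so
  ## pre-index treatment histories vary between patients. The interruption is
  ## placed before the pre-index measurement window: peri-index dose
  ## trajectories stay fully observed (a documented simplification; real
  ## interruptions also overlap measurement windows and add outcome noise)
  pd_drugs <- c(levodopa = 1, pramipexole = 100, ropinirole = 20,
                rasagiline = 100, selegiline = 10)
  drug_idx <- sample.int(5L, n, replace = TRUE,
                         prob = c(0.7, 0.12, 0.1, 0.04, 0.04))
  pd_drug <- names(pd_drugs)[drug_idx]
  pd_factor <- unname(pd_drugs[drug_idx])
  start_delay <- sample(0:90, n, replace = TRUE)
  pd_start <- diag_date + start_delay
  max_rx <- as.integer(ceiling(horizon / 30)) + 1L
  slip <- matrix(stats::rpois(n * max_rx, 1.5), n, max_rx)
  slip[, 1] <- 0L
  rx_date_m <- pd_start + t(apply(slip + 30L, 1, cumsum)) - 30L
  # therapy interruption: a refill-free hole of up to ~400 days ending well
  # before the pre-index window (90-day window plus one refill cycle), so
  # coverage has resumed by the time measurement starts
  hole_room <- pmax(0, anchor_used - 130 - pd_start)
  hole_len <- ifelse(runif(n) < 0.6, pmin(floor(runif(n, 30, 400)), hole_room), 0)
  hole_start <- pd_start + floor(runif(n) * (hole_room - hole_len + 1))
  in_hole <- rx_date_m >= hole_start & rx_date_m < hole_start + hole_len
  keep_rx <- rx_date_m < horizon & !in_hole
  keep_rx[bad_norx, ] <- FALSE
  pid_rep <- row(rx_date_m)[keep_rx]
  ord <- order(pid_rep, rx_date_m[keep_rx])
  pid_rep <- pid_rep[ord]
  rx_date <- rx_date_m[keep_rx][ord]
  rx_period <- pmin(30L, horizon - rx_date)
  dose_mg <- anchored_dose(rx_date, anchor_used[pid_rep], baseline[pid_rep],
                           g_pre[pid_rep], g_post[pid_rep])
  pd_tab <- data.table::data.table(
    patient_id = ids[pid_rep],
    drug_code = pd_drug[pid_rep],
    drug_class = "pd_drug",
    prescription_date = rx_date,
    period_days = rx_period,
    daily_dose = round(dose_mg / pd_factor[pid_rep], 6),
    single_dose = round(dose_mg / pd_factor[pid_rep] / 3, 6)
  )

  ## --- antihistamine prescriptions ---
  ah_list <- list()
  if (ne) {
    gdist <- config$gap_days_distribution
    n_more <- sample(2:8, ne, replace = TRUE)
    max_more <- max(n_more)
    starts <- matrix(NA_integer_, ne, 2L + max_more)
    periods <- matrix(NA_integer_, ne, 2L + max_more)
    starts[, 1] <- anchor[exp_idx]; periods[, 1] <- p1
    starts[, 2] <- second_start; periods[, 2] <- p2
    cur_end <- second_start + p2
    for (j in seq_len(max_more)) {
      active <- n_more >= j
      na_ <- sum(active)
      if (!na_) break
      short <- runif(na_) < gdist$p_short
      gap <- integer(na_)
      gap[short] <- sample(gdist$short[1]:gdist$short[2], sum(short), replace = TRUE)
      gap[!short] <- sample(gdist$long[1]:gdist$long[2], sum(!short), replace = TRUE)
      per <- sample(14:30, na_, replace = TRUE)
      starts[active, 2L + j] <- cur_end[active] + gap
      periods[active, 2L + j] <- per
      cur_end[active] <- starts[active, 2L + j] + per
    }
    keep <- !is.na(starts) & starts < horizon
    row_of <- row(starts)[keep]
    ah_list$main <- data.table::data.table(
      patient_id = ids[exp_idx][row_of],
      drug_code = ah_drug[exp_idx][row_of],
      drug_class = "antihistamine",
      prescription_date = starts[keep],
      period_days = pmin(periods[keep], horizon - starts[keep]),
      daily_dose = 1, single_dose = 1
    )
    # multi-antihistamine users: prescriptions of a second distinct agent
    mi_idx <- which(multi_type[exp_idx])
    if (length(mi_idx)) {
      second <- vapply(ah_drug[exp_idx[mi_idx]],
                       function(d) sample(setdiff(names(ah_w), d), 1L), "")
      lo <- diag_date[exp_idx[mi_idx]]
      hi <- pmax(lo + 1, horizon - 30)
      sdate <- as.integer(floor(runif(length(mi_idx), lo, hi)))
      ah_list$multi <- data.table::data.table(
        patient_id = ids[exp_idx[mi_idx]],
        drug_code = unname(second),
        drug_class = "antihistamine",
        prescription_date = sdate,
        period_days = sample(7:20, length(mi_idx), replace = TRUE),
        daily_dose = 1, single_dose = 1
      )
    }
  }
  # occasional short antihistamine use among the non-exposed (non-qualifying)
  occ_idx <- which(!exposed & runif(n) < 0.10 & !(seq_len(n) %in% bad_norx))
  if (length(occ_idx)) {
    ah_list$occasional <- data.table::data.table(
      patient_id = ids[occ_idx],
      drug_code = sample(names(ah_w), length(occ_idx), replace = TRUE, prob = ah_w),
      drug_class = "antihistamine",
      prescription_date = as.integer(floor(runif(length(occ_idx), diag_date[occ_idx],
                                                 pmax(diag_date[occ_idx] + 1,
                                                      horizon - 14)))),
      period_days = sample(5:14, length(occ_idx), replace = TRUE),
      daily_dose = 1, single_dose = 1
    )
  }

  rx <- data.table::rbindlist(c(list(pd_tab), ah_list), use.names = TRUE)
  data.table::setorder(rx, patient_id, drug_class, drug_code, prescription_date)

  # deliberate missingness: blank one of the three dose fields per hit row.
  # Hits cluster within "missingness-prone" patients (incomplete records come
  # from the same source in real registries): the overall expected row
  # fraction stays at missing_field_fraction, while patient-level attrition
  # stays registry-like (~13% of patients at the 0.02 default) instead of the
  # near-total attrition independent row corruption would cause.
  f_prone <- min(1, config$missing_field_fraction / 0.15)
  q_row <- if (f_prone > 0) config$missing_field_fraction / f_prone else 0
  prone <- ids[runif(n) < f_prone]
  miss <- which(rx$patient_id %in% prone & runif(nrow(rx)) < q_row)
  if (length(miss)) {
    fld <- sample(c("period_days", "daily_dose", "single_dose"),
                  length(miss), replace = TRUE)
    for (f in c("period_days", "daily_dose", "single_dose")) {
      rows <- miss[fld == f]
      if (length(rows)) data.table::set(rx, i = rows, j = f, value = NA)
    }
  }

  patients <- data.frame(
    patient_id = ids, sex = sex, pd_diagnosis_date = diag_date,
    age_at_diagnosis = age, stringsAsFactors = FALSE
  )
  # true group/effect at the measured index date: the exposure effect is only
  # observable for patients whose assigned exposure qualifies in-horizon
  truth <- data.frame(
    patient_id = ids, severity = z, baseline_ledd = baseline,
    progression_pct = prog, exposed_assigned = exposed,
    qualifies = qualifies, multi_type = multi_type, ah_drug = ah_drug,
    interval_days = interval, anchor = anchor,
    true_group = ifelse(exposed & qualifies & multi_type, "excluded_multi_type",
                        ifelse(exposed & qualifies, "exposed", "unexposed")),
    true_increment_ratio = prog * (1 - ifelse(eff_seen, config$exposure_effect, 0)),
    stringsAsFactors = FALSE
  )
  attr(truth, "median_interval") <- anchor_ref
  list(patients = patients, prescriptions = as.data.frame(rx), truth = truth)
}
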