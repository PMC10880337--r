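mk_rx <- function(dates, periods, pid = "A", drug = "fexofenadine") {
  data.frame(patient_id = pid, drug_code = drug, drug_class = "antihistamine",
             prescription_date = as.integer(dates),
             period_days = as.integer(periods),
             daily_dose = 1, single_dose = 1, stringsAsFactors = FALSE)
}

test_that("episode construction handles the one-month boundary rules", {
  # gap 5 < 31: one episode [0, 45), qualifying (45 > 31)
  ep <- build_episodes(mk_rx(c(0, 25), c(20, 20)))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, 0)
  expect_equal(ep$end, 45)
  expect_equal(ep$duration_days, 45)
  expect_true(ep$qualifying)
  # a single 31-day prescription: duration 31 is NOT 'exceeding one month'
  ep <- build_episodes(mk_rx(0, 31))
  expect_equal(ep$duration_days, 31)
  expect_false(ep$qualifying)
  # gap exactly 31: two episodes, neither qualifying
  ep <- build_episodes(mk_rx(c(0, 41), c(10, 30)))
  expect_equal(nrow(ep), 2)
  expect_false(any(ep$qualifying))
  # overlapping refills merge into one span
  ep <- build_episodes(mk_rx(c(0, 10), c(30, 30)))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$end, 40)
  expect_error(build_episodes(mk_rx(0, 10), gap_days = -1), "non-negative")
})

test_that("episode builder matches the boolean-calendar oracle", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(1:6, 1)
    rx <- random_rx(n)
    ep <- build_episodes(rx)
    or <- oracle_episodes_one(rx$prescription_date, rx$period_days)
    expect_equal(ep$start, or$start, info = paste("instance", i))
    expect_equal(ep$end, or$end)
    expect_equal(ep$duration_days, or$duration)
    expect_equal(ep$qualifying, or$qualifying)
  }
})

test_that("episode merging is order-independent", {
  set.seed(7)
  for (i in 1:50) {
    rx <- random_rx(sample(2:8, 1))
    shuffled <- rx[sample.int(nrow(rx)), , drop = FALSE]
    expect_equal(build_episodes(rx), build_episodes(shuffled))
  }
})

test_that("patients partition into exposed / multi-type / unexposed", {
  pats <- data.frame(patient_id = c("one", "two", "short", "none"),
                     sex = "male", pd_diagnosis_date = 0L,
                     age_at_diagnosis = 60)
  ah <- rbind(
    mk_rx(c(100, 120), c(25, 25), pid = "one"),            # qualifying, single
    mk_rx(c(100, 120), c(25, 25), pid = "two"),            # qualifying ...
    mk_rx(300, 7, pid = "two", drug = "cetirizine"),       # ... but 2nd agent
    mk_rx(50, 10, pid = "short")                           # non-qualifying
  )
  eps <- build_episodes(ah)
  asg <- classify_patients(pats, eps, ah)
  expect_equal(asg$group[match(c("one", "two", "short", "none"),
                               asg$patient_id)],
               c("exposed", "excluded_multi_type", "unexposed", "unexposed"))
  expect_equal(asg$exposed_drug[asg$patient_id == "one"], "fexofenadine")
  expect_true(all(is.na(asg$exposed_drug[asg$group != "exposed"])))
  # every retained patient lands in exactly one group
  expect_equal(sort(asg$patient_id), sort(pats$patient_id))
})

test_that("median interval uses the even-count convention", {
  expect_equal(compute_median_interval(c(10, 20, 30)), 20)
  expect_equal(compute_median_interval(c(10, 20)), 15)
  expect_error(compute_median_interval(numeric(0)), "median")
})

test_that("index dates follow the median-transfer strategy", {
  pats <- data.frame(patient_id = c("e1", "e2", "u1", "far"),
                     sex = "male", pd_diagnosis_date = c(0L, 0L, 100L, 100L),
                     age_at_diagnosis = 60)
  ah <- rbind(
    mk_rx(300, 40, pid = "e1"),
    # e2: short early run, then the qualifying episode at day 800
    mk_rx(c(100, 800, 830), c(10, 28, 28), pid = "e2")
  )
  eps <- build_episodes(ah)
  asg <- classify_patients(pats, eps, ah)
  out <- assign_index_dates(asg, pats, eps, ah, window_days = 90,
                            horizon = 1200)
  idx <- function(id) out$index_date[out$patient_id == id]
  expect_equal(idx("e1"), 300L)
  # default anchor is the first *qualifying* episode, not the first ever rx
  expect_equal(idx("e2"), 800L)
  # exposed intervals {300, 800} -> median 550; unexposed diagnosed day 100
  expect_equal(attr(out, "median_interval"), 550)
  expect_equal(idx("u1"), 650L)
  # the literal first-ever prescription is available as a config
  out2 <- assign_index_dates(asg, pats, eps, ah, index_mode = "first_ever")
  expect_equal(out2$index_date[out2$patient_id == "e2"], 100L)
  # windows extending beyond the horizon are flagged
  out3 <- assign_index_dates(asg, pats, eps, ah, window_days = 90, horizon = 700)
  expect_false(out3$window_ok[out3$patient_id == "e2"])
  expect_true(out3$window_ok[out3$patient_id == "e1"])
  # the worked example: unexposed diagnosed day 100 with median 752 -> 852
  asg1 <- asg[asg$patient_id %in% c("e1", "u1"), ]
  out4 <- assign_index_dates(asg1, pats, eps, ah, median_interval = 752)
  expect_equal(out4$index_date[out4$patient_id == "u1"], 852L)
})
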