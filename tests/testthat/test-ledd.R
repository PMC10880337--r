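pd_rx <- function(dates, periods, doses, drug = "levodopa", pid = "A") {
  data.frame(patient_id = pid, drug_code = drug, drug_class = "pd_drug",
             prescription_date = as.integer(dates),
             period_days = as.integer(periods),
             daily_dose = doses, single_dose = doses / 3,
             stringsAsFactors = FALSE)
}

tab <- default_drug_table()

test_that("LED conversion applies the packaged factors", {
  expect_equal(led_of(list(drug_code = "levodopa", daily_dose = 300), tab), 300)
  # pramipexole 1 mg/day at the published factor 100
  expect_equal(led_of(list(drug_code = "pramipexole", daily_dose = 1), tab), 100)
  expect_equal(led_of(list(drug_code = "ropinirole", daily_dose = 2), tab), 40)
  # decarboxylase inhibitors carry no levodopa-equivalent
  expect_equal(led_of(list(drug_code = "carbidopa", daily_dose = 75), tab), 0)
  expect_error(led_of(list(drug_code = "unobtainium", daily_dose = 1), tab),
               "unobtainium")
  expect_error(led_of(list(drug_code = "entacapone", daily_dose = 600), tab),
               "ledd_window")
})

test_that("window LEDD averages coverage-weighted LED over 90 days", {
  # full coverage of the before-window at 300 mg/day
  rx <- pd_rx(0, 200, 300)
  expect_equal(ledd_window(rx, 100, "before"), 300, ignore_attr = TRUE)
  # half the window covered: 150
  rx <- pd_rx(55, 45, 300)
  expect_equal(ledd_window(rx, 100, "before"), 150, ignore_attr = TRUE)
  # 300 mg/day for [-90,-30), 400 mg/day for [-30,0): (300*60 + 400*30)/90
  rx <- pd_rx(c(10, 70), c(60, 30), c(300, 400))
  expect_equal(ledd_window(rx, 100, "before"), (300 * 60 + 400 * 30) / 90,
               ignore_attr = TRUE)
  # proration of a prescription spanning the window edge
  rx <- pd_rx(80, 40, 90)
  expect_equal(ledd_window(rx, 100, "after"), 90 * 20 / 90, ignore_attr = TRUE)
  # flagging when the window leaves the observed horizon
  v <- ledd_window(pd_rx(0, 200, 300), 150, "after", horizon = 200)
  expect_true(attr(v, "flagged"))
  v <- ledd_window(pd_rx(0, 200, 300), 100, "before", horizon = 200)
  expect_false(attr(v, "flagged"))
})

test_that("entacapone contributes a fraction of the concurrent levodopa LED", {
  rx <- rbind(pd_rx(10, 90, 300),
              pd_rx(40, 30, 600, drug = "entacapone"))
  # levodopa covers the whole window at 300; entacapone overlaps 30 days
  want <- (300 * 90 + 0.33 * 300 * 30) / 90
  expect_equal(ledd_window(rx, 100, "before"), want, ignore_attr = TRUE)
  # entacapone without any levodopa on board contributes nothing
  rx <- pd_rx(0, 200, 600, drug = "entacapone")
  expect_equal(ledd_window(rx, 100, "before"), 0, ignore_attr = TRUE)
})

test_that("window LEDD equals the day-by-day oracle on random instances", {
  set.seed(99)
  drugs <- c("levodopa", "pramipexole", "ropinirole", "entacapone")
  for (i in 1:1000) {
    n <- sample(1:5, 1)
    rx <- pd_rx(sample.int(260, n, replace = TRUE) - 1L,
                sample.int(120, n, replace = TRUE),
                round(runif(n, 50, 600)),
                drug = sample(drugs, n, replace = TRUE))
    index <- sample(95:200, 1)
    side <- sample(c("before", "after"), 1)
    got <- as.numeric(ledd_window(rx, index, side, drug_table = tab))
    want <- oracle_ledd_window(rx, index, side, 90, tab)
    expect_equal(got, want, tolerance = 1e-10, info = paste("instance", i))
  }
})

test_that("window LEDD is additive under prescription splitting and scales with dose", {
  set.seed(3)
  for (i in 1:50) {
    start <- sample(0:150, 1)
    len <- sample(20:80, 1)
    cut <- sample(seq_len(len - 1), 1)
    dose <- round(runif(1, 50, 500))
    whole <- pd_rx(start, len, dose)
    split <- pd_rx(c(start, start + cut), c(cut, len - cut), dose)
    index <- sample(90:180, 1)
    expect_equal(ledd_window(whole, index, "before"),
                 ledd_window(split, index, "before"))
    # doubling every daily dose doubles the window value
    doubled <- whole; doubled$daily_dose <- doubled$daily_dose * 2
    expect_equal(as.numeric(ledd_window(doubled, index, "before")),
                 2 * as.numeric(ledd_window(whole, index, "before")))
  }
})

test_that("cumulative mode reports LED-days instead of the daily average", {
  rx <- pd_rx(0, 200, 300)
  expect_equal(as.numeric(ledd_window(rx, 100, "before", cumulative = TRUE)),
               300 * 90)
})

test_that("ledd_difference is after minus before", {
  expect_equal(ledd_difference(100, 110), 10)
  expect_equal(ledd_difference(110, 110), 0)
  expect_equal(ledd_difference(110, 100), -10)
})
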