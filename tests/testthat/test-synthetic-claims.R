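test_that("config validation rejects bad values and names the field", {
  expect_error(simulation_config(0), "n_patients")
  expect_error(simulation_config(10, exposure_prevalence = 1.2),
               "exposure_prevalence")
  expect_error(simulation_config(10, baseline_ledd_sd = -1), "baseline_ledd_sd")
  expect_error(simulation_config(10, exposure_effect = -0.1), "exposure_effect")
  expect_error(simulation_config(10, gap_days_distribution = list(p_short = 2)),
               "gap_days_distribution")
})

test_that("trajectory blocks compound by progression_pct x (1 - effect)", {
  tr <- generate_trajectory(100, 10, 0, 180)
  expect_equal(unique(tr[1:90]), 100)
  expect_equal(unique(tr[91:180]), 110)
  # full suppression: flat at baseline
  expect_equal(unique(generate_trajectory(100, 10, 1, 300)), 100)
  # half suppression at the cohort defaults: 250 -> 261.25
  tr <- generate_trajectory(250, 9, 0.5, 180)
  expect_equal(unique(tr[91:180]), 261.25)
  # negative progression is allowed but the series never goes negative
  tr <- generate_trajectory(10, -80, 0, 90 * 10)
  expect_true(all(tr >= 0))
  expect_lt(tr[900], tr[1])
  expect_error(generate_trajectory(-5, 10, 0, 90), "baseline")
  expect_error(generate_trajectory(100, 10, 0, 0), "horizon")
})

test_that("identical config and seed give bit-identical tables", {
  cfg <- simulation_config(300, seed = 11, exposure_effect = 0.2,
                           confounding_strength = 0.4)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
})

test_that("generated tables respect the claims schema contracts", {
  cfg <- simulation_config(800, seed = 5)
  pop <- generate_population(cfg)
  expect_false(anyDuplicated(pop$patients$patient_id) > 0)
  # ages >= 40 except the deliberately invalid fraction
  n_young <- sum(pop$patients$age_at_diagnosis < 40)
  expect_lte(n_young, ceiling(0.02 * 800))
  rx <- flag_prescriptions(pop$prescriptions)
  # corrupted row fraction near the configured 2% (clustered corruption, so
  # the tolerance is wider than simple binomial error)
  expect_lt(abs(mean(!rx$valid) - 0.02), 0.02)
  # round trip through CSV is value-identical
  d <- withr::local_tempdir()
  paths <- write_claims(pop, d)
  back <- read_claims(paths[["patients"]], paths[["prescriptions"]])
  expect_equal(back$patients, pop$patients)
  expect_equal(back$prescriptions$daily_dose, pop$prescriptions$daily_dose)
  expect_equal(sum(!back$prescriptions$valid), sum(!rx$valid))
})

test_that("latent increment ratios are null when no effect, halved at effect 0.5", {
  null_diffs <- effect_ratios <- matrix(NA_real_, 6, 2)
  for (r in 1:6) {
    pop0 <- generate_population(simulation_config(3000, seed = 100 + r))
    tr0 <- pop0$truth
    g <- tr0$true_group
    null_diffs[r, ] <- c(mean(tr0$true_increment_ratio[g == "exposed"]),
                         mean(tr0$true_increment_ratio[g == "unexposed"]))
    pop5 <- generate_population(simulation_config(3000, seed = 100 + r,
                                                  exposure_effect = 0.5))
    tr5 <- pop5$truth
    g5 <- tr5$true_group
    effect_ratios[r, ] <- c(mean(tr5$true_increment_ratio[g5 == "exposed"]),
                            mean(tr5$true_increment_ratio[g5 == "unexposed"]))
  }
  # null: group means agree within 2 SE of the replicate-to-replicate spread
  d0 <- null_diffs[, 1] - null_diffs[, 2]
  expect_lt(abs(mean(d0)), 2 * sd(d0) / sqrt(length(d0)))
  # effect 0.5: exposed latent ratio is half the unexposed one
  ratio_of_means <- mean(effect_ratios[, 1]) / mean(effect_ratios[, 2])
  expect_lt(abs(ratio_of_means - 0.5), 0.06)
})

test_that("confounding shifts baseline severity of the exposed", {
  pop <- generate_population(simulation_config(4000, seed = 3,
                                               confounding_strength = 0.8))
  tr <- pop$truth
  expect_gt(mean(tr$severity[tr$exposed_assigned]),
            mean(tr$severity[!tr$exposed_assigned]) + 0.2)
})

test_that("the exposed group's measured median interval sits near 752 days", {
  pop <- generate_population(simulation_config(8000, seed = 21))
  ex <- apply_exclusions(pop$patients, pop$prescriptions)
  ah <- ex$prescriptions[ex$prescriptions$drug_class == "antihistamine", ]
  eps <- build_episodes(ah)
  asg <- classify_patients(ex$patients, eps, ah)
  asg <- assign_index_dates(asg, ex$patients, eps, ah)
  med <- attr(asg, "median_interval")
  expect_gt(med, 650)
  expect_lt(med, 860)
})
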