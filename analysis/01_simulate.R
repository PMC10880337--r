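#!/usr/bin/env Rscript

# Step 1 — simulate a claims extract.
# Writes patients.csv, prescriptions.csv and truth.csv (latent values, for
# validation only) under --out-dir.
#
#   Rscript analysis/01_simulate.R [--n 20000] [--seed 1] [--effect 0]
#                                  [--confounding 0] [--prevalence 0.25]
#                                  [--out-dir results/claims]

suppressPackageStartupMessages({
  library(optparse)
  library(leddscreen)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 20000L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--effect", type = "double", default = 0),
  make_option("--confounding", type = "double", default = 0),
  make_option("--prevalence", type = "double", default = 0.25),
  make_option("--out-dir", dest = "out_dir", type = "character",
              default = "results/claims")
)))

cfg <- simulation_config(
  n_patients = opts$n, seed = opts$seed,
  exposure_effect = opts$effect,
  confounding_strength = opts$confounding,
  exposure_prevalence = opts$prevalence
)
pop <- generate_population(cfg)
paths <- write_claims(pop, opts$out_dir)

rx <- flag_prescriptions(pop$prescriptions)
message(sprintf(
  "Simulated %d patients, %d prescription rows (%d with a missing field).",
  nrow(pop$patients), nrow(rx), sum(!rx$valid)))
message(sprintf(
  "Assigned exposure: %d patients (%.1f%%), of whom %d qualify in-horizon and %d use a second antihistamine.",
  sum(pop$truth$exposed_assigned),
  100 * mean(pop$truth$exposed_assigned),
  sum(pop$truth$qualifies), sum(pop$truth$multi_type)))
message(sprintf(
  "Latent median diagnosis-to-exposure interval: %.0f days.",
  attr(pop$truth, "median_interval")))
message("Wrote: ", paste(paths, collapse = ", "))
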