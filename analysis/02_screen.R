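#!/usr/bin/env Rscript

# Step 2 — run the full antihistamine screen on a claims extract
# (overall, by antihistamine generation, and per drug), mirroring the
# published table layout. Writes the report, the attrition log, and the
# covariate-balance table under results/.
#
#   Rscript analysis/02_screen.R [--claims-dir results/claims]
#                                [--out results/screen_report.csv]
#                                [--ttest welch] [--adjust none]

suppressPackageStartupMessages({
  library(optparse)
  library(leddscreen)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--claims-dir", dest = "claims_dir", type = "character",
              default = "results/claims"),
  make_option("--out", type = "character", default = "results/screen_report.csv"),
  make_option("--window-days", dest = "window_days", type = "integer", default = 90L),
  make_option("--gap-days", dest = "gap_days", type = "integer", default = 31L),
  make_option("--min-duration-days", dest = "min_dur", type = "integer", default = 31L),
  make_option("--ratio", type = "integer", default = 3L),
  make_option("--caliper", type = "double", default = 0.25),
  make_option("--ttest", type = "character", default = "welch"),
  make_option("--adjust", type = "character", default = "none")
)))

claims <- read_claims(file.path(opts$claims_dir, "patients.csv"),
                      file.path(opts$claims_dir, "prescriptions.csv"))
report <- run_screen(
  claims,
  window_days = opts$window_days, gap_days = opts$gap_days,
  min_duration_days = opts$min_dur, ratio = opts$ratio,
  caliper = opts$caliper, ttest = opts$ttest, adjust = opts$adjust,
  verbose = TRUE
)

print(report)
sig <- report[!is.na(report$p_value) & report$p_value < 0.05 &
                report$exposed_ratio < report$unexposed_ratio &
                report$drug %in% antihistamine_codes(), "drug"]
message(if (length(sig)) {
  paste("Drugs with significantly lower exposed increment ratio:",
        paste(sig, collapse = ", "))
} else "No single drug reaches p < 0.05 with a lower exposed increment ratio.")

dir.create(dirname(opts$out), showWarnings = FALSE, recursive = TRUE)
write.csv(as.data.frame(report), opts$out, row.names = FALSE)
write.csv(attr(report, "attrition"),
          file.path(dirname(opts$out), "attrition.csv"), row.names = FALSE)
details <- attr(report, "details")
bal <- do.call(rbind, lapply(names(details), function(k) {
  b <- details[[k]]$balance
  if (is.null(b)) return(NULL)
  cbind(drug = k, b)
}))
if (!is.null(bal)) {
  write.csv(bal, file.path(dirname(opts$out), "balance.csv"), row.names = FALSE)
}
message("Wrote ", opts$out)
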