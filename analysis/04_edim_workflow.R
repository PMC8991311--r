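#!/usr/bin/env Rscript

# The tiered indirect-matching workflow, demonstrated and calibrated.
#
# First the canonical two-brother scenario: one brother's case resolves
# by direct search; the other's is reached only through the shared Y-STR
# search key plus a sibling likelihood ratio, and is reported as a
# close-kin investigative lead naming the solved case's known individual.
# Then a calibrated experiment: with database sibship prevalence fixed at
# the twin-extrapolated 134,000/700,000 ratio, the measured close-kin
# uplift among otherwise-unsolved cases is compared with the analytic
# 19.14% sibling-match rate.

suppressPackageStartupMessages(library(edimatch))
dir.create("results", showWarnings = FALSE)

bd <- make_bob_doug_fixture()
reports <- run_edim(bd$indexes, edim_config(key_order = "y_str"))
cat("Two-brother scenario:\n")
print(reports[, c("case_id", "outcome", "matched_record", "anchor_case",
                  "log10_lr")])
write_lead_reports(reports, "results/edim_leads.jsonl")
write_lead_reports(reports, "results/edim_leads.csv", format = "csv")

cat("\nCalibrated uplift (10 replicates of 200 cases):\n")
uplift <- vapply(1:10, function(s) {
  simulate_edim_calibration(n_cases = 200, seed = 52000 + s)$uplift_pct
}, numeric(1))
cat(sprintf("  mean close-kin uplift %.2f%% (analytic sibling rate %.2f%%)\n",
            mean(uplift), twin_extrapolation(twin_inputs())$match_pct))

s <- summarize_run(reports)
out <- rbind(
  data.frame(metric = paste0("bobdoug_", s$counts$outcome),
             value = s$counts$n),
  data.frame(metric = c("bobdoug_uplift_pct", "calibrated_uplift_pct",
                        "analytic_sibling_pct"),
             value = c(s$uplift_pct, round_half_up(mean(uplift), 2),
                       twin_extrapolation(twin_inputs())$match_pct)))
write.csv(out, "results/edim_summary.csv", row.names = FALSE)
cat("wrote results/edim_leads.{jsonl,csv} and results/edim_summary.csv\n")
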