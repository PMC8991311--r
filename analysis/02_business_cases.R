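#!/usr/bin/env Rscript

# Cost-benefit analyses of database expansion.
#
# Three scenarios: (1) the realised state-database expansion, valued with
# published cost-of-crime and recidivism factors; (2) the identical-twin
# sibship extrapolation, which converts the twin-pair count found by
# database quality control into an expected sibling-match rate and a
# national projection for Y-STR indirect matching; (3) the limiting
# universal-database case.

suppressPackageStartupMessages(library(edimatch))
dir.create("results", showWarnings = FALSE)

cb <- expansion_cost_benefit(expansion_inputs())
cat("State expansion: ")
print(cb)

sib <- twin_extrapolation(twin_inputs())
cat("Twin extrapolation: ")
print(sib)

np <- edim_national_projection(twin_inputs())
cat("National projection: ")
print(np)

uc <- universal_db_case(universal_inputs())
cat("Universal database: ")
print(uc)

rows <- data.frame(
  quantity = c("expansion_benefit_usd", "expansion_cost_usd",
               "benefit_per_dollar", "roi_pct",
               "sibling_pairs", "sibling_match_pct",
               "additional_solved_annual", "prevented_assaults",
               "savings_billion_usd",
               "universal_additional_solved", "universal_benefit_usd",
               "universal_cost_usd"),
  value = c(cb$display$total_benefit, cb$total_cost,
            cb$display$benefit_per_dollar, cb$display$roi_pct,
            sib$sibling_pairs, sib$match_pct,
            np$additional_solved, np$prevented, np$savings_billion,
            uc$additional_solved, round_half_up(uc$total_benefit),
            uc$total_cost))
write.csv(rows, "results/business_cases.csv", row.names = FALSE)
cat("wrote results/business_cases.csv\n")
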