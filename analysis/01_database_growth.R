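#!/usr/bin/env Rscript

# Database growth vs cold-case hits.
#
# A single cold-case project's forensic profiles were static after 2004,
# so every later hit reflects growth of the state's known-offender index
# alone. Regressing cumulative hits on database size over the project's
# active period (5 points, 2003-2004) and over the full 18-year record
# (7 points) quantifies that relationship, and the reciprocal slope gives
# the headline "new profiles per additional hit".

suppressPackageStartupMessages(library(edimatch))
dir.create("results", showWarnings = FALSE)

early <- louisiana_hits_table("early")
full <- louisiana_hits_table("all")
fit_e <- fit_hits_regression(early)
fit_f <- fit_hits_regression(full)

cat("Active period (2003-2004):\n  ")
print(fit_e)
cat(sprintf("  -> one hit per %d new offender profiles\n",
            profiles_per_hit(fit_e$slope)))
cat("Full record (2003-2021):\n  ")
print(fit_f)
cat(sprintf("  -> 2021 standing ratio: 1 hit per %d database samples\n",
            ratio_per_hit(699618, 164)))
cat(sprintf("  -> project hit rate: %.0f%% (164 of 285 profiles)\n",
            hit_rate_pct(164, 285, decimals = 0)))
cat(sprintf("National: %.2f%% forensic hit rate; 1 hit per %.2f knowns\n",
            hit_rate_pct(587773, 1144255),
            ratio_per_hit(19350445, 587773, decimals = 2)))

tab <- data.frame(
  period = c("2003-2004", "2003-2021"),
  n_points = c(fit_e$n, fit_f$n),
  slope = round_half_up(c(fit_e$slope, fit_f$slope), 4),
  r2 = round_half_up(c(fit_e$r2, fit_f$r2), 4),
  profiles_per_hit = c(profiles_per_hit(fit_e$slope),
                       profiles_per_hit(fit_f$slope)))
write.csv(tab, "results/database_growth.csv", row.names = FALSE)
cat("wrote results/database_growth.csv\n")
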