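#!/usr/bin/env Rscript
# Stage 3: descriptive statistics and Mann-Whitney comparisons.
#
# For the pooled cohort and for each sex separately, compares every HRV
# feature between alert and fatigued segments (two-sided Mann-Whitney U,
# alpha = 0.01, no multiple-testing correction) and tabulates the
# direction of change from alert to fatigued.

library(hrvfatigue)

out_dir <- "results"
feats <- read.delim(file.path(out_dir, "features.tsv"))
if (!all(hrv_feature_names() %in% colnames(feats))) {
  stop("run analysis/02_extract_features.R first")
}

tabs <- list()
for (g in c("all", "male", "female")) {
  cmp <- compare_states(feats, g, alpha = 0.01)
  tabs[[g]] <- cmp
  write.table(cmp, file.path(out_dir, sprintf("comparison_%s.tsv", g)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("%-6s group: %2d of 20 features significant at p < 0.01\n",
              g, sum(cmp$significant)))
}

dirs <- direction_summary(tabs$all, tabs$male, tabs$female)
write.table(dirs, file.path(out_dir, "directions.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\ndirection of change (alert -> fatigued):\n")
print(dirs, row.names = FALSE)
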