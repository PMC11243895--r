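#!/usr/bin/env Rscript
# Stage 4: CART fatigue classifiers with exhaustive feature-subset search.
#
# For each group (pooled, male, female) and each subset size k = 2, 3, 4,
# enumerates every k-feature subset of the twenty HRV features (190, 1140
# and 4845 subsets), trains one Gini CART per subset on a shared stratified
# 8:2 split, and ranks subsets by held-out accuracy. Reports the best
# subset per group and size with SEN/SPE/PPV/ACC.

library(hrvfatigue)

seed <- 1L
out_dir <- "results"
feats <- read.delim(file.path(out_dir, "features.tsv"))
if (!all(hrv_feature_names() %in% colnames(feats))) {
  stop("run analysis/02_extract_features.R first")
}

best <- list()
for (g in c("all", "male", "female")) {
  gf <- if (g == "all") feats else feats[feats$sex == g, ]
  for (k in 2:4) {
    res <- exhaustive_subset_search(gf, k, min_samples = 5, seed = seed)
    write.table(head(res, 50),
                file.path(out_dir, sprintf("search_%s_k%d.tsv", g, k)),
                sep = "\t", row.names = FALSE, quote = FALSE)
    top <- res[1, ]
    best[[length(best) + 1]] <- data.frame(group = g, k = k,
                                           subset = top$subset,
                                           SEN = top$SEN, SPE = top$SPE,
                                           PPV = top$PPV, ACC = top$ACC)
    cat(sprintf("%-6s k=%d: %4d subsets | best %-38s ACC %5.1f%%\n",
                g, k, nrow(res), top$subset, top$ACC))
  }
}

summary_tab <- do.call(rbind, best)
write.table(summary_tab, file.path(out_dir, "best_classifiers.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("\nbest classifiers ->", file.path(out_dir, "best_classifiers.tsv"), "\n")
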