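#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study cohort and build labelled segments.
#
# 18 subjects (9 male, 9 female), 60-minute recordings, a single
# alert-to-fatigued changepoint per subject, five simulated raters per
# minute. The recording is cut into 59 overlapping 2-minute windows per
# subject and each window gets its expert-consensus label; discordant
# windows are dropped. Writes the segment table for the later stages.

library(hrvfatigue)

seed <- 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- cohort_config(n_male = 9, n_female = 9, duration_s = 3600,
                     seed = seed)
cohort <- simulate_cohort(cfg)
segs <- cohort_segments(cohort, cfg$duration_s, quiet = FALSE)
tab <- segment_table(segs)

write.table(tab, file.path(out_dir, "segments.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("subjects: %d, windows per subject: %d\n", length(cohort),
            attr(segs, "n_total") / length(cohort)))
print(table(tab$label, tab$sex))
cat(sprintf("discordant (excluded): %d of %d windows\n",
            attr(segs, "n_total") - nrow(tab), attr(segs, "n_total")))
cat("segment table ->", file.path(out_dir, "segments.tsv"), "\n")
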