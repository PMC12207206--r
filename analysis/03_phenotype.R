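#!/usr/bin/env Rscript
# Classify every post-ICI biopsy with the timeline rules (EOT window,
# 90-day resistance triggers, 180-day primary/acquired split) and report
# the filter cascade against the planted truth.

library(icirwe)
library(jsonlite)

tabs <- read_clinical_tables("results/sim")
truth <- read_json("results/sim/truth.json", simplifyVector = TRUE)

lab <- phenotype_cohort(tabs$biopsies, tabs$therapy_lines,
                        tabs$progression_events, tabs$patients)
write.csv(lab, "results/labels.csv", row.names = FALSE, quote = FALSE)
cas <- attr(lab, "cascade")
write_json(as.list(cas), "results/cascade.json", auto_unbox = TRUE)

cat("filter cascade:\n"); print(cas)
got <- lab$label[match(truth$patients$sample_id, lab$sample_id)]
cat("agreement with planted labels:",
    sprintf("%.1f%%", 100 * mean(got == truth$expected_label)), "\n")
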