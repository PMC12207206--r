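#!/usr/bin/env Rscript
# Apply the cohort inclusion/exclusion rules, then derive real-world OS and
# rwPFS for every patient from the therapy-line timelines, and summarize
# both with Kaplan-Meier estimates.

library(icirwe)

tabs <- read_clinical_tables("results/sim")
cc <- apply_cohort_criteria(tabs$patients, tabs$variants)
cat("included", length(cc$included), "of", nrow(tabs$patients),
    "patients; exclusions by first failing rule:\n")
print(cc$exclusion_counts)

os <- derive_endpoints(tabs$patients, tabs$therapy_lines,
                       tabs$progression_events, "os")
pfs <- derive_endpoints(tabs$patients, tabs$therapy_lines,
                        tabs$progression_events, "rwpfs")
out <- merge(os[, c("patient_id", "time_days", "event")],
             pfs[, c("patient_id", "time_days", "event")],
             by = "patient_id", suffixes = c("_os", "_rwpfs"))
write.csv(out, "results/outcomes.csv", row.names = FALSE, quote = FALSE)

km_os <- km_estimate(os); km_pfs <- km_estimate(pfs)
cat(sprintf("OS: %d events, median %s days\n", sum(os$event),
            format(km_os$median)))
cat(sprintf("rwPFS: %d events, median %s days\n", sum(pfs$event),
            format(km_pfs$median)))
cat("rwPFS <= OS for all patients:",
    all(pfs$time_days <= os$time_days[match(pfs$patient_id,
                                            os$patient_id)]), "\n")
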