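#!/usr/bin/env Rscript
# Simulate the accelerated-longitudinal multimodal cohort and export it as
# delimited text (parcellation, per-scan feature tables, manifest, FC
# matrices, ground-truth sidecar).

source("analysis/00_settings.R")

coh <- the_cohort()
print(coh)

msns <- cohort_msns(coh)
fcs <- cohort_fc(coh, msns, seed = SEED + 3L)
out <- file.path(RESULTS, "cohort")
write_cohort(coh, out, fc = fcs)
message("cohort exported to ", out)

meta <- cohort_meta(coh)
message(sprintf("scans: %d | subjects: %d | two-visit subjects: %d",
                nrow(meta), length(unique(meta$subject)),
                sum(table(meta$subject) >= 2)))
message(sprintf("age range %.1f-%.1f y, %.0f%% female",
                min(meta$age), max(meta$age),
                100 * mean(meta$sex[!duplicated(meta$subject)] == "F")))
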