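#!/usr/bin/env Rscript
# Quality control and morphometric similarity network construction: subject
# exclusion on robust global-feature outliers, region exclusion on zero-MAD
# features, per-scan MSNs and weighted degree.

source("analysis/00_settings.R")

coh <- the_cohort()
qc_s <- qc_subjects(coh)
message(sprintf("subject QC: %d excluded of %d",
                length(qc_s$excluded_subjects),
                length(unique(coh$meta$subject))))
coh$scans <- qc_s$kept
coh$meta <- cohort_meta(qc_s$kept)

qc_r <- qc_regions(coh)
message(sprintf("region QC: %d dropped, %d analyzed",
                length(qc_r$dropped_regions), length(qc_r$kept_regions)))

msns <- cohort_msns(coh, regions = qc_r$kept_regions)
k <- cohort_degrees(msns)
colnames(k) <- qc_r$kept_regions
meta <- cohort_meta(coh)

deg <- data.frame(meta[rep(seq_len(nrow(meta)), each = ncol(k)),
                       c("subject", "session", "age")],
                  region = rep(colnames(k), times = nrow(k)),
                  k = as.vector(t(k)))
write_tsv(deg, "degree_long.tsv")

message(sprintf("weighted degree: mean %.3f, range [%.3f, %.3f]",
                mean(k), min(k), max(k)))
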