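# Shared settings for the analysis scripts. Each numbered script is a thin
# driver over the msndev package; re-running any script reproduces its
# outputs exactly because every stage regenerates the cohort from this seed.

library(msndev)

SEED <- 20260922L
N_SUBJECTS <- 150L
N_REGIONS <- 90L
N_MODULES <- 5L
FDR_LEVEL <- 0.05
FC_DENSITY <- 0.10
N_PERM_SPIN <- 1000L

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

the_parcellation <- function() make_parcellation(N_REGIONS, N_MODULES, seed = SEED)

the_truth <- function(parc) default_ground_truth(parc, seed = SEED + 1L)

the_cohort <- function() {
  parc <- the_parcellation()
  simulate_cohort(cohort_design(n_subjects = N_SUBJECTS, seed = SEED + 2L),
                  parc, the_truth(parc))
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
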