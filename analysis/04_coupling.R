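#!/usr/bin/env Rscript
# Structure-function coupling: Fisher-transformed, motion-residualized FC
# edges, global and regional Spearman coupling against the MSN, and the
# mixed-model age trend of coupling.

source("analysis/00_settings.R")

coh <- the_cohort()
parc <- coh$parcellation
meta <- cohort_meta(coh)
msns <- cohort_msns(coh)
fcs_raw <- cohort_fc(coh, msns, seed = SEED + 3L)
fcs <- prepare_fc(fcs_raw, meta$mean_fd)

cpl <- cohort_coupling(msns, fcs)
message(sprintf("global coupling: mean rho %.3f (range %.3f to %.3f)",
                mean(cpl$global), min(cpl$global), max(cpl$global)))

cmap <- coupling_age_model(cpl, meta)
g <- attr(cmap, "global_coupling")
message(sprintf("age effect on global coupling: t = %.2f, p = %.2g",
                g$t_age, g$p_age))
write_tsv(cmap, "coupling_age_map.tsv")
write_tsv(data.frame(meta[, c("subject", "session", "age")],
                     global_rho = cpl$global), "coupling_global.tsv")

dk <- age_effect_map({k <- cohort_degrees(msns); colnames(k) <- parc$region_id; k},
                     meta)
co_base <- colocate(dk$baseline, cmap$baseline, parc, n_perm = N_PERM_SPIN,
                    seed = SEED + 5L)
co_chg <- colocate(dk$t, cmap$t, parc, n_perm = N_PERM_SPIN, seed = SEED + 6L)
message(sprintf("baseline degree vs baseline coupling: r = %.2f (p_spin %.3g)",
                co_base$observed, co_base$p_spin))
message(sprintf("degree change vs coupling change:     r = %.2f (p_spin %.3g)",
                co_chg$observed, co_chg$p_spin))
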