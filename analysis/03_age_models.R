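#!/usr/bin/env Rscript
# Age-trajectory models: global and regional age effects on the six
# morphometric features and on MSN weighted degree (the hubness map), with
# FDR control, zone aggregation and zone-block similarity trends.

source("analysis/00_settings.R")

coh <- the_cohort()
parc <- coh$parcellation
meta <- cohort_meta(coh)
msns <- cohort_msns(coh)

message("-- global feature trends --")
glob <- do.call(rbind, lapply(coh$truth$features, function(f) {
  v <- vapply(coh$scans, function(s) mean(s$features[, f]), numeric(1))
  fit <- fit_lme(data.frame(meta, value = v))
  data.frame(feature = f, beta_age = fit$beta_age, t_age = fit$t_age,
             p = fit$p_age)
}))
glob$q <- p.adjust(glob$p, method = "BH")
print(glob, digits = 3)
write_tsv(glob, "global_feature_trends.tsv")

message("-- regional degree age map --")
k <- cohort_degrees(msns)
colnames(k) <- parc$region_id
dk <- age_effect_map(k, meta, fdr_level = FDR_LEVEL)
write_tsv(dk, "degree_age_map.tsv")
message(sprintf("%d of %d regions significant at q < %.2f",
                sum(dk$q < FDR_LEVEL), nrow(dk), FDR_LEVEL))

message("-- cytoarchitectonic zone means of the degree age effect --")
za <- zone_aggregate(dk$t, parc)
print(za, digits = 3)
write_tsv(za, "zone_dk_means.tsv")

message("-- zone-block similarity trends --")
zb_list <- lapply(msns, zone_block_means, parcellation = parc)
blocks <- do.call(rbind, lapply(seq_len(nrow(zb_list[[1]])), function(r) {
  v <- vapply(zb_list, function(d) d$mean_edge[r], numeric(1))
  fit <- fit_lme(data.frame(meta, value = v))
  data.frame(zone_a = zb_list[[1]]$zone_a[r], zone_b = zb_list[[1]]$zone_b[r],
             t_age = fit$t_age, p = fit$p_age)
}))
blocks$q <- p.adjust(blocks$p, method = "BH")
print(blocks, digits = 3)
write_tsv(blocks, "zone_block_trends.tsv")

message("-- feature vs degree age-effect colocation --")
feat_maps <- lapply(setNames(nm = coh$truth$features), function(f) {
  vals <- t(vapply(coh$scans, function(s) s$features[, f],
                   numeric(nrow(parc))))
  age_effect_map(vals, meta)$t
})
fd <- feature_degree_correlation(feat_maps, dk$t, parc,
                                 n_perm = N_PERM_SPIN, seed = SEED + 4L)
print(fd, digits = 3)
write_tsv(fd, "feature_degree_colocation.tsv")
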