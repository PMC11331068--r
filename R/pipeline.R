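#' Default pipeline configuration
#'
#' Collects every tunable constant of the analysis in one serializable list:
#' cohort scale, QC thresholds (subject robust-z >= 5, region MAD = 0 is
#' structural), FDR level 0.05, baseline age 14, FC threshold density,
#' permutation counts, and stage toggles.
#'
#' @param seed mandatory integer seed for the whole run.
#' @param n_subjects,n_regions,n_modules synthetic cohort scale.
#' @param subject_mad_threshold subject-QC robust z cut.
#' @param fdr_level FDR significance level.
#' @param baseline_age age-centering constant in years.
#' @param fc_density proportional threshold for functional graphs.
#' @param n_perm_spin spin-test permutations.
#' @param run_robustness,robustness_reps toggle and replicate count for the
#'   robustness stage.
#' @return list of class `run_config`.
#' @export
default_config <- function(seed,
                           n_subjects = 150L,
                           n_regions = 90L,
                           n_modules = 5L,
                           subject_mad_threshold = 5,
                           fdr_level = 0.05,
                           baseline_age = 14,
                           fc_density = 0.10,
                           n_perm_spin = 500L,
                           run_robustness = FALSE,
                           robustness_reps = 10L) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              n_regions = as.integer(n_regions), n_modules = as.integer(n_modules),
              subject_mad_threshold = subject_mad_threshold,
              fdr_level = fdr_level, baseline_age = baseline_age,
              fc_density = fc_density, n_perm_spin = as.integer(n_perm_spin),
              run_robustness = isTRUE(run_robustness),
              robustness_reps = as.integer(robustness_reps))
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a configuration list.
#' @return the config, invisibly; errors on an invalid field.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1,
            cfg$n_subjects >= 10, cfg$n_regions >= 16,
            cfg$n_regions %% 2 == 0,
            cfg$subject_mad_threshold > 0,
            cfg$fdr_level > 0, cfg$fdr_level < 1,
            cfg$fc_density > 0, cfg$fc_density <= 1,
            cfg$n_perm_spin >= 10)
  invisible(cfg)
}

#' Read/write a configuration as JSON
#'
#' The serialized form round-trips losslessly through
#' [jsonlite::write_json()] / [jsonlite::read_json()].
#'
#' @param cfg a `run_config`.
#' @param path JSON file path.
#' @return `read_config` returns a validated `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> QC -> MSN -> degree age model -> zone summaries
#' -> structure-function coupling -> functional graph metrics -> map
#' colocations -> (optionally) robustness, and writes stage outputs plus a
#' machine-readable summary to `out_dir`. Re-running with the same config
#' produces byte-identical summary output.
#'
#' @param config a `run_config` from [default_config()].
#' @param out_dir output directory; created if absent. If NULL, nothing is
#'   written and the result list is only returned.
#' @return invisible list with all stage outputs and `summary` (the headline
#'   quantities: region counts after QC, significant-region counts, zone
#'   means of the degree t-map, global coupling age t, colocation statistics
#'   and sign checks).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_config(config)
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # stage 1: simulate -------------------------------------------------------
  parc <- make_parcellation(config$n_regions, config$n_modules,
                            seed = config$seed)
  truth <- default_ground_truth(parc, seed = config$seed + 1L)
  design <- cohort_design(n_subjects = config$n_subjects,
                          seed = config$seed + 2L)
  cohort <- simulate_cohort(design, parc, truth)
  say("simulate: %d scans / %d subjects / %d regions",
      nrow(cohort$meta), config$n_subjects, config$n_regions)

  # stage 2: QC -------------------------------------------------------------
  qc_s <- qc_subjects(cohort, threshold = config$subject_mad_threshold)
  cohort$scans <- qc_s$kept
  cohort$meta <- cohort_meta(qc_s$kept)
  qc_r <- qc_regions(cohort)
  keep_idx <- match(qc_r$kept_regions, parc$region_id)
  parc_kept <- parc[keep_idx, , drop = FALSE]
  class(parc_kept) <- class(parc)
  cohort$parcellation <- parc_kept
  say("qc: excluded %d subjects, dropped %d regions (%d analyzed)",
      length(qc_s$excluded_subjects), length(qc_r$dropped_regions),
      length(qc_r$kept_regions))

  # stage 3: MSN + degree age model -----------------------------------------
  msns <- cohort_msns(cohort, regions = qc_r$kept_regions)
  k <- cohort_degrees(msns)
  colnames(k) <- qc_r$kept_regions
  meta <- cohort_meta(cohort)
  dk <- age_effect_map(k, meta, baseline_age = config$baseline_age,
                       fdr_level = config$fdr_level)
  attr(dk, "degrees") <- k
  zones_dk <- zone_aggregate(dk$t, parc_kept)
  say("degree: %d/%d regions significant at q < %g",
      sum(dk$q < config$fdr_level), nrow(dk), config$fdr_level)

  # stage 4: coupling ---------------------------------------------------------
  fcs_raw <- cohort_fc(cohort, msns, seed = config$seed + 3L)
  fcs <- prepare_fc(fcs_raw, meta$mean_fd)
  cpl <- cohort_coupling(msns, fcs)
  cpl_map <- coupling_age_model(cpl, meta, baseline_age = config$baseline_age)
  g_cpl <- attr(cpl_map, "global_coupling")
  say("coupling: global age t = %.2f (p = %.3g)", g_cpl$t_age, g_cpl$p_age)

  # stage 5: functional graph metrics ----------------------------------------
  # thresholded topology needs the connectome itself, so graph metrics use the
  # Fisher-z FC; edgewise residualized values serve the coupling analyses
  fcs_graph <- lapply(fcs_raw, atanh)
  gm <- metric_age_maps(fcs_graph, meta, modules = parc_kept$module,
                        density = config$fc_density,
                        metrics = c("degree", "participation"),
                        baseline_age = config$baseline_age)
  say("graph: PC map, %d regions", nrow(gm$participation))

  # stage 6: colocation -------------------------------------------------------
  co_pc <- colocate(dk$t, gm$participation$t, parc_kept,
                    n_perm = config$n_perm_spin, seed = config$seed + 4L)
  co_cpl <- colocate(dk$t, cpl_map$t, parc_kept,
                     n_perm = config$n_perm_spin, seed = config$seed + 5L)
  say("colocation: dk~dPC r = %.3f (p_spin %.3g); dk~dcoupling r = %.3f (p_spin %.3g)",
      co_pc$observed, co_pc$p_spin, co_cpl$observed, co_cpl$p_spin)

  # stage 7: robustness (optional) --------------------------------------------
  rob <- NULL
  if (config$run_robustness) {
    rob <- list(
      ablation = ablation(cohort, fractions = c(0.75, 0.5),
                          n_reps = config$robustness_reps,
                          seed = config$seed + 6L),
      stability = rank_stability(cohort, dk_map = dk)
    )
    say("robustness: ablation + rank stability done")
  }

  zm <- stats::setNames(zones_dk$mean, zones_dk$zone)
  iso <- as.character(parc_kept$zone) != "paralimbic"
  summary <- list(
    seed = config$seed,
    n_scans = nrow(meta),
    n_subjects_analyzed = length(unique(meta$subject)),
    n_subjects_excluded = length(qc_s$excluded_subjects),
    n_regions_analyzed = length(qc_r$kept_regions),
    n_regions_dropped = length(qc_r$dropped_regions),
    n_sig_dk = sum(dk$q < config$fdr_level),
    zone_mean_dk_t = as.list(zm),
    frac_paralimbic_dk_pos = mean(dk$t[!iso] > 0),
    frac_isocortical_dk_neg = mean(dk$t[iso] < 0),
    global_coupling_t = g_cpl$t_age,
    global_coupling_p = g_cpl$p_age,
    dk_vs_dpc_r = co_pc$observed,
    dk_vs_dpc_p_spin = co_pc$p_spin,
    dk_vs_dcoupling_r = co_cpl$observed,
    dk_vs_dcoupling_p_spin = co_cpl$p_spin,
    sign_checks = list(
      paralimbic_dk_positive = zm[["paralimbic"]] > 0,
      isocortex_dk_negative = all(zm[c("idiotypic", "unimodal", "heteromodal")] < 0),
      coupling_declines = g_cpl$t_age < 0,
      dk_dpc_negative = co_pc$observed < 0,
      dk_dcoupling_positive = co_cpl$observed > 0
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
    .write_tsv(dk, file.path(out_dir, "degree_age_map.tsv"))
    .write_tsv(zones_dk, file.path(out_dir, "zone_dk.tsv"))
    .write_tsv(cpl_map, file.path(out_dir, "coupling_age_map.tsv"))
    .write_tsv(gm$participation, file.path(out_dir, "participation_age_map.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  say("pipeline done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(config = config, parcellation = parc_kept, cohort = cohort,
                 qc = list(subjects = qc_s$excluded_subjects,
                           regions = qc_r$dropped_regions),
                 dk_map = dk, zone_dk = zones_dk, coupling = cpl,
                 coupling_map = cpl_map, graph_maps = gm,
                 colocation = list(dk_pc = co_pc, dk_coupling = co_cpl),
                 robustness = rob, summary = summary))
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) signif(col, 10) else col
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
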