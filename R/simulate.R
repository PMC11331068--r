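#' Accelerated-longitudinal cohort design
#'
#' Describes the sampling frame of the synthetic cohort: subjects are
#' allocated evenly to age strata spanning the age range, with sex balanced
#' within each stratum; each subject contributes 1-3 scans at 6-18 month
#' intervals, and all ages remain inside the range.
#'
#' @param n_subjects number of subjects (default 291, the default analysis
#'   cohort scale).
#' @param age_range baseline-to-final age range in years.
#' @param visit_probs probabilities of a subject contributing 1, 2 or 3 scans.
#' @param gap_months admissible inter-visit gap range in months.
#' @param site_probs per-subject probabilities of the three scanning sites.
#' @param n_strata number of age strata.
#' @param seed integer seed; the single source of randomness for
#'   [simulate_cohort()].
#' @return a list of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 291L,
                          age_range = c(14, 26),
                          visit_probs = c(0.40, 0.50, 0.10),
                          gap_months = c(6, 18),
                          site_probs = c(0.70, 0.22, 0.08),
                          n_strata = 5L,
                          seed = 1L) {
  stopifnot(n_subjects >= 2, length(age_range) == 2, diff(age_range) > 0,
            length(visit_probs) == 3, abs(sum(visit_probs) - 1) < 1e-8,
            gap_months[1] >= 6, gap_months[2] <= 18,
            length(site_probs) == 3, n_strata >= 1)
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 visit_probs = visit_probs, gap_months = gap_months,
                 site_probs = site_probs, n_strata = as.integer(n_strata),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate an accelerated-longitudinal multimodal cohort
#'
#' Generates one scan record per session per subject under the generative
#' model described in [default_ground_truth()]: linear fixed effects of age,
#' sex and site per feature, a subject random intercept, i.i.d. residual
#' noise, and a zone-drift structural term that plants the morphometric
#' convergence/differentiation signal.
#'
#' Randomness is drawn from one stream seeded by `design$seed` for the
#' design-level assignments (strata, sexes, sites, visit counts, ages), then
#' split into one deterministic sub-stream per subject for subject-level
#' draws (random intercepts, noise, motion), so removing subjects does not
#' perturb the data of the remaining ones.
#'
#' @param design a [cohort_design()].
#' @param parcellation a [make_parcellation()] table.
#' @param truth a ground-truth object, e.g. [default_ground_truth()].
#' @return an object of class `msn_cohort`: list with `scans` (list of
#'   scan records: `subject_id`, `session`, `age`, `sex`, `site`, `mean_fd`,
#'   `features` region x 6 matrix), `meta` (one row per scan), and the
#'   `parcellation`, `design`, `truth` used.
#' @export
simulate_cohort <- function(design, parcellation, truth) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(parcellation, "parcellation"),
            inherits(truth, "msn_ground_truth"))
  n <- nrow(parcellation)
  ns <- design$n_subjects
  feats <- truth$features

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed %% .Machine$integer.max)

  # Design-level assignments ------------------------------------------------
  stratum <- rep_len(seq_len(design$n_strata), ns)
  sex <- character(ns)
  for (s in unique(stratum)) {           # balanced within stratum
    idx <- which(stratum == s)
    half <- length(idx) %/% 2
    lab <- c(rep("F", half), rep("M", length(idx) - half))
    sex[idx] <- sample(lab)
  }
  site <- paste0("site", sample.int(3, ns, replace = TRUE, prob = design$site_probs))
  nvis <- sample.int(3, ns, replace = TRUE, prob = design$visit_probs)
  edges <- seq(design$age_range[1], design$age_range[2],
               length.out = design$n_strata + 1)
  base_age <- stats::runif(ns, edges[stratum], edges[stratum + 1])
  gaps <- matrix(stats::runif(ns * 2, design$gap_months[1] / 12,
                              design$gap_months[2] / 12), ns, 2)
  # keep every session age inside the range
  tot <- ifelse(nvis >= 2, gaps[, 1], 0) + ifelse(nvis == 3, gaps[, 2], 0)
  base_age <- pmin(base_age, design$age_range[2] - tot)
  base_age <- pmax(base_age, design$age_range[1])

  drift_by_region <- truth$drift[as.character(parcellation$zone)]
  drift_c <- drift_by_region - mean(drift_by_region)
  para <- parcellation$zone == "paralimbic"
  load_base <- ifelse(para, -truth$loading, truth$loading)
  slope_mat <- matrix(truth$feature_slope, n, 6, byrow = TRUE) +
    outer(drift_c, truth$slope_het * truth$region_scale)
  scale_row <- matrix(truth$region_scale, n, 6, byrow = TRUE)
  zone_rows <- truth$zone_profile[as.character(parcellation$zone), , drop = FALSE]
  base_cm <- colMeans(outer(load_base, truth$gradient_profile) + zone_rows + truth$idio)

  scans <- list()
  meta <- list()
  subj_idio_sd <- if (is.null(truth$subject_idio_sd)) 0 else truth$subject_idio_sd
  for (i in seq_len(ns)) {
    set.seed(.subject_seed(design$seed, i))
    subj_int <- stats::rnorm(6, 0, truth$subject_sd)
    # stable per-subject regional signature (morphometric individuality):
    # constant across a subject's visits, centered across regions per feature
    # so the cortical grand mean keeps the specified subject intercept only
    if (subj_idio_sd > 0) {
      sidio <- matrix(stats::rnorm(n * 6, 0, subj_idio_sd), n, 6)
      sidio <- sweep(sidio, 2, colMeans(sidio)) * scale_row
    } else {
      sidio <- 0
    }
    sid <- sprintf("sub%04d", i)
    ages <- base_age[i] + cumsum(c(0, gaps[i, ]))[seq_len(nvis[i])]
    for (v in seq_len(nvis[i])) {
      a <- ages[v]
      d <- a - 14
      sc <- exp(-drift_by_region * d)
      # paralimbic convergence: the gradient anticorrelation decays with age;
      # isocortical differentiation: the shared zone profile decays while the
      # idiosyncratic profile persists, so regions lose their zone-shared
      # structure and stand increasingly on their individual morphometry
      load_age <- ifelse(para, -truth$loading * sc, truth$loading)
      zone_sc <- ifelse(para, 1, 1 / sc)
      struct <- outer(load_age, truth$gradient_profile) +
        zone_rows * zone_sc + truth$idio
      # per-feature recentering to the baseline column means keeps the
      # cortical grand mean exactly linear in age; a common offset cancels
      # in MSN standardization
      struct <- sweep(struct, 2, colMeans(struct) - base_cm)
      fx <- matrix(truth$feature_mean, n, 6, byrow = TRUE) +
        slope_mat * d +
        struct * scale_row + sidio +
        matrix(subj_int, n, 6, byrow = TRUE) +
        matrix(stats::rnorm(n * 6), n, 6) %*% diag(truth$residual_sd)
      if (sex[i] == "F") {
        fx <- fx + matrix(truth$sex_offset, n, 6, byrow = TRUE)
      }
      fx <- fx + matrix(truth$site_offset[site[i], ], n, 6, byrow = TRUE)
      dimnames(fx) <- list(parcellation$region_id, feats)
      fd <- stats::rlnorm(1, truth$fd_meanlog, truth$fd_sdlog)
      rec <- list(subject_id = sid, session = v, age = a, sex = sex[i],
                  site = site[i], mean_fd = fd, features = fx)
      class(rec) <- "scan_record"
      scans[[length(scans) + 1L]] <- rec
      meta[[length(meta) + 1L]] <- data.frame(
        subject = sid, session = v, age = a, sex = sex[i], site = site[i],
        mean_fd = fd, stringsAsFactors = FALSE)
    }
  }
  out <- list(scans = scans, meta = do.call(rbind, meta),
              parcellation = parcellation, design = design, truth = truth)
  class(out) <- "msn_cohort"
  out
}

.subject_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + i * 7919) %% 2147483629)
}

#' Simulate a functional connectome coupled to a structural network
#'
#' Generates one symmetric functional-connectivity (FC) matrix for a scan.
#' Each edge is built on a latent z-scale as a mixture of (i) the normal
#' quantile rank transform of the corresponding MSN edge, weighted by a
#' coupling strength `lambda_ij(age)`, and (ii) modular noise in which
#' within-module edges receive an age- and zone-dependent bonus; the latent
#' score is mapped through tanh so the output lies on the correlation scale,
#' as raw FC estimates would. The coupling strength declines with age
#' (structure-function decoupling), faster in isocortical regions.
#'
#' @param scan a scan record from [simulate_cohort()].
#' @param msn the scan's morphometric similarity matrix ([build_msn()]).
#' @param parcellation the parcellation (module and zone labels).
#' @param truth ground truth (coupling and modular-noise parameters).
#' @param seed integer seed for the edge noise.
#' @return symmetric region x region matrix with NA diagonal, entries in
#'   (-1, 1).
#' @export
simulate_fc <- function(scan, msn, parcellation, truth, seed = 1L) {
  n <- nrow(msn)
  stopifnot(n == nrow(parcellation))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  d <- scan$age - 14
  ut <- upper.tri(msn)
  vals <- msn[ut]
  q <- stats::qnorm((rank(vals) - 0.5) / length(vals))

  lam_g <- min(1, max(0, truth$lambda0 + truth$lambda_slope * d))
  m_i <- pmin(2, pmax(0.05,
    1 + truth$coupling_slope_zone[as.character(parcellation$zone)] * d))
  w_i <- pmin(2, pmax(0,
    1 + truth$pc_slope_zone[as.character(parcellation$zone)] * d))
  lam_ij <- lam_g * sqrt(outer(m_i, m_i))[ut]
  lam_ij <- pmin(1, pmax(0, lam_ij))
  same_mod <- outer(parcellation$module, parcellation$module, "==")[ut]
  bonus <- truth$fc_module_bonus * (outer(w_i, w_i, "+") / 2)[ut] * same_mod
  noise <- stats::rnorm(length(vals), 0, truth$fc_noise_sd)

  z <- truth$fc_scale * (lam_ij * q + (1 - lam_ij) * (noise + bonus))
  if (truth$motion_coupling != 0) {
    z <- z + truth$motion_coupling * scan$mean_fd
  }
  fc <- matrix(0, n, n, dimnames = dimnames(msn))
  fc[ut] <- tanh(z)
  fc <- fc + t(fc)
  diag(fc) <- NA_real_
  fc
}

#' Simulate functional connectomes for every scan of a cohort
#'
#' @param cohort an `msn_cohort`.
#' @param msns list of MSN matrices, one per scan (e.g. [cohort_msns()]).
#' @param truth ground truth; defaults to the cohort's.
#' @param seed base seed; scan `k` uses `seed + k`.
#' @return list of FC matrices.
#' @export
cohort_fc <- function(cohort, msns, truth = cohort$truth, seed = 1L) {
  stopifnot(length(msns) == length(cohort$scans))
  lapply(seq_along(cohort$scans), function(k) {
    simulate_fc(cohort$scans[[k]], msns[[k]], cohort$parcellation, truth,
                seed = seed + k)
  })
}

#' Write a cohort to delimited-text files
#'
#' Writes the parcellation table, one feature TSV per scan, a cohort
#' manifest, optional dense FC matrices, and a JSON sidecar with the full
#' ground truth, into `dir`.
#'
#' @param cohort an `msn_cohort`.
#' @param dir output directory (created if absent).
#' @param fc optional list of FC matrices to write alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, fc = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$parcellation
  utils::write.table(p, file.path(dir, "parcellation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  man <- cohort$meta
  man$file <- sprintf("%s_ses%02d_features.tsv", man$subject, man$session)
  for (k in seq_along(cohort$scans)) {
    sc <- cohort$scans[[k]]
    utils::write.table(
      data.frame(region_id = rownames(sc$features), sc$features,
                 check.names = FALSE),
      file.path(dir, man$file[k]), sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fc)) {
      utils::write.table(
        round(fc[[k]], 8),
        file.path(dir, sprintf("%s_ses%02d_fc.tsv", man$subject[k], man$session[k])),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  tr$idio <- NULL      # large; regenerable from the recorded seed
  tr$loading <- NULL
  jsonlite::write_json(unclass(tr), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from delimited-text files
#'
#' Reads back the directory layout produced by [write_cohort()]: the
#' parcellation table, the cohort manifest, one feature TSV per scan, and
#' optional dense FC matrices.
#'
#' @param dir directory written by [write_cohort()] (or any directory with
#'   the same layout, e.g. exported real data).
#' @param read_fc if TRUE, also read `*_fc.tsv` matrices.
#' @return an `msn_cohort` (with `fc` attached when read); the ground-truth
#'   sidecar, if present, is stored as `truth_json`.
#' @export
read_cohort <- function(dir, read_fc = FALSE) {
  parc <- utils::read.delim(file.path(dir, "parcellation.tsv"),
                            stringsAsFactors = FALSE)
  parc$zone <- factor(parc$zone, levels = c("idiotypic", "unimodal",
                                            "heteromodal", "paralimbic"))
  class(parc) <- c("parcellation", "data.frame")
  man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  scans <- vector("list", nrow(man))
  fc <- if (read_fc) vector("list", nrow(man)) else NULL
  for (k in seq_len(nrow(man))) {
    fx <- utils::read.delim(file.path(dir, man$file[k]), check.names = FALSE)
    m <- as.matrix(fx[, -1, drop = FALSE])
    rownames(m) <- fx$region_id
    rec <- list(subject_id = man$subject[k], session = man$session[k],
                age = man$age[k], sex = man$sex[k], site = man$site[k],
                mean_fd = man$mean_fd[k], features = m)
    class(rec) <- "scan_record"
    scans[[k]] <- rec
    if (read_fc) {
      fpath <- file.path(dir, sprintf("%s_ses%02d_fc.tsv", man$subject[k],
                                      man$session[k]))
      fm <- as.matrix(utils::read.delim(fpath, header = FALSE))
      dimnames(fm) <- list(parc$region_id, parc$region_id)
      diag(fm) <- NA_real_
      fc[[k]] <- fm
    }
  }
  out <- list(scans = scans, meta = man[, c("subject", "session", "age",
                                            "sex", "site", "mean_fd")],
              parcellation = parc, design = NULL, truth = NULL)
  tj <- file.path(dir, "ground_truth.json")
  if (file.exists(tj)) out$truth_json <- jsonlite::read_json(tj, simplifyVector = TRUE)
  if (read_fc) out$fc <- fc
  class(out) <- "msn_cohort"
  out
}

#' @export
print.msn_cohort <- function(x, ...) {
  cat(sprintf("msn_cohort: %d scans from %d subjects, %d regions\n",
              nrow(x$meta), length(unique(x$meta$subject)),
              nrow(x$parcellation)))
  cat(sprintf("ages %.1f-%.1f, sites: %s\n", min(x$meta$age), max(x$meta$age),
              paste(names(table(x$meta$site)), table(x$meta$site),
                    sep = "=", collapse = " ")))
  invisible(x)
}
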