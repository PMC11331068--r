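#' Age-effect t-map of MSN weighted degree for a cohort
#'
#' Convenience wrapper running the full degree pipeline (standardize, MSN,
#' weighted degree, per-region random-intercept age model) used by the
#' robustness analyses so that resampled and full-sample runs share one code
#' path.
#'
#' @param cohort an `msn_cohort` (or scan list).
#' @param regions optional region subset (post-QC).
#' @return an [age_effect_map()]; the per-scan degree matrix is in
#'   `attr(, "degrees")`.
#' @export
degree_age_map <- function(cohort, regions = NULL) {
  msns <- cohort_msns(cohort, regions = regions)
  k <- cohort_degrees(msns)
  colnames(k) <- rownames(msns[[1]])
  map <- age_effect_map(k, cohort_meta(cohort))
  attr(map, "degrees") <- k
  map
}

#' Ablation analysis: stability of the age-effect map under subsampling
#'
#' Repeatedly subsamples subjects (never individual scans, preserving the
#' longitudinal structure), re-runs the full degree pipeline, and records the
#' spatial (Pearson) correlation between the subsample t-map and the
#' full-sample t-map for each retained-sample fraction.
#'
#' @param cohort an `msn_cohort`.
#' @param fractions retained-subject fractions (1.0 is included implicitly
#'   as the reference).
#' @param n_reps replicates per fraction.
#' @param seed integer seed.
#' @param min_subjects smallest admissible subsample; smaller fractions are
#'   skipped with a warning.
#' @return data.frame of class `ablation_result`: `fraction`, `rep`,
#'   `n_subjects`, `cor_with_full`.
#' @export
ablation <- function(cohort, fractions = c(0.9, 0.75, 0.5, 0.25),
                     n_reps = 20L, seed = 1L, min_subjects = 20L) {
  subjects <- unique(cohort$meta$subject)
  full <- degree_age_map(cohort)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  rows <- list(data.frame(fraction = 1.0, rep = 1L,
                          n_subjects = length(subjects), cor_with_full = 1.0))
  for (f in sort(fractions, decreasing = TRUE)) {
    ns <- round(f * length(subjects))
    if (ns < min_subjects) {
      warning(sprintf("fraction %.2f leaves %d < %d subjects; skipped", f, ns, min_subjects))
      next
    }
    for (r in seq_len(n_reps)) {
      sub <- sample(subjects, ns)
      m <- degree_age_map(subset_cohort(cohort, sub))
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, rep = r, n_subjects = ns,
        cor_with_full = stats::cor(m$t, full$t))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ablation_result", "data.frame")
  out
}

#' Leave-N-out bootstrap confidence intervals for regional age effects
#'
#' Per permutation, drops `leave_frac` of the subjects at random, refits the
#' degree age map, and takes the empirical 2.5/97.5 percentiles of the
#' per-region age-slope estimates as the confidence interval.
#'
#' @param cohort an `msn_cohort`.
#' @param leave_frac fraction of subjects left out per permutation.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param level CI level (default 0.95).
#' @return data.frame of class `bootstrap_ci`: `region`, `estimate` (full
#'   sample), `lower`, `upper`; attribute `n_failed` counts non-convergent
#'   refits (reported, not imputed).
#' @export
bootstrap_ci <- function(cohort, leave_frac = 0.1, n_perm = 1000L, seed = 1L,
                         level = 0.95) {
  subjects <- unique(cohort$meta$subject)
  full <- degree_age_map(cohort)
  n_drop <- round(leave_frac * length(subjects))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  betas <- matrix(NA_real_, n_perm, nrow(full))
  n_failed <- 0L
  for (p in seq_len(n_perm)) {
    keep <- if (n_drop > 0) setdiff(subjects, sample(subjects, n_drop)) else subjects
    m <- tryCatch(degree_age_map(subset_cohort(cohort, keep)),
                  error = function(e) NULL)
    if (is.null(m)) { n_failed <- n_failed + 1L; next }
    betas[p, ] <- m$beta_age
  }
  a <- (1 - level) / 2
  qs <- apply(betas, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(region = full$region, estimate = full$beta_age,
                    lower = qs[1, ], upper = qs[2, ])
  attr(out, "n_failed") <- n_failed
  attr(out, "leave_frac") <- leave_frac
  class(out) <- c("bootstrap_ci", "data.frame")
  out
}

#' Within-subject degree change versus the between-subject age-effect map
#'
#' For each subject with at least two scans, takes the difference in
#' regional weighted degree between the first follow-up and baseline; the
#' per-region mean of these within-subject changes is correlated (Spearman)
#' with the between-subject age-effect t-map, with spin-test inference.
#'
#' @param cohort an `msn_cohort`.
#' @param dk_map optional precomputed [degree_age_map()] (with its
#'   `degrees` attribute); computed if missing.
#' @param n_perm,seed spin-test settings.
#' @param min_pairs minimum number of two-visit subjects required.
#' @return list: `delta` (per-region mean within-subject change), `rho`
#'   (Spearman with the t-map), `spin` (a `spin_null`), `n_pairs`.
#' @export
within_subject_change <- function(cohort, dk_map = NULL, n_perm = 1000L,
                                  seed = 1L, min_pairs = 10L) {
  if (is.null(dk_map)) dk_map <- degree_age_map(cohort)
  k <- attr(dk_map, "degrees")
  meta <- cohort_meta(cohort)
  tab <- table(meta$subject)
  two <- names(tab)[tab >= 2]
  if (length(two) < min_pairs) {
    stop(sprintf("insufficient data: only %d subjects with >= 2 visits (need %d)",
                 length(two), min_pairs))
  }
  deltas <- t(vapply(two, function(s) {
    idx <- which(meta$subject == s)
    idx <- idx[order(meta$session[idx])]
    k[idx[2], ] - k[idx[1], ]
  }, numeric(ncol(k))))
  delta_mean <- colMeans(deltas)
  rho <- stats::cor(delta_mean, dk_map$t, method = "spearman")
  spin <- colocate(delta_mean, dk_map$t, cohort$parcellation,
                   n_perm = n_perm, seed = seed, rank = TRUE)
  list(delta = delta_mean, rho = rho, spin = spin, n_pairs = length(two))
}

#' Between-visit rank stability of regional degree
#'
#' For each region, the Spearman correlation across two-visit subjects
#' between visit-1 and visit-2 weighted degree, a proxy for test-retest
#' reliability; p-values are FDR-adjusted across regions. Also reports the
#' overlap between rank-stable regions and regions with significant age
#' effects on degree.
#'
#' @param cohort an `msn_cohort`.
#' @param dk_map optional precomputed [degree_age_map()].
#' @param fdr_level significance level on q.
#' @return list: `stability` (data.frame region, rho, p, q), `n_significant`,
#'   `n_overlap_dk` (count, with the significant-degree-change regions).
#' @export
rank_stability <- function(cohort, dk_map = NULL, fdr_level = 0.05) {
  if (is.null(dk_map)) dk_map <- degree_age_map(cohort)
  k <- attr(dk_map, "degrees")
  meta <- cohort_meta(cohort)
  tab <- table(meta$subject)
  two <- names(tab)[tab >= 2]
  if (length(two) < 3) stop("insufficient data: need >= 3 two-visit subjects")
  v1 <- t(vapply(two, function(s) {
    idx <- which(meta$subject == s); idx <- idx[order(meta$session[idx])]
    k[idx[1], ]
  }, numeric(ncol(k))))
  v2 <- t(vapply(two, function(s) {
    idx <- which(meta$subject == s); idx <- idx[order(meta$session[idx])]
    k[idx[2], ]
  }, numeric(ncol(k))))
  res <- lapply(seq_len(ncol(k)), function(j) {
    ct <- suppressWarnings(
      stats::cor.test(v1[, j], v2[, j], method = "spearman", exact = FALSE))
    data.frame(region = colnames(k)[j], rho = unname(ct$estimate),
               p = ct$p.value)
  })
  st <- do.call(rbind, res)
  st$q <- stats::p.adjust(st$p, method = "BH")
  sig_stable <- st$q < fdr_level & st$rho > 0
  sig_dk <- dk_map$q < fdr_level
  list(stability = st,
       n_significant = sum(sig_stable),
       n_overlap_dk = sum(sig_stable & sig_dk),
       n_pairs = length(two))
}
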