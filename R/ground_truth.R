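#' Default ground-truth parameters for the synthetic cohort generator
#'
#' Encodes the generative model behind [simulate_cohort()] and [simulate_fc()].
#' Each regional feature value is
#'
#'   value = mean_f + slope_{f,i} * (age - 14) + sex + site + subject + struct + noise
#'
#' where the structural term, in units of the feature's cross-region spread,
#' has three components: a common morphometric gradient profile `v` (a
#' 6-vector: macrostructural features load positively, microstructural
#' negatively) carried with loading `+g_i` by isocortical and `-g_i` by
#' paralimbic regions; a per-zone profile (a symmetric configuration of
#' directions orthogonal to `v`, see below) giving within-zone similarity
#' its positive baseline; and a fixed idiosyncratic profile `idio_i` per
#' region (orthogonal to `v`, equal norms, zero-sum within zone and
#' feature):
#'
#'   isocortex:  struct_i = g_i * v + s_i(age) * zone_{z(i)} + idio_i
#'   paralimbic: struct_i = -g_i * s_i(age) * v + zone_{z(i)} + idio_i
#'
#' with `s_i(age) = exp(drift_{z(i)} * (age - 14))` for isocortex and
#' `exp(-drift * (age - 14))` for paralimbic. Negative drift (isocortex)
#' decays the shared zone profile with age: regions lose their zone-shared
#' structure and stand increasingly on their individual morphometry, so
#' within-zone similarity erodes and isocortical weighted degree falls
#' (differentiation). Positive drift (paralimbic) decays the paralimbic
#' anticorrelation with the isocortical gradient, so paralimbic similarity
#' to the rest of the cortex rises (convergence) while its own within-zone
#' similarity still declines -- together reproducing declining within-zone
#' similarity in every zone and rising paralimbic-isocortex between-zone
#' similarity. A per-feature recentering to the baseline cross-region mean
#' keeps the cortical grand mean of each feature exactly linear in age (a
#' common offset cancels in the MSN standardization, so it leaves networks
#' untouched).
#'
#' Default fixed-effect magnitudes are chosen so that, at the default cohort
#' scale, the global age t-statistics echo the canonical adolescent pattern:
#' strong cortical thinning and gray-matter loss, moderate surface-area loss,
#' clear myelination (MT) increase, and near-null FA/MD trends. Feature slopes
#' additionally carry a centered, drift-linked regional heterogeneity
#' (`slope_het`): macrostructural decline is steeper, and microstructural
#' increase larger, in differentiating regions, which is the mechanism that
#' couples feature age-effect maps to the degree age-effect map.
#'
#' Functional connectivity is generated edgewise on a latent z-scale as
#' `lambda_ij(age)` times the normal-quantile rank transform of the MSN edge
#' plus `(1 - lambda_ij)` times modular noise (within-module edges inflated),
#' then mapped through tanh to the correlation scale. `lambda` declines with
#' age (global structure-function decoupling), faster in isocortex
#' (`coupling_slope_zone`); the within-module inflation fades with age in
#' isocortex and grows in paralimbic cortex (`pc_slope_zone`), which is what
#' plants rising isocortical and falling paralimbic participation
#' coefficients.
#'
#' @param parcellation a [make_parcellation()] table.
#' @param seed seed for the fixed random components of the truth (zone
#'   profiles, idiosyncratic deviations).
#' @param drift named per-zone drift coefficients per year (positive =
#'   convergence).
#' @param lambda0,lambda_slope baseline structure-function mixing at age 14
#'   and its change per year.
#' @param motion_coupling if nonzero, adds `motion_coupling * mean_fd` to all
#'   FC edges (z-scale) to test motion residualization.
#' @return a list of class `msn_ground_truth`.
#' @export
default_ground_truth <- function(parcellation,
                                 seed = 42L,
                                 drift = c(idiotypic = -0.050,
                                           unimodal = -0.050,
                                           heteromodal = -0.050,
                                           paralimbic = 0.070),
                                 lambda0 = 0.25,
                                 lambda_slope = -0.010,
                                 motion_coupling = 0) {
  stopifnot(inherits(parcellation, "parcellation"))
  n <- nrow(parcellation)
  features <- c("CT", "GM", "SA", "MT", "FA", "MD")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  zones <- levels(parcellation$zone)
  para <- parcellation$zone == "paralimbic"
  # Region loadings on the common gradient profile. Paralimbic loadings are
  # applied with a negative sign in the generator: the agranular/dysgranular
  # paralimbic profile sits at the opposite end of the macro/micro gradient
  # from the isocortex, which is what makes paralimbic regions the
  # anticorrelated minority of the similarity network at baseline.
  loading <- abs(stats::rnorm(n, mean = ifelse(para, 1.5, 1.0), sd = 0.2))
  loading <- pmax(loading, 0.2)

  # Idiosyncratic deviations: orthogonal to the (feature-centered) gradient
  # profile so they cannot leak a random-signed component into a region's
  # gradient alignment, and zero-sum within zone x feature so the cortical
  # grand mean carries no idiosyncratic term.
  gradient_profile <- c(CT = 1.0, GM = 0.9, SA = 0.75, MT = -1.0, FA = -0.7, MD = -0.55)
  idio_sd <- 1.0
  idio <- matrix(stats::rnorm(n * 6), n, 6,
                 dimnames = list(parcellation$region_id, features))
  vc <- gradient_profile - mean(gradient_profile)
  idio <- idio - outer(as.numeric(idio %*% vc) / sum(vc^2), vc)
  # equalize norms: every region carries an equally broad idiosyncratic
  # deviation, so planted zone effects are uniformly recoverable
  idio <- idio / sqrt(rowSums(idio^2)) * (idio_sd * sqrt(6))
  for (z in zones) {
    rows <- parcellation$zone == z
    idio[rows, ] <- sweep(idio[rows, , drop = FALSE], 2,
                          colMeans(idio[rows, , drop = FALSE]))
  }

  # Zone profiles: a shared 6-vector per cytoarchitectonic zone, giving
  # within-zone similarity its positive baseline.
  zone_norm <- c(idiotypic = 1.8, unimodal = 1.8, heteromodal = 1.8,
                 paralimbic = 0.7)
  # Orthonormal frame in the subspace orthogonal to the gradient; only its
  # orientation depends on the seed.
  frame <- matrix(stats::rnorm(18), 3, 6)
  frame <- frame - outer(as.numeric(frame %*% vc) / sum(vc^2), vc)
  for (z in 1:3) {
    for (w in seq_len(z - 1)) {
      frame[z, ] <- frame[z, ] - sum(frame[z, ] * frame[w, ]) * frame[w, ]
    }
    frame[z, ] <- frame[z, ] / sqrt(sum(frame[z, ]^2))
  }
  # The three isocortical profiles sit at 120 degrees in the (e1, e2) plane
  # (equal norms, summing to zero per feature); the paralimbic profile takes
  # the third, orthogonal direction with a small norm -- its network identity
  # is mainly the gradient anticorrelation. The broad idiosyncratic spread
  # keeps the regional median profile near zero, so the MAD standardization
  # leaves the planted zone geometry intact.
  zone_profile <- rbind(
    idiotypic   = zone_norm[["idiotypic"]] * frame[1, ],
    unimodal    = zone_norm[["unimodal"]] * (-0.5 * frame[1, ] + sqrt(3) / 2 * frame[2, ]),
    heteromodal = zone_norm[["heteromodal"]] * (-0.5 * frame[1, ] - sqrt(3) / 2 * frame[2, ]),
    paralimbic  = zone_norm[["paralimbic"]] * frame[3, ]
  )[zones, , drop = FALSE]
  colnames(zone_profile) <- features

  truth <- list(
    features      = features,
    feature_mean  = c(CT = 2.60, GM = 1900, SA = 420, MT = 0.92, FA = 0.165, MD = 0.78),
    feature_slope = c(CT = -0.010, GM = -14, SA = -1.6, MT = 0.0012,
                      FA = 0.00018, MD = -0.0001),
    region_scale  = c(CT = 0.25, GM = 450, SA = 110, MT = 0.06, FA = 0.02, MD = 0.04),
    subject_sd    = c(CT = 0.08, GM = 160, SA = 40, MT = 0.02, FA = 0.006, MD = 0.012),
    residual_sd   = c(CT = 0.12, GM = 220, SA = 55, MT = 0.03, FA = 0.010, MD = 0.020),
    sex_offset    = c(CT = 0, GM = 55, SA = 8, MT = 0, FA = 0, MD = 0),
    site_offset   = rbind(site1 = rep(0, 6),
                          site2 = c(0.03, 60, 15, 0.008, 0.002, 0.004),
                          site3 = c(-0.02, -45, -10, -0.005, -0.0015, -0.003)),
    slope_het     = c(CT = 0.45, GM = 0.40, SA = 0.35, MT = -0.45, FA = -0.30, MD = -0.30),
    subject_idio_sd = 0.20,
    gradient_profile = gradient_profile,
    loading       = loading,
    zone_profile  = zone_profile,
    idio          = idio,
    drift         = drift,
    lambda0       = lambda0,
    lambda_slope  = lambda_slope,
    coupling_slope_zone = c(idiotypic = -0.015, unimodal = -0.015,
                            heteromodal = -0.015, paralimbic = 0.005),
    pc_slope_zone = c(idiotypic = -0.050, unimodal = -0.050,
                      heteromodal = -0.050, paralimbic = 0.050),
    fc_module_bonus = 0.8,
    fc_noise_sd   = 1.0,
    fc_scale      = 0.30,
    fd_meanlog    = -1.6,
    fd_sdlog      = 0.4,
    motion_coupling = motion_coupling,
    seed          = as.integer(seed)
  )
  colnames(truth$site_offset) <- features
  stopifnot(all(truth$subject_sd > 0), all(truth$residual_sd > 0))
  if (sign(drift[["paralimbic"]]) == sign(drift[["heteromodal"]]) &&
      any(drift != 0)) {
    warning("default scenario expects paralimbic drift sign opposite to isocortical zones")
  }
  class(truth) <- "msn_ground_truth"
  truth
}

#' A null ground truth: no age effects, no drift, optional noise scaling
#'
#' Convenience wrapper producing a truth in which every age slope, drift and
#' coupling trend is zero. Used for type-I-error calibration of the
#' longitudinal models and for degenerate-generator checks.
#'
#' @inheritParams default_ground_truth
#' @param noise_scale multiplies subject and residual SDs (0 gives noiseless
#'   repeated scans).
#' @export
null_ground_truth <- function(parcellation, seed = 42L, noise_scale = 1) {
  truth <- default_ground_truth(
    parcellation, seed = seed,
    drift = c(idiotypic = 0, unimodal = 0, heteromodal = 0, paralimbic = 0)
  )
  truth$feature_slope[] <- 0
  truth$slope_het[] <- 0
  truth$lambda_slope <- 0
  truth$coupling_slope_zone[] <- 0
  truth$pc_slope_zone[] <- 0
  truth$subject_sd <- truth$subject_sd * noise_scale
  truth$residual_sd <- truth$residual_sd * noise_scale
  truth
}
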