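#' Haar-uniform random 3D rotation matrix
#'
#' Draws a rotation uniformly from SO(3) via QR decomposition of a Gaussian
#' matrix with sign correction and determinant fix.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Spin permutations of a regional cortical map
#'
#' Generates spatial-autocorrelation-preserving permutations of a regional
#' map by spherical rotation: each permutation draws one uniform random 3D
#' rotation, applies it to the left-hemisphere centroids and the sagittally
#' mirrored rotation to the right hemisphere, then reassigns each region the
#' value of the nearest rotated original centroid within its hemisphere.
#' Masked (NA) regions propagate their mask through the reassignment.
#'
#' @param map numeric vector, one value per parcellation region (NA =
#'   masked).
#' @param parcellation a [make_parcellation()] table.
#' @param n_perm number of permutations.
#' @param seed integer seed; fixed seed gives an identical permutation set.
#' @param rotations optional list of 3 x 3 rotation matrices to use instead
#'   of random draws (e.g. `diag(3)` for the identity).
#' @return n_perm x n_regions matrix of permuted maps.
#' @export
spin_permute <- function(map, parcellation, n_perm = 1000L, seed = 1L,
                         rotations = NULL) {
  stopifnot(length(map) == nrow(parcellation))
  xyz <- as.matrix(parcellation[, c("x", "y", "z")])
  hemi <- parcellation$hemisphere
  idx_l <- which(hemi == "L"); idx_r <- which(hemi == "R")
  if (length(idx_l) < 3 || length(idx_r) < 3) {
    stop("degenerate parcellation: need at least 3 regions per hemisphere")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  M <- diag(c(-1, 1, 1))                       # sagittal mirror (x -> -x)
  if (is.null(rotations)) {
    rotations <- replicate(n_perm, random_rotation(), simplify = FALSE)
  } else {
    n_perm <- length(rotations)
  }
  out <- matrix(NA_real_, n_perm, length(map))
  xl <- xyz[idx_l, , drop = FALSE]; xr <- xyz[idx_r, , drop = FALSE]
  for (p in seq_len(n_perm)) {
    R <- rotations[[p]]
    Rm <- M %*% R %*% M
    # value at region i <- value of region whose rotated centroid is nearest
    rot_l <- xl %*% t(R)
    rot_r <- xr %*% t(Rm)
    near_l <- max.col(xl %*% t(rot_l), ties.method = "first")
    near_r <- max.col(xr %*% t(rot_r), ties.method = "first")
    out[p, idx_l] <- map[idx_l][near_l]
    out[p, idx_r] <- map[idx_r][near_r]
  }
  out
}

#' Spatial colocation of two regional maps with spin-test inference
#'
#' Observed statistic: Pearson correlation between the two maps over their
#' shared unmasked support (of ranked values when `rank = TRUE`, giving a
#' Spearman-type statistic). The null distribution is built by spinning
#' `map_a` only and recomputing the statistic against the fixed `map_b`.
#' The two-sided p-value uses the permutation-inclusive estimator
#' `p = (1 + #(|stat_perm| >= |stat_obs|)) / (n_perm + 1)`, so it is never
#' exactly zero.
#'
#' @param map_a,map_b numeric vectors over the parcellation regions.
#' @param parcellation a [make_parcellation()] table.
#' @param n_perm number of spins.
#' @param seed rotation seed.
#' @param rank if TRUE, correlate ranked values.
#' @return list of class `spin_null`: `observed`, `p_spin`, `p_parametric`
#'   (naive two-sided p of the correlation), `perms` (null statistics),
#'   `n_perm`, `seed`.
#' @export
colocate <- function(map_a, map_b, parcellation, n_perm = 1000L, seed = 1L,
                     rank = FALSE) {
  stopifnot(length(map_a) == length(map_b),
            length(map_a) == nrow(parcellation))
  ok <- is.finite(map_a) & is.finite(map_b)
  if (stats::sd(map_a[ok]) == 0 || stats::sd(map_b[ok]) == 0) {
    stop("undefined correlation: constant map")
  }
  stat <- function(a, b) {
    use <- is.finite(a) & is.finite(b)
    if (rank) stats::cor(rank(a[use]), rank(b[use]))
    else stats::cor(a[use], b[use])
  }
  obs <- stat(map_a, map_b)
  nuse <- sum(ok)
  tval <- obs * sqrt((nuse - 2) / max(1e-12, 1 - obs^2))
  p_param <- 2 * stats::pt(-abs(tval), nuse - 2)
  perms <- spin_permute(map_a, parcellation, n_perm = n_perm, seed = seed)
  null_stats <- apply(perms, 1, stat, b = map_b)
  p_spin <- (1 + sum(abs(null_stats) >= abs(obs))) / (length(null_stats) + 1)
  structure(list(observed = obs, p_spin = p_spin, p_parametric = p_param,
                 perms = null_stats, n_perm = length(null_stats),
                 seed = as.integer(seed)),
            class = "spin_null")
}

#' Zone aggregation of a regional map
#'
#' Mean, SD and region count of the unmasked map values within each
#' cytoarchitectonic zone.
#'
#' @param map numeric vector over regions.
#' @param parcellation parcellation table.
#' @return data.frame with `zone`, `mean`, `sd`, `n`.
#' @export
zone_aggregate <- function(map, parcellation) {
  stopifnot(length(map) == nrow(parcellation))
  zones <- levels(parcellation$zone)
  out <- lapply(zones, function(z) {
    v <- map[parcellation$zone == z]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      warning(sprintf("zone '%s' empty after masking", z))
      return(data.frame(zone = z, mean = NA_real_, sd = NA_real_, n = 0L))
    }
    data.frame(zone = z, mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  do.call(rbind, out)
}

#' Correlation of feature age-effect maps with the degree age-effect map
#'
#' One [colocate()] call per feature: correlates each feature's regional
#' age-effect t-map with the t-map of age effects on MSN weighted degree,
#' with spin-test inference.
#'
#' @param feature_t_maps named list (or matrix columns) of per-feature
#'   regional t-maps.
#' @param degree_t_map regional t-map of the degree age effect.
#' @param parcellation parcellation table.
#' @param n_perm,seed spin-test settings.
#' @return data.frame with `feature`, `r`, `p_spin`, `p_parametric`.
#' @export
feature_degree_correlation <- function(feature_t_maps, degree_t_map,
                                       parcellation, n_perm = 1000L,
                                       seed = 1L) {
  if (is.matrix(feature_t_maps)) {
    feature_t_maps <- as.list(as.data.frame(feature_t_maps))
  }
  out <- lapply(names(feature_t_maps), function(f) {
    sn <- colocate(feature_t_maps[[f]], degree_t_map, parcellation,
                   n_perm = n_perm, seed = seed)
    data.frame(feature = f, r = sn$observed, p_spin = sn$p_spin,
               p_parametric = sn$p_parametric)
  })
  do.call(rbind, out)
}

#' @export
print.spin_null <- function(x, ...) {
  cat(sprintf("spin_null: observed %.4f, p_spin %.4g (%d perms), parametric p %.4g\n",
              x$observed, x$p_spin, x$n_perm, x$p_parametric))
  invisible(x)
}
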