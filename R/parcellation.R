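#' Synthetic cortical parcellation on the unit sphere
#'
#' Places `n_regions` regions quasi-uniformly on the unit sphere, mirrored
#' across hemispheres, and assigns each region a cytoarchitectonic zone
#' (idiotypic, unimodal, heteromodal, paralimbic) and a functional-module
#' label. Zones and modules are spatially contiguous caps (spherical Voronoi
#' cells around farthest-point seeds), so zone labels carry nontrivial spatial
#' autocorrelation -- the property that makes spin-test nulls meaningful.
#'
#' The left hemisphere occupies the x < 0 half-space; the right hemisphere is
#' its sagittal mirror image, and zone/module labels are mirrored so the two
#' hemispheres are homotopic.
#'
#' @param n_regions total number of regions (even; 358 in the default
#'   analysis scale).
#' @param n_modules number of functional modules (>= 2).
#' @param seed integer seed controlling centroid jitter and seed-point choice.
#' @return a `data.frame` of class `parcellation` with columns `region_id`,
#'   `hemisphere` ("L"/"R"), `zone` (factor with the four Mesulam-style
#'   levels), `module` (integer), and unit-norm centroid coordinates
#'   `x`, `y`, `z`.
#' @examples
#' p <- make_parcellation(90, n_modules = 5, seed = 1)
#' table(p$zone)
#' @export
make_parcellation <- function(n_regions, n_modules, seed = 1L) {
  if (n_regions < 2L * n_modules) {
    stop("invalid design: n_regions must be at least 2 * n_modules")
  }
  if (n_regions %% 2L != 0L) stop("invalid design: n_regions must be even")
  if (n_modules < 2L) stop("invalid design: n_modules must be >= 2")
  nh <- n_regions %/% 2L
  if (nh < 8L) stop("invalid design: need at least 8 regions per hemisphere")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  # Fibonacci lattice on the sphere, folded into the x < 0 hemisphere and
  # jittered; folding a uniform lattice is measure-preserving.
  i <- seq_len(nh)
  phi <- (1 + sqrt(5)) / 2
  zc <- 1 - (2 * i - 1) / nh
  theta <- 2 * pi * i / phi
  r <- sqrt(pmax(0, 1 - zc^2))
  pts <- cbind(x = r * cos(theta), y = r * sin(theta), z = zc)
  jit <- matrix(stats::rnorm(3 * nh, sd = 0.35 / sqrt(nh)), ncol = 3)
  pts <- pts + jit
  pts[, 1] <- -abs(pts[, 1]) - 1e-6
  pts <- pts / sqrt(rowSums(pts^2))

  zones <- c("idiotypic", "unimodal", "heteromodal", "paralimbic")
  zone_seed <- .farthest_point_seeds(pts, 4L, start = sample.int(nh, 1L))
  zone_cap <- .balanced_caps(pts, pts[zone_seed, , drop = FALSE])
  zone_lab <- zones[zone_cap]
  mod_seed <- .farthest_point_seeds(pts, n_modules, start = sample.int(nh, 1L))
  mod_lab <- .nearest_seed(pts, pts[mod_seed, , drop = FALSE])

  mirror <- pts
  mirror[, 1] <- -mirror[, 1]
  ids_l <- sprintf("L_%03d", i)
  ids_r <- sprintf("R_%03d", i)
  out <- data.frame(
    region_id  = c(ids_l, ids_r),
    hemisphere = rep(c("L", "R"), each = nh),
    zone       = factor(rep(zone_lab, 2L), levels = zones),
    module     = rep(as.integer(mod_lab), 2L),
    x = c(pts[, 1], mirror[, 1]),
    y = c(pts[, 2], mirror[, 2]),
    z = c(pts[, 3], mirror[, 3]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Spatially autocorrelated scalar map on a parcellation
#'
#' Draws a Gaussian-process realization over region centroids with a
#' squared-exponential kernel in geodesic (great-circle) distance. Used to
#' generate smooth cortical maps with controlled spatial autocorrelation for
#' null calibration of the spin test.
#'
#' @param parcellation a [make_parcellation()] table.
#' @param lengthscale kernel lengthscale in radians (default 0.6; larger =
#'   smoother).
#' @param seed integer seed.
#' @return numeric vector, one value per region, zero mean unit scale.
#' @export
make_smooth_map <- function(parcellation, lengthscale = 0.6, seed = 1L) {
  xyz <- as.matrix(parcellation[, c("x", "y", "z")])
  n <- nrow(xyz)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  dots <- pmin(pmax(tcrossprod(xyz), -1), 1)
  gd <- acos(dots)
  K <- exp(-gd^2 / (2 * lengthscale^2))
  # eigendecomposition square root: robust when K is numerically rank-deficient
  ev <- eigen(K, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  as.numeric(ev$vectors %*% (sqrt(lam) * stats::rnorm(n)))
}

# Greedy farthest-point sampling of k seed indices (geodesic metric).
.farthest_point_seeds <- function(pts, k, start = 1L) {
  n <- nrow(pts)
  seeds <- integer(k)
  seeds[1] <- start
  d <- acos(pmin(1, pmax(-1, pts %*% pts[start, ])))
  if (k > 1) {
    for (j in 2:k) {
      seeds[j] <- which.max(d)
      dj <- acos(pmin(1, pmax(-1, pts %*% pts[seeds[j], ])))
      d <- pmin(d, dj)
    }
  }
  seeds
}

# Index of nearest seed point for each row of pts.
.nearest_seed <- function(pts, seed_pts) {
  sim <- pts %*% t(seed_pts)
  max.col(sim, ties.method = "first")
}

# Capacity-balanced spherical caps: regions are assigned to their nearest
# seed subject to near-equal cap sizes; the most decisively placed regions
# claim their cap first, preserving spatial contiguity.
.balanced_caps <- function(pts, seed_pts) {
  n <- nrow(pts); k <- nrow(seed_pts)
  cap <- ceiling(n / k)
  sim <- pts %*% t(seed_pts)
  margin <- apply(sim, 1, function(s) diff(sort(s, decreasing = TRUE)[2:1]))
  assign <- integer(n)
  left <- rep(cap, k)
  for (i in order(-margin)) {
    pref <- order(sim[i, ], decreasing = TRUE)
    j <- pref[left[pref] > 0][1]
    assign[i] <- j
    left[j] <- left[j] - 1L
  }
  assign
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "parcellation: %d regions (%d per hemisphere), %d modules\n",
    nrow(x), sum(x$hemisphere == "L"), length(unique(x$module))
  ))
  print(table(zone = x$zone[x$hemisphere == "L"]))
  invisible(x)
}
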