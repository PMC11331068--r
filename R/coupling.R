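#' Prepare functional connectivity matrices for analysis
#'
#' Applies the Fisher r-to-z transform (atanh) to every edge of every scan's
#' raw FC matrix, then removes residual head-motion effects by regressing
#' each edge, across scans, on the scan's mean framewise displacement and
#' keeping the residuals ("motion-corrected z scores"). The motion
#' regression is a single pooled edgewise regression across the cohort. When
#' mean FD is constant across scans the regression reduces to subtracting
#' the edge mean.
#'
#' @param fc_list list of symmetric raw FC matrices (correlations in (-1,1),
#'   NA diagonal), one per scan.
#' @param mean_fd numeric vector of per-scan mean framewise displacement.
#' @return list of residualized z-scale FC matrices.
#' @export
prepare_fc <- function(fc_list, mean_fd) {
  stopifnot(length(fc_list) == length(mean_fd))
  n <- nrow(fc_list[[1]])
  ut <- upper.tri(fc_list[[1]])
  E <- vapply(fc_list, function(m) m[ut], numeric(sum(ut)))
  if (any(abs(E) >= 1)) {
    bad <- which(abs(E) >= 1, arr.ind = TRUE)[1, ]
    stop(sprintf("infinite z: |r| >= 1 at edge %d of scan %d", bad[1], bad[2]))
  }
  Z <- atanh(E)                                   # edges x scans
  if (stats::sd(mean_fd) == 0) {
    # constant motion: the regression has zero slope, only the edge mean goes
    R <- t(Z - rowMeans(Z))
  } else {
    X <- cbind(1, mean_fd)
    beta <- solve(crossprod(X), crossprod(X, t(Z))) # 2 x edges
    R <- t(Z) - X %*% beta                          # scans x edges (residuals)
  }
  lapply(seq_along(fc_list), function(k) {
    m <- matrix(0, n, n, dimnames = dimnames(fc_list[[k]]))
    m[ut] <- R[k, ]
    m <- m + t(m)
    diag(m) <- NA_real_
    m
  })
}

#' Global structure-function coupling
#'
#' Spearman correlation (average ranks for ties) between the strict upper
#' triangles of a scan's structural (MSN) and functional connectivity
#' matrices.
#'
#' @param msn,fc matched symmetric matrices with NA diagonal.
#' @return scalar rho in \[-1, 1\].
#' @export
global_coupling <- function(msn, fc) {
  stopifnot(all(dim(msn) == dim(fc)))
  ut <- upper.tri(msn)
  a <- msn[ut]; b <- fc[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant upper triangle")
  }
  stats::cor(a, b, method = "spearman")
}

#' Regional structure-function coupling
#'
#' For each region, the Spearman correlation between the region's
#' off-diagonal edge row in the MSN and in the FC matrix (N - 1 edge pairs
#' per region; only the self-edge is excluded).
#'
#' @inheritParams global_coupling
#' @return named numeric vector of per-region rho.
#' @export
regional_coupling <- function(msn, fc) {
  stopifnot(all(dim(msn) == dim(fc)))
  n <- nrow(msn)
  # row-wise Spearman as Pearson on average ranks, vectorized across regions
  RA <- matrix(0, n, n - 1)
  RB <- matrix(0, n, n - 1)
  for (i in seq_len(n)) {
    a <- msn[i, -i]; b <- fc[i, -i]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop(sprintf("undefined correlation: constant edge row for region %d", i))
    }
    RA[i, ] <- rank(a)
    RB[i, ] <- rank(b)
  }
  ca <- RA - rowMeans(RA)
  cb <- RB - rowMeans(RB)
  rho <- rowSums(ca * cb) / sqrt(rowSums(ca^2) * rowSums(cb^2))
  names(rho) <- rownames(msn)
  rho
}

#' Coupling for every scan of a cohort
#'
#' @param msns,fcs lists of matched per-scan MSN and (prepared) FC matrices.
#' @return list with `global` (numeric vector per scan) and `regional`
#'   (scans x regions matrix).
#' @export
cohort_coupling <- function(msns, fcs) {
  stopifnot(length(msns) == length(fcs))
  glob <- vapply(seq_along(msns), function(k) global_coupling(msns[[k]], fcs[[k]]),
                 numeric(1))
  reg <- t(vapply(seq_along(msns),
                  function(k) regional_coupling(msns[[k]], fcs[[k]]),
                  numeric(nrow(msns[[1]]))))
  colnames(reg) <- rownames(msns[[1]])
  list(global = glob, regional = reg)
}

#' Age model of structure-function coupling
#'
#' Delegates to the random-intercept age model: globally on the per-scan
#' coupling rho, and regionally on each region's rho, returning the age-14
#' baseline coupling map and the t-map of coupling change.
#'
#' @param coupling result of [cohort_coupling()].
#' @param meta scan metadata (subject, age, sex, site).
#' @inheritParams age_effect_map
#' @return an [age_effect_map()] over regions; the global coupling `lme_fit`
#'   is in `attr(, "global_coupling")`.
#' @export
coupling_age_model <- function(coupling, meta, baseline_age = 14,
                               df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  map <- age_effect_map(coupling$regional, meta, baseline_age = baseline_age,
                        df_method = df_method)
  gdat <- data.frame(subject = meta$subject, age = meta$age, sex = meta$sex,
                     site = meta$site, value = coupling$global)
  attr(map, "global_coupling") <- fit_lme(gdat, baseline_age = baseline_age,
                                          df_method = df_method)
  map
}
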