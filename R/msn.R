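#' Subject-level quality control by robust outlier detection
#'
#' Flags scans whose global (cortex-mean) value of any feature is a robust
#' outlier across the cohort: |x - median| / (1.4826 * MAD) >= `threshold`,
#' with median and MAD taken over all scans. Exclusion is at subject level:
#' if any of a subject's scans is flagged, all of that subject's scans are
#' removed.
#'
#' @param scans an `msn_cohort` or list of scan records.
#' @param threshold robust z-score cut (default 5).
#' @return list with `kept` and `excluded` scan lists, `excluded_subjects`,
#'   and the per-scan flag table.
#' @export
qc_subjects <- function(scans, threshold = 5) {
  scans <- .as_scan_list(scans)
  if (length(scans) < 3) stop("need at least 3 scans for MAD-based QC")
  gm <- t(vapply(scans, function(s) colMeans(s$features),
                 numeric(ncol(scans[[1]]$features))))
  bad <- rep(FALSE, length(scans))
  for (j in seq_len(ncol(gm))) {
    m <- stats::median(gm[, j])
    s <- stats::mad(gm[, j])
    if (s == 0) {
      stop(sprintf("degenerate feature '%s': zero MAD of global means across scans",
                   colnames(gm)[j]))
    }
    bad <- bad | (abs(gm[, j] - m) / s >= threshold)
  }
  subj <- vapply(scans, `[[`, "", "subject_id")
  excl_subj <- unique(subj[bad])
  keep <- !(subj %in% excl_subj)
  if (!any(keep)) stop("empty cohort: all subjects excluded by QC")
  list(kept = scans[keep], excluded = scans[!keep],
       excluded_subjects = excl_subj,
       flags = data.frame(subject = subj, flagged = bad))
}

#' Region-level quality control: drop zero-MAD regions
#'
#' Drops any region whose value for at least one feature has exactly zero
#' median absolute deviation across scans (a constant signal, as produced by
#' local signal dropout), and returns the surviving region set used by all
#' downstream stages.
#'
#' @param scans an `msn_cohort` or list of scan records.
#' @return list with `kept_regions`, `dropped_regions` (character vectors of
#'   region ids).
#' @export
qc_regions <- function(scans) {
  scans <- .as_scan_list(scans)
  fx <- scans[[1]]$features
  regions <- rownames(fx)
  nfeat <- ncol(fx)
  drop <- rep(FALSE, length(regions))
  for (j in seq_len(nfeat)) {
    vals <- vapply(scans, function(s) s$features[, j], numeric(length(regions)))
    drop <- drop | apply(vals, 1, function(v) stats::mad(v) == 0)
  }
  kept <- regions[!drop]
  if (length(kept) < 3) stop("invalid parcellation: fewer than 3 regions survive QC")
  list(kept_regions = kept, dropped_regions = regions[drop])
}

#' Robust within-scan standardization of regional features
#'
#' Standardizes each feature across regions within one scan using the median
#' and the consistency-scaled median absolute deviation:
#' `(x - median(x)) / (1.4826 * MAD(x))`. The output median of every feature
#' is 0. The 1.4826 constant makes the scale comparable to a z-score under
#' normality; it cancels in the Pearson correlations of [build_msn()], so MSN
#' edges do not depend on it.
#'
#' @param scan a scan record, or a bare region x feature matrix.
#' @return standardized region x feature matrix.
#' @export
standardize_features <- function(scan) {
  fx <- if (is.list(scan) && !is.null(scan$features)) scan$features else scan
  stopifnot(is.matrix(fx))
  out <- fx
  for (j in seq_len(ncol(fx))) {
    med <- stats::median(fx[, j])
    s <- stats::mad(fx[, j])  # includes the 1.4826 constant
    if (s == 0) {
      stop(sprintf("degenerate feature '%s': zero within-scan MAD",
                   colnames(fx)[j]))
    }
    out[, j] <- (fx[, j] - med) / s
  }
  out
}

#' Build a morphometric similarity network from standardized features
#'
#' Edge (i, j) is the Pearson correlation between region i's and region j's
#' standardized feature vectors. The matrix is symmetric; the diagonal is
#' excluded (set to NA).
#'
#' @param standardized region x feature matrix (at least 3 features).
#' @return symmetric region x region matrix of class `similarity_matrix`
#'   with NA diagonal.
#' @export
build_msn <- function(standardized) {
  stopifnot(is.matrix(standardized), ncol(standardized) >= 3)
  rv <- apply(standardized, 1, stats::var)
  if (any(rv == 0)) {
    stop(sprintf("undefined correlation: zero-variance feature vector for region(s) %s",
                 paste(rownames(standardized)[rv == 0], collapse = ", ")))
  }
  m <- stats::cor(t(standardized))
  diag(m) <- NA_real_
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' MSN weighted degree (hubness)
#'
#' The weighted degree of region i is the arithmetic mean of its edge
#' weights, i.e. the mean of row i excluding the diagonal. Signed edges are
#' retained: no thresholding, no absolute value.
#'
#' @param msn a similarity matrix with NA diagonal.
#' @return named numeric vector of per-region degrees, each in \[-1, 1\].
#' @export
weighted_degree <- function(msn) {
  rowMeans(msn, na.rm = TRUE)
}

#' Within- and between-zone mean similarity
#'
#' Averages MSN edge weights within each cytoarchitectonic zone (excluding
#' the diagonal) and between each unordered zone pair.
#'
#' @param msn similarity matrix.
#' @param parcellation parcellation table aligned with `msn` rows.
#' @return data.frame with columns `zone_a`, `zone_b` (`zone_a == zone_b`
#'   for within-zone entries) and `mean_edge`; 4 within + 6 between rows for
#'   4 zones. A within-zone value for a zone with fewer than 2 regions is NA
#'   with a warning.
#' @export
zone_block_means <- function(msn, parcellation) {
  stopifnot(nrow(msn) == nrow(parcellation))
  zones <- levels(parcellation$zone)
  lab <- as.character(parcellation$zone)
  out <- list()
  for (a in seq_along(zones)) {
    for (b in a:length(zones)) {
      ia <- which(lab == zones[a]); ib <- which(lab == zones[b])
      if (a == b) {
        if (length(ia) < 2) {
          warning(sprintf("zone '%s' has < 2 regions; within-zone mean undefined", zones[a]))
          val <- NA_real_
        } else {
          blk <- msn[ia, ia]
          val <- mean(blk[upper.tri(blk)])
        }
      } else {
        val <- mean(msn[ia, ib])
      }
      out[[length(out) + 1L]] <- data.frame(zone_a = zones[a], zone_b = zones[b],
                                            mean_edge = val)
    }
  }
  do.call(rbind, out)
}

#' Per-scan MSNs for a whole cohort
#'
#' @param cohort `msn_cohort` or scan list.
#' @param regions optional character vector of region ids to retain (e.g.
#'   the `kept_regions` of [qc_regions()]).
#' @return list of similarity matrices, one per scan.
#' @export
cohort_msns <- function(cohort, regions = NULL) {
  scans <- .as_scan_list(cohort)
  lapply(scans, function(s) {
    fx <- s$features
    if (!is.null(regions)) fx <- fx[regions, , drop = FALSE]
    build_msn(standardize_features(fx))
  })
}

#' Scan-by-region weighted-degree matrix for a cohort
#'
#' @param msns list of per-scan similarity matrices.
#' @return matrix with one row per scan, one column per region.
#' @export
cohort_degrees <- function(msns) {
  t(vapply(msns, weighted_degree, numeric(nrow(msns[[1]]))))
}

.as_scan_list <- function(x) {
  if (inherits(x, "msn_cohort")) x$scans else x
}

#' Scan metadata table for a cohort or scan list
#'
#' @param x `msn_cohort` or scan list.
#' @return data.frame with subject, session, age, sex, site, mean_fd.
#' @export
cohort_meta <- function(x) {
  if (inherits(x, "msn_cohort") && length(x$scans) == nrow(x$meta)) return(x$meta)
  scans <- .as_scan_list(x)
  do.call(rbind, lapply(scans, function(s) {
    data.frame(subject = s$subject_id, session = s$session, age = s$age,
               sex = s$sex, site = s$site, mean_fd = s$mean_fd,
               stringsAsFactors = FALSE)
  }))
}

#' Restrict a cohort to a subset of subjects or scans
#'
#' @param cohort `msn_cohort`.
#' @param subjects character vector of subject ids to keep.
#' @return a new `msn_cohort`.
#' @export
subset_cohort <- function(cohort, subjects) {
  keep <- cohort$meta$subject %in% subjects
  out <- cohort
  out$scans <- cohort$scans[keep]
  out$meta <- cohort$meta[keep, , drop = FALSE]
  out
}
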