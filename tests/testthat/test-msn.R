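test_that("MAD standardization matches hand computation and is affine invariant", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(10, 30, 20, 50, 40))
  z <- standardize_features(x)
  # column a: median 3, raw MAD 1, consistency constant 1.4826
  expect_equal(z[, "a"], (c(1, 2, 3, 4, 5) - 3) / 1.4826)
  expect_equal(median(z[, "a"]), 0)
  expect_equal(median(z[, "b"]), 0)
  # affine rescaling of an input feature (unit change) leaves output unchanged
  x2 <- x; x2[, "b"] <- 1000 * x2[, "b"] - 77
  expect_equal(standardize_features(x2), z)
})

test_that("degenerate (constant) features are rejected by name", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(standardize_features(x), "degenerate feature 'b'")
})

test_that("MSN edges match a brute-force Pearson oracle", {
  set.seed(42)
  z <- matrix(rnorm(60), 10, 6)
  rownames(z) <- paste0("r", 1:10)
  msn <- build_msn(z)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(msn[i, j], naive_pearson(z[i, ], z[j, ]), tolerance = 1e-12)
    }
  }
  expect_true(all(is.na(diag(msn))))
  expect_equal(unclass(msn), t(unclass(msn)))
})

test_that("identical and sign-flipped feature vectors give edges +1 and -1", {
  z <- matrix(rnorm(18), 3, 6)
  z[2, ] <- z[1, ]
  z[3, ] <- -z[1, ]
  msn <- build_msn(z)
  expect_equal(msn[1, 2], 1)
  expect_equal(msn[1, 3], -1)
})

test_that("MSN is invariant to affine transforms of one raw feature", {
  fx <- fix_cohort(n_subjects = 5)$scans[[1]]$features
  fx2 <- fx; fx2[, "GM"] <- fx2[, "GM"] / 1000 + 3   # unit change mm^3 -> cm^3
  m1 <- build_msn(standardize_features(fx))
  m2 <- build_msn(standardize_features(fx2))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("weighted degree is the row mean over off-diagonal edges", {
  m <- matrix(NA_real_, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.0
  m[2, 3] <- m[3, 2] <- -0.9
  expect_equal(unname(weighted_degree(m)), c(0.45, 0.0, -0.45))
  # constant network
  mc <- matrix(0.5, 4, 4); diag(mc) <- NA
  expect_equal(unname(weighted_degree(mc)), rep(0.5, 4))
})

test_that("mean degree equals mean off-diagonal edge and degree permutes with regions", {
  fx <- fix_cohort(n_subjects = 5)$scans[[2]]$features
  msn <- build_msn(standardize_features(fx))
  k <- weighted_degree(msn)
  expect_equal(mean(k), mean(msn[upper.tri(msn)]))
  perm <- sample(nrow(msn))
  expect_equal(unname(weighted_degree(msn[perm, perm])), unname(k[perm]))
})

test_that("zone block means recover constant and block-structured networks", {
  parc <- fix_parc()
  n <- nrow(parc)
  mc <- matrix(0.3, n, n); diag(mc) <- NA
  zb <- zone_block_means(mc, parc)
  expect_equal(nrow(zb), 10)             # 4 within + 6 between
  expect_equal(sum(zb$zone_a == zb$zone_b), 4)
  expect_true(all(abs(zb$mean_edge - 0.3) < 1e-12))
  # planted block structure
  para <- parc$zone == "paralimbic"
  mb <- matrix(0.1, n, n); mb[para, para] <- 0.8; diag(mb) <- NA
  zb2 <- zone_block_means(mb, parc)
  w_p <- zb2$mean_edge[zb2$zone_a == "paralimbic" & zb2$zone_b == "paralimbic"]
  expect_equal(w_p, 0.8)
  between_p <- zb2$mean_edge[xor(zb2$zone_a == "paralimbic", zb2$zone_b == "paralimbic")]
  expect_true(all(abs(between_p - 0.1) < 1e-12))
})

test_that("subject QC excludes a planted global outlier subject and no one else", {
  coh <- fix_cohort(n_subjects = 30)
  scans <- coh$scans
  # shift one subject's MT far outside the cohort
  bad_subject <- scans[[5]]$subject_id
  for (k in which(coh$meta$subject == bad_subject)) {
    scans[[k]]$features[, "MT"] <- scans[[k]]$features[, "MT"] + 20 * sd(
      vapply(coh$scans, function(s) mean(s$features[, "MT"]), numeric(1)))
  }
  qc <- qc_subjects(scans)
  expect_equal(qc$excluded_subjects, bad_subject)
  # verify with a direct robust z-score computation
  gm <- vapply(scans, function(s) mean(s$features[, "MT"]), numeric(1))
  rz <- abs(gm - median(gm)) / mad(gm)
  expect_true(all(rz[coh$meta$subject == bad_subject] >= 5))
})

test_that("homogeneous cohorts pass subject QC untouched", {
  coh <- fix_cohort(n_subjects = 40)
  qc <- qc_subjects(coh)
  expect_length(qc$excluded_subjects, 0)
  expect_length(qc$kept, length(coh$scans))
})

test_that("constant global feature means trip the degeneracy guard, not mass exclusion", {
  coh <- fix_cohort(n_subjects = 10)
  scans <- lapply(coh$scans, function(s) {
    s$features[, "FA"] <- seq_len(nrow(s$features))  # identical across scans
    s
  })
  expect_error(qc_subjects(scans), "degenerate feature 'FA'")
})

test_that("region QC drops exactly the zero-MAD regions", {
  coh <- fix_cohort(n_subjects = 15)
  scans <- lapply(coh$scans, function(s) {
    s$features["L_003", "SA"] <- 123.4   # constant across scans
    s
  })
  qc <- qc_regions(scans)
  expect_equal(qc$dropped_regions, "L_003")
  expect_equal(length(qc$kept_regions), nrow(coh$parcellation) - 1)
  # untouched continuous cohort: nothing dropped
  qc0 <- qc_regions(coh)
  expect_length(qc0$dropped_regions, 0)
})
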