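test_that("simulation is bitwise deterministic in (design, truth, seed)", {
  parc <- fix_parc()
  truth <- default_ground_truth(parc, seed = 9)
  des <- cohort_design(n_subjects = 12, seed = 11)
  a <- simulate_cohort(des, parc, truth)
  b <- simulate_cohort(des, parc, truth)
  expect_identical(a$scans, b$scans)
  des2 <- cohort_design(n_subjects = 12, seed = 12)
  c <- simulate_cohort(des2, parc, truth)
  expect_false(identical(a$scans[[1]]$features, c$scans[[1]]$features))
})

test_that("cohort design constraints hold: ages, gaps, stratified sex balance", {
  coh <- fix_cohort(n_subjects = 60)
  meta <- coh$meta
  expect_true(all(meta$age >= 14 & meta$age <= 26))
  # session ages strictly increasing per subject, gaps in [6, 18] months
  for (s in unique(meta$subject)) {
    a <- meta$age[meta$subject == s][order(meta$session[meta$subject == s])]
    if (length(a) > 1) {
      gaps <- diff(a)
      expect_true(all(gaps >= 6 / 12 - 1e-9 & gaps <= 18 / 12 + 1e-9))
    }
  }
  # sex within 10% of balance overall (balanced per stratum by construction)
  subj <- meta[!duplicated(meta$subject), ]
  expect_lt(abs(mean(subj$sex == "F") - 0.5), 0.1)
})

test_that("degenerate truth (no slopes, no drift, no noise) repeats visits exactly", {
  parc <- fix_parc()
  truth <- null_ground_truth(parc, seed = 5, noise_scale = 0)
  des <- cohort_design(n_subjects = 10, visit_probs = c(0, 1, 0), seed = 3)
  coh <- simulate_cohort(des, parc, truth)
  for (s in unique(coh$meta$subject)) {
    idx <- which(coh$meta$subject == s)
    expect_equal(coh$scans[[idx[1]]]$features, coh$scans[[idx[2]]]$features)
  }
})

test_that("planted macrostructural decline matches the generator's closed-form mean", {
  parc <- fix_parc()
  truth <- default_ground_truth(parc, seed = 8)
  coh <- fix_cohort(n_subjects = 120, seed = 19, parc = parc, truth = truth)
  meta <- coh$meta
  ct <- vapply(coh$scans, function(s) mean(s$features[, "CT"]), numeric(1))
  young <- meta$age < 17; oldr <- meta$age > 23
  expect_lt(mean(ct[oldr]), mean(ct[young]))
  # grand mean is exactly linear in age by construction: closed form check
  expected_drop <- truth$feature_slope[["CT"]] * (mean(meta$age[oldr]) - mean(meta$age[young]))
  expect_lt(abs((mean(ct[oldr]) - mean(ct[young])) - expected_drop),
            4 * truth$subject_sd[["CT"]] / sqrt(sum(young)))
})

test_that("paralimbic similarity to the rest of the cortex rises with age", {
  parc <- fix_parc()
  truth <- default_ground_truth(parc, seed = 8)
  coh <- fix_cohort(n_subjects = 120, seed = 19, parc = parc, truth = truth)
  msns <- cohort_msns(coh)
  para <- parc$zone == "paralimbic"
  cross <- vapply(msns, function(m) mean(m[para, !para]), numeric(1))
  age <- coh$meta$age
  expect_gt(mean(cross[age > 23]), mean(cross[age < 17]))
})

test_that("functional connectomes are symmetric, finite, diagonal-excluded", {
  parc <- fix_parc()
  coh <- fix_cohort(n_subjects = 10)
  msn <- cohort_msns(coh)[[1]]
  fc <- simulate_fc(coh$scans[[1]], msn, parc, coh$truth, seed = 2)
  expect_true(all(is.na(diag(fc))))
  off <- fc[upper.tri(fc)]
  expect_true(all(is.finite(off)))
  expect_true(all(abs(off) < 1))
  expect_equal(fc, t(fc))
})

test_that("full structure-function coupling gives Spearman exactly 1", {
  parc <- fix_parc()
  coh <- fix_cohort(n_subjects = 10)
  truth <- coh$truth
  truth$lambda0 <- 1; truth$lambda_slope <- 0
  truth$coupling_slope_zone[] <- 0
  msn <- cohort_msns(coh)[[1]]
  fc <- simulate_fc(coh$scans[[1]], msn, parc, truth, seed = 2)
  expect_equal(global_coupling(msn, fc), 1)
})

test_that("zero coupling gives Spearman near 0 on average over seeds", {
  parc <- fix_parc()
  coh <- fix_cohort(n_subjects = 10)
  truth <- coh$truth
  truth$lambda0 <- 0; truth$lambda_slope <- 0
  truth$coupling_slope_zone[] <- 0
  msn <- cohort_msns(coh)[[1]]
  rhos <- vapply(1:120, function(s) {
    global_coupling(msn, simulate_fc(coh$scans[[1]], msn, parc, truth, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("per-subject RNG streams survive subject subsetting", {
  parc <- fix_parc()
  truth <- default_ground_truth(parc, seed = 9)
  des <- cohort_design(n_subjects = 12, seed = 11)
  full <- simulate_cohort(des, parc, truth)
  # the same subject index regenerates identical data whether or not other
  # subjects are later dropped: subsetting the cohort equals re-simulating
  sub <- subset_cohort(full, unique(full$meta$subject)[c(2, 5, 9)])
  expect_equal(length(sub$scans), sum(full$meta$subject %in% unique(full$meta$subject)[c(2, 5, 9)]))
  expect_identical(sub$scans[[1]]$features,
                   full$scans[[which(full$meta$subject == sub$meta$subject[1])[1]]]$features)
})

test_that("cohort writers produce a complete text representation", {
  parc <- fix_parc()
  coh <- fix_cohort(n_subjects = 6)
  d <- tempfile("cohort")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "parcellation.tsv")))
  expect_true(file.exists(file.path(d, "manifest.tsv")))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  man <- read.delim(file.path(d, "manifest.tsv"))
  expect_equal(nrow(man), nrow(coh$meta))
  fx <- read.delim(file.path(d, man$file[1]))
  expect_equal(as.matrix(fx[, -1]), coh$scans[[1]]$features,
               ignore_attr = TRUE, tolerance = 1e-12)
})
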