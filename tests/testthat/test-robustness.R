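test_that("ablation at fraction 1 reproduces the full map exactly and draws are seeded", {
  coh <- fix_cohort2(n_subjects = 30, seed = 17)
  ab <- ablation(coh, fractions = 0.75, n_reps = 3, seed = 5, min_subjects = 10)
  expect_equal(ab$cor_with_full[ab$fraction == 1], 1)
  ab2 <- ablation(coh, fractions = 0.75, n_reps = 3, seed = 5, min_subjects = 10)
  expect_identical(ab, ab2)
  expect_true(all(ab$n_subjects[ab$fraction == 0.75] == round(0.75 * 30)))
})

test_that("subsample maps degrade with decreasing retained fraction", {
  coh <- fix_cohort2(n_subjects = 44, seed = 23)
  ab <- ablation(coh, fractions = c(0.75, 0.5), n_reps = 6, seed = 2,
                 min_subjects = 10)
  m75 <- mean(ab$cor_with_full[ab$fraction == 0.75])
  m50 <- mean(ab$cor_with_full[ab$fraction == 0.5])
  expect_gt(m75, m50)
  expect_gt(m50, 0)
})

test_that("too-small fractions are skipped with a warning", {
  coh <- fix_cohort2(n_subjects = 30, seed = 17)
  expect_warning(ab <- ablation(coh, fractions = c(0.75, 0.1), n_reps = 2,
                                seed = 1, min_subjects = 10), "skipped")
  expect_false(any(ab$fraction == 0.1))
})

test_that("leave-none-out bootstrap degenerates to the point estimate", {
  coh <- fix_cohort2(n_subjects = 25, seed = 31)
  ci <- bootstrap_ci(coh, leave_frac = 0, n_perm = 3, seed = 1)
  expect_equal(ci$lower, ci$estimate, tolerance = 1e-10)
  expect_equal(ci$upper, ci$estimate, tolerance = 1e-10)
})

test_that("bootstrap intervals bracket the full-sample estimate for most regions", {
  coh <- fix_cohort2(n_subjects = 40, seed = 37)
  ci <- bootstrap_ci(coh, leave_frac = 0.1, n_perm = 30, seed = 2)
  inside <- mean(ci$lower <= ci$estimate & ci$estimate <= ci$upper)
  expect_gte(inside, 0.95)
  expect_equal(attr(ci, "n_failed"), 0)
})

test_that("within-subject change agrees in sign with the between-subject map", {
  coh <- fix_cohort2(n_subjects = 60, seed = 41)
  ws <- within_subject_change(coh, n_perm = 50, seed = 3)
  expect_equal(ws$n_pairs, 60)
  expect_gt(ws$rho, 0)
  expect_s3_class(ws$spin, "spin_null")
})

test_that("cross-sectional cohorts cannot support within-subject analyses", {
  parc <- fix_parc()
  truth <- default_ground_truth(parc, seed = 2)
  des <- cohort_design(n_subjects = 20, visit_probs = c(1, 0, 0), seed = 4)
  coh <- simulate_cohort(des, parc, truth)
  expect_error(within_subject_change(coh), "insufficient data")
  expect_error(rank_stability(coh), "insufficient data")
})

test_that("noise-free repeated scans are perfectly rank-stable between visits", {
  parc <- fix_parc()
  coh <- fix_cohort2(n_subjects = 20, seed = 8, parc = parc)
  # make visit 2 an exact repeat of visit 1: ideal test-retest conditions
  for (s in unique(coh$meta$subject)) {
    idx <- which(coh$meta$subject == s)
    coh$scans[[idx[2]]]$features <- coh$scans[[idx[1]]]$features
  }
  rs <- rank_stability(coh)
  expect_true(all(rs$stability$rho > 0.999))
  expect_equal(rs$n_significant, nrow(parc))
})

test_that("subject morphometric individuality yields positive rank stability", {
  parc <- fix_parc()
  truth <- default_ground_truth(parc, seed = 52)
  truth$subject_idio_sd <- 0.6       # pronounced morphometric individuality
  des <- cohort_design(n_subjects = 40, visit_probs = c(0, 1, 0), seed = 51)
  coh <- simulate_cohort(des, parc, truth)
  rs <- rank_stability(coh)
  expect_gt(mean(rs$stability$rho), 0.1)
  # without any subject signature, stability collapses to noise
  truth0 <- truth; truth0$subject_idio_sd <- 0
  coh0 <- simulate_cohort(des, parc, truth0)
  rs0 <- rank_stability(coh0)
  expect_lt(mean(rs0$stability$rho), mean(rs$stability$rho))
})

test_that("resampling operates at subject level, never scan level", {
  coh <- fix_cohort2(n_subjects = 25, seed = 43)
  subjects <- unique(coh$meta$subject)
  sub <- subset_cohort(coh, subjects[1:10])
  # every retained subject keeps all of their scans
  expect_true(all(table(sub$meta$subject) == table(coh$meta$subject)[subjects[1:10]]))
})

test_that("robustness reuses the identical pipeline code path", {
  coh <- fix_cohort2(n_subjects = 25, seed = 47)
  full_map <- degree_age_map(coh)
  ab <- ablation(coh, fractions = numeric(0), n_reps = 0, seed = 1)
  # the fraction-1 reference inside ablation is the same computation
  again <- degree_age_map(coh)
  expect_identical(attr(full_map, "degrees"), attr(again, "degrees"))
  expect_equal(full_map$t, again$t)
})
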