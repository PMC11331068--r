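# Shared fixtures, built once per test file. Sizes are kept small: the unit
# tests exercise correctness, not power.

fixture_env <- new.env(parent = emptyenv())

fix_parc <- function(n = 40, modules = 4, seed = 7) {
  key <- sprintf("parc_%d_%d_%d", n, modules, seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- make_parcellation(n, modules, seed = seed)
  }
  fixture_env[[key]]
}

fix_cohort <- function(n_subjects = 40, seed = 7, parc = fix_parc(),
                       truth = NULL) {
  if (!is.null(truth)) {
    return(simulate_cohort(cohort_design(n_subjects = n_subjects, seed = seed),
                           parc, truth))
  }
  key <- sprintf("cohort_%d_%d_%d", n_subjects, seed, nrow(parc))
  if (is.null(fixture_env[[key]])) {
    truth <- default_ground_truth(parc, seed = seed + 1)
    fixture_env[[key]] <- simulate_cohort(
      cohort_design(n_subjects = n_subjects, seed = seed), parc, truth)
  }
  fixture_env[[key]]
}

# Two-visit cohort used by the longitudinal robustness tests
fix_cohort2 <- function(n_subjects = 40, seed = 7, parc = fix_parc()) {
  key <- sprintf("cohort2_%d_%d_%d", n_subjects, seed, nrow(parc))
  if (is.null(fixture_env[[key]])) {
    truth <- default_ground_truth(parc, seed = seed + 1)
    des <- cohort_design(n_subjects = n_subjects, visit_probs = c(0, 1, 0),
                         seed = seed)
    fixture_env[[key]] <- simulate_cohort(des, parc, truth)
  }
  fixture_env[[key]]
}

# Brute-force two-pass Pearson, independent of stats::cor
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Brute-force Spearman: explicit average ranks then naive Pearson
naive_spearman <- function(x, y) {
  naive_pearson(rank(x), rank(y))
}

# Floyd-Warshall all-pairs shortest paths on a length matrix (Inf = absent)
naive_shortest_paths <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# random symmetric nonnegative weighted adjacency with zero diagonal
random_graph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  a <- matrix(0, n, n)
  ut <- which(upper.tri(a))
  on <- sample(ut, round(density * length(ut)))
  a[on] <- runif(length(on), 0.1, 1)
  a <- a + t(a)
  a
}
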