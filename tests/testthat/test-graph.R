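test_that("proportional thresholding keeps exactly the strongest positive edges", {
  fc <- matrix(0, 4, 4)
  w <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  fc[upper.tri(fc)] <- w
  fc <- fc + t(fc); diag(fc) <- NA
  g <- threshold_fc(fc, 0.5)
  kept <- g$adj[upper.tri(g$adj)]
  expect_equal(sum(kept > 0), 3)
  expect_setequal(kept[kept > 0], c(0.9, 0.8, 0.7))
  expect_equal(unname(diag(g$adj)), rep(0, 4))
  # density 1 on all-positive input reproduces the matrix with zeroed diagonal
  g1 <- threshold_fc(fc, 1)
  expect_equal(g1$adj[upper.tri(g1$adj)], w)
  # all-negative input: empty graph with a warning
  expect_warning(g0 <- threshold_fc(-fc, 0.5), "positive edges")
  expect_true(all(g0$adj == 0))
})

test_that("thresholded edge sets are nested across densities", {
  fc <- random_graph(20, density = 0.9, seed = 3)
  fcna <- fc; diag(fcna) <- NA
  e1 <- threshold_fc(fcna, 0.4)$adj > 0
  e2 <- threshold_fc(fcna, 0.15)$adj > 0
  expect_true(all(e1[e2]))           # sparse set contained in dense set
  expect_lt(sum(e2), sum(e1))
})

test_that("participation coefficient matches its closed forms", {
  # all edges within own module -> 0
  adj <- matrix(0, 4, 4); adj[1, 2] <- adj[2, 1] <- 1; adj[3, 4] <- adj[4, 3] <- 1
  expect_equal(unname(participation_coefficient(adj, c(1, 1, 2, 2))), rep(0, 4))
  # equal weight to two modules -> 1 - 2 (1/2)^2 = 0.5
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  pc <- participation_coefficient(star, c(1, 1, 1, 2, 2))
  expect_equal(unname(pc[1]), 0.5)
  # equal weight to m modules -> 1 - 1/m, increasing in m
  pcs <- vapply(2:5, function(m) {
    a <- matrix(0, m + 1, m + 1); a[1, 2:(m + 1)] <- a[2:(m + 1), 1] <- 1
    unname(participation_coefficient(a, c(1, seq_len(m) + 1))[1])
  }, numeric(1))
  expect_equal(pcs, 1 - 1 / (2:5))
  expect_true(all(diff(pcs) > 0))
  # uniform weight rescaling leaves PC untouched; isolated nodes get 0
  g <- random_graph(12, seed = 5)
  mods <- rep(1:3, each = 4)
  expect_equal(participation_coefficient(g, mods),
               participation_coefficient(10 * g, mods), tolerance = 1e-12)
  g[, 1] <- g[1, ] <- 0
  expect_equal(unname(participation_coefficient(g, mods)[1]), 0)
  expect_warning(pc1 <- participation_coefficient(g, rep(1, 12)), "single module")
  expect_true(all(pc1 == 0))
})

test_that("complete and star graphs reproduce textbook metric values", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  nm <- nodal_metrics(threshold_fc({d <- k5; diag(d) <- NA; d}, 1,
                                   modules = c(1, 1, 1, 2, 2)))
  expect_equal(nm$nodal$clustering, rep(1, 5))
  expect_equal(unname(nm$global["global_efficiency"]), 1)
  expect_equal(nm$nodal$eigencentrality, rep(1 / sqrt(5), 5), tolerance = 1e-9)
  # star S5: leaves have zero clustering; hub spreads across 2 leaf modules
  s5 <- matrix(0, 5, 5); s5[1, 2:5] <- s5[2:5, 1] <- 1; diag(s5) <- NA
  nms <- nodal_metrics(suppressWarnings(threshold_fc(s5, 1, modules = c(3, 1, 1, 2, 2))))
  expect_equal(nms$nodal$clustering, rep(0, 5))
  expect_equal(nms$nodal$participation[1], 0.5)
})

test_that("all metrics match brute-force oracles on a random weighted graph", {
  adj <- random_graph(12, density = 0.6, seed = 11)
  mods <- rep(1:3, each = 4)
  nm <- nodal_metrics(suppressWarnings(threshold_fc({d <- adj; diag(d) <- NA; d}, 1, modules = mods)))

  expect_equal(nm$nodal$degree, rowSums(adj), tolerance = 1e-12)

  # eigenvector centrality: dense eigendecomposition oracle
  W <- adj / max(adj)
  ev <- eigen(W, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  expect_equal(nm$nodal$eigencentrality, v / sqrt(sum(v^2)), tolerance = 1e-8)

  # Onnela clustering: explicit triangle enumeration
  W13 <- W^(1 / 3)
  n <- nrow(W)
  cl <- numeric(n)
  for (i in 1:n) {
    k <- sum(adj[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j != i && h != i && j != h) acc <- acc + W13[i, j] * W13[j, h] * W13[h, i]
    }
    cl[i] <- acc / (k * (k - 1))
  }
  expect_equal(nm$nodal$clustering, cl, tolerance = 1e-9)

  # efficiency: Floyd-Warshall on lengths 1/weight
  len <- 1 / W; len[W == 0] <- Inf
  D <- naive_shortest_paths(len)
  inv <- 1 / D; diag(inv) <- 0; inv[is.infinite(D)] <- 0
  expect_equal(nm$nodal$efficiency, rowSums(inv) / (n - 1), tolerance = 1e-9)
  expect_equal(unname(nm$global["global_efficiency"]), sum(inv) / (n * (n - 1)),
               tolerance = 1e-9)

  # participation: direct formula
  pc <- vapply(1:n, function(i) {
    k <- sum(adj[i, ])
    1 - sum(vapply(unique(mods), function(s) (sum(adj[i, mods == s]) / k)^2,
                   numeric(1)))
  }, numeric(1))
  expect_equal(unname(nm$nodal$participation), pc, tolerance = 1e-9)

  # within/between module connectivity
  ut <- upper.tri(adj)
  same <- outer(mods, mods, "==")
  expect_equal(unname(nm$global["within_module_mean"]), mean(adj[ut & same]))
  expect_equal(unname(nm$global["between_module_mean"]), mean(adj[ut & !same]))

  # igraph agreement (independent library route) for centrality
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ig_ec <- igraph::eigen_centrality(g)$vector
  ig_ec <- ig_ec / sqrt(sum(ig_ec^2))
  expect_equal(nm$nodal$eigencentrality, unname(ig_ec), tolerance = 1e-6)
})

test_that("binary graphs give unweighted textbook metrics and disconnection is handled", {
  # two disjoint triangles
  adj <- matrix(0, 6, 6)
  adj[1, 2] <- adj[2, 3] <- adj[1, 3] <- 1
  adj[4, 5] <- adj[5, 6] <- adj[4, 6] <- 1
  adj <- pmax(adj, t(adj))
  nm <- nodal_metrics(suppressWarnings(
    threshold_fc({d <- adj; diag(d) <- NA; d}, 1, modules = rep(1:2, each = 3))))
  expect_equal(nm$nodal$clustering, rep(1, 6))
  expect_false(nm$connected)
  # unreachable pairs contribute zero efficiency
  expect_equal(nm$nodal$efficiency, rep(2 / 5, 6))
  # centrality lives on the largest component, zeros elsewhere
  expect_true(all(nm$nodal$eigencentrality[1:3] > 0 | nm$nodal$eigencentrality[4:6] > 0))
  expect_equal(sum(nm$nodal$eigencentrality == 0), 3)
})

test_that("planted intermodular mixing raises isocortical participation with age", {
  # same scan, same edge noise, evaluated at the two ends of the age range:
  # the within-module inflation fades in isocortex and grows in paralimbic
  # cortex, so thresholded participation moves in opposite directions
  parc <- fix_parc()
  coh <- fix_cohort(n_subjects = 8)
  truth <- coh$truth
  msn <- cohort_msns(coh)[[1]]
  pc_at_age <- function(age) {
    scan <- coh$scans[[1]]
    scan$age <- age
    pcs <- sapply(1:20, function(sd0) {
      fc <- atanh(simulate_fc(scan, msn, parc, truth, seed = sd0))
      nodal_metrics(threshold_fc(fc, 0.15, modules = parc$module))$nodal$participation
    })
    rowMeans(pcs)
  }
  pc14 <- pc_at_age(14); pc26 <- pc_at_age(26)
  iso <- as.character(parc$zone) != "paralimbic"
  expect_gt(mean(pc26[iso] - pc14[iso]), 0)
  expect_gt(mean(pc26[iso] - pc14[iso]), mean(pc26[!iso] - pc14[!iso]))
})

test_that("relabeling nodes permutes every metric identically", {
  adj <- random_graph(10, seed = 21)
  mods <- rep(1:2, 5)
  adjna <- adj; diag(adjna) <- NA
  nm <- nodal_metrics(threshold_fc(adjna, 0.5, modules = mods))
  prm <- sample(10)
  nm2 <- nodal_metrics(threshold_fc(adjna[prm, prm], 0.5, modules = mods[prm]))
  for (col in c("degree", "clustering", "efficiency", "participation")) {
    expect_equal(nm2$nodal[[col]], nm$nodal[[col]][prm], tolerance = 1e-9)
  }
})
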