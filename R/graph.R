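#' Proportional thresholding of a functional connectome
#'
#' Keeps the top fraction (`density`) of positive edges by weight and zeroes
#' the rest, producing the nonnegative weighted adjacency on which graph
#' metrics are computed. The edge-count target is `round(density * N(N-1)/2)`;
#' ties at the cutoff are broken by stable (column-major upper-triangle) edge
#' index order. If fewer positive edges exist than the target, all positives
#' are kept with a warning. Negative edges are always discarded: path-based
#' metrics require nonnegative weights.
#'
#' @param fc symmetric matrix (z-scale or correlation scale), NA diagonal.
#' @param density fraction of all possible edges to retain, in (0, 1].
#' @param modules optional integer module label per node, carried on the
#'   result for [participation_coefficient()].
#' @return list of class `thresholded_graph`: `adj` (symmetric nonnegative
#'   matrix, zero diagonal), `density` (achieved), `modules`.
#' @export
threshold_fc <- function(fc, density, modules = NULL) {
  stopifnot(density > 0, density <= 1)
  n <- nrow(fc)
  ut <- which(upper.tri(fc))
  w <- fc[ut]
  target <- round(density * length(ut))
  pos <- which(w > 0)
  if (length(pos) < target) {
    warning(sprintf("only %d positive edges available for target %d; keeping all positives",
                    length(pos), target))
    keep <- pos
  } else {
    ord <- pos[order(w[pos], pos, decreasing = c(TRUE, FALSE), method = "radix")]
    keep <- ord[seq_len(target)]
  }
  adj <- matrix(0, n, n, dimnames = dimnames(fc))
  adj[ut[keep]] <- w[keep]
  adj <- adj + t(adj)
  diag(adj) <- 0
  out <- list(adj = adj, density = length(keep) / length(ut), modules = modules)
  class(out) <- "thresholded_graph"
  out
}

.graph_adj <- function(graph) {
  if (inherits(graph, "thresholded_graph")) graph$adj else graph
}

#' Participation coefficient
#'
#' The Guimera-Amaral participation coefficient over weighted degrees:
#' `PC_i = 1 - sum_s (k_is / k_i)^2`, where `k_is` is node i's total edge
#' weight to module s and `k_i` its total strength. PC is 0 for a node whose
#' edges all stay within one module and approaches `1 - 1/m` for weight
#' spread evenly over m modules. Isolated nodes get PC = 0. Invariant to
#' uniform rescaling of all weights.
#'
#' @param graph a `thresholded_graph`, or an adjacency matrix (then
#'   `modules` is required).
#' @param modules integer module label per node.
#' @return numeric vector of PC values in \[0, 1).
#' @export
participation_coefficient <- function(graph, modules = NULL) {
  adj <- .graph_adj(graph)
  if (is.null(modules) && inherits(graph, "thresholded_graph")) {
    modules <- graph$modules
  }
  if (is.null(modules)) stop("module labels required")
  stopifnot(length(modules) == nrow(adj))
  if (length(unique(modules)) < 2) {
    warning("single module: participation coefficient degenerate (all zero)")
    return(stats::setNames(rep(0, nrow(adj)), rownames(adj)))
  }
  k <- rowSums(adj)
  mods <- sort(unique(modules))
  kis <- vapply(mods, function(s) rowSums(adj[, modules == s, drop = FALSE]),
                numeric(nrow(adj)))
  pc <- 1 - rowSums((kis / ifelse(k > 0, k, 1))^2)
  pc[k == 0] <- 0
  stats::setNames(pc, rownames(adj))
}

#' Nodal and global graph metrics of a thresholded functional connectome
#'
#' Computes, per node: weighted degree (strength), eigenvector centrality
#' (leading eigenvector by power iteration, tolerance 1e-10, unit Euclidean
#' norm; on a disconnected graph computed in the largest component with
#' zeros elsewhere and a flag), weighted clustering coefficient (Onnela:
#' geometric mean of triangle weights normalized by the maximum weight),
#' nodal efficiency (mean inverse shortest-path length on lengths = 1/weight,
#' unreachable pairs contributing 0), participation coefficient, and
#' within-module degree. Per graph: global efficiency and mean within- and
#' between-module connectivity. Weights are normalized by their maximum
#' before path and triangle computations so efficiencies and clustering lie
#' in \[0, 1\]; all metrics equal their unweighted textbook values on binary
#' graphs.
#'
#' @param graph a `thresholded_graph` (module labels required for the
#'   module-based metrics).
#' @return list with `nodal` (data.frame: degree, eigencentrality,
#'   clustering, efficiency, participation, within_module_degree) and
#'   `global` (global_efficiency, within_module_mean, between_module_mean),
#'   plus `connected` flag.
#' @export
nodal_metrics <- function(graph) {
  adj <- .graph_adj(graph)
  modules <- if (inherits(graph, "thresholded_graph")) graph$modules else NULL
  n <- nrow(adj)
  stopifnot(isSymmetric(unname(adj)), all(adj >= 0))
  wmax <- max(adj)
  W <- if (wmax > 0) adj / wmax else adj

  strength <- rowSums(adj)
  kbin <- rowSums(adj > 0)

  # Onnela weighted clustering: C_i = (W^(1/3) %*% W^(1/3) %*% W^(1/3))_ii / (k_i (k_i - 1))
  W13 <- W^(1 / 3)
  tri <- diag(W13 %*% W13 %*% W13)
  clustering <- ifelse(kbin > 1, tri / (kbin * (kbin - 1)), 0)

  # shortest paths on lengths 1/weight
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- igraph::E(g)$weight
  D <- igraph::distances(g, weights = 1 / len)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  efficiency <- rowSums(inv) / max(1, n - 1)
  global_eff <- sum(inv) / max(1, n * (n - 1))

  comp <- igraph::components(g)
  ec <- .power_eigencentrality(W, comp)

  if (!is.null(modules)) {
    pc <- participation_coefficient(adj, modules)
    same <- outer(modules, modules, "==")
    wmd <- rowSums(adj * same)
    ut <- upper.tri(adj)
    within_mean <- mean(adj[ut & same])
    between_mean <- mean(adj[ut & !same])
  } else {
    pc <- rep(NA_real_, n); wmd <- rep(NA_real_, n)
    within_mean <- NA_real_; between_mean <- NA_real_
  }

  list(
    nodal = data.frame(
      node = if (!is.null(rownames(adj))) rownames(adj) else seq_len(n),
      degree = strength, eigencentrality = ec, clustering = clustering,
      efficiency = efficiency, participation = pc,
      within_module_degree = wmd, row.names = NULL),
    global = c(global_efficiency = global_eff,
               within_module_mean = within_mean,
               between_module_mean = between_mean),
    connected = comp$no == 1
  )
}

# Leading eigenvector of W restricted to the largest component; power
# iteration to tolerance 1e-10, nonnegative, unit L2 norm.
.power_eigencentrality <- function(W, comp = NULL) {
  n <- nrow(W)
  if (is.null(comp)) {
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    comp <- igraph::components(g)
  }
  main <- which(comp$membership == which.max(comp$csize))
  ec <- numeric(n)
  Wm <- W[main, main, drop = FALSE]
  if (sum(Wm) == 0) return(ec)
  v <- rep(1 / sqrt(length(main)), length(main))
  # iterate on Wm + I: same eigenvectors, spectrum shifted positive so the
  # iteration cannot oscillate on bipartite components
  for (it in seq_len(10000)) {
    v2 <- as.numeric(Wm %*% v) + v
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v2 <- v2 / nv
    if (max(abs(v2 - v)) < 1e-10) { v <- v2; break }
    v <- v2
  }
  v <- abs(v)
  ec[main] <- v / sqrt(sum(v^2))
  ec
}

#' Age-effect maps for every nodal graph metric across a cohort
#'
#' Thresholds each scan's FC matrix, computes nodal metrics, and fits the
#' random-intercept age model per metric per node, returning one
#' [age_effect_map()] per metric.
#'
#' @param fcs list of per-scan (prepared) FC matrices.
#' @param meta scan metadata.
#' @param modules module label per node.
#' @param density threshold density (default 0.10).
#' @param metrics which nodal metrics to model.
#' @inheritParams age_effect_map
#' @return named list of `age_effect_map`s.
#' @export
metric_age_maps <- function(fcs, meta, modules, density = 0.10,
                            metrics = c("degree", "eigencentrality", "clustering",
                                        "efficiency", "participation",
                                        "within_module_degree"),
                            baseline_age = 14) {
  n <- nrow(fcs[[1]])
  per_scan <- lapply(fcs, function(fc) {
    nodal_metrics(threshold_fc(fc, density, modules = modules))$nodal
  })
  out <- list()
  for (m in metrics) {
    vals <- t(vapply(per_scan, function(d) d[[m]], numeric(n)))
    colnames(vals) <- rownames(fcs[[1]])
    out[[m]] <- age_effect_map(vals, meta, baseline_age = baseline_age)
  }
  out
}
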