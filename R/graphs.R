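# Topological summaries of GC matrices: weighted density, cost-thresholded
# binary digraphs, global/local efficiency curves, and permutation group
# comparison of the curves.

as_f_matrix <- function(gc) {
  if (inherits(gc, "gc_matrix")) gc$f else as.matrix(gc)
}

#' Total weighted network density
#'
#' Mean of the off-diagonal F values: the average Granger-causal strength
#' over all directed network pairs.
#'
#' @param gc A `gc_matrix` or a square matrix with `NA` (ignored) diagonal.
#' @return Scalar density.
#' @export
weighted_density <- function(gc) {
  f <- as_f_matrix(gc)
  off <- f[row(f) != col(f)]
  if (any(!is.finite(off))) stopf("off-diagonal entries must be finite")
  mean(off)
}

#' Threshold a weighted matrix at a network cost
#'
#' Keeps the `ceiling(cost * n * (n - 1))` largest off-diagonal entries as
#' directed edges. Ties at the cutoff are broken deterministically in
#' (source, target) lexicographic order, so edge sets are nested across
#' costs.
#'
#' @param gc A `gc_matrix` or square weight matrix.
#' @param cost Fraction of possible directed edges to keep, in (0, 1].
#' @return Binary adjacency matrix (`adj[i, j] = 1` for edge i -> j).
#' @export
#' @examples
#' m <- matrix(1:9, 3); diag(m) <- NA
#' sum(threshold_by_cost(m, 1))  # 6 = complete digraph on 3 nodes
threshold_by_cost <- function(gc, cost) {
  f <- as_f_matrix(gc)
  n <- nrow(f)
  if (!(cost > 0 && cost <= 1)) stopf("cost must lie in (0, 1]")
  m <- n * (n - 1L)
  k <- ceiling(cost * m)
  off <- which(row(f) != col(f))
  # order by weight descending, ties by (source=row, target=col) ascending
  o <- off[order(-f[off], row(f)[off], col(f)[off])]
  adj <- matrix(0L, n, n, dimnames = dimnames(f))
  adj[o[seq_len(k)]] <- 1L
  adj
}

# All-pairs shortest directed path lengths of a small binary digraph via
# boolean matrix powers; Inf where unreachable.
digraph_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- adj > 0
  D[reach & is.infinite(D)] <- 1
  P <- reach
  for (step in 2:max(2, n - 1)) {
    if (!any(is.infinite(D[row(D) != col(D)]))) break
    P <- (P %*% (adj > 0)) > 0
    new <- P & is.infinite(D)
    D[new] <- step
  }
  D
}

#' Global efficiency of a binary directed graph
#'
#' Mean inverse shortest-path length over all ordered node pairs;
#' unreachable pairs contribute 0. Lies in `[0, 1]` and equals 1 exactly for
#' the complete digraph.
#'
#' @param adj Binary adjacency matrix (directed).
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) stopf("need at least 2 nodes")
  D <- digraph_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Local efficiency of a binary directed graph
#'
#' Mean over nodes of the global efficiency of the subgraph induced by the
#' node's neighbors (union of in- and out-neighbors, the node itself
#' excluded). Nodes with fewer than 2 neighbors contribute 0.
#'
#' @param adj Binary adjacency matrix (directed).
#' @return Scalar efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) stopf("need at least 2 nodes")
  eff <- vapply(seq_len(n), function(v) {
    nb <- which((adj[v, ] > 0 | adj[, v] > 0) & seq_len(n) != v)
    if (length(nb) < 2) return(0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, 0)
  mean(eff)
}

#' Efficiency curves over a grid of network costs
#'
#' @param gc A `gc_matrix` or square weight matrix.
#' @param cost_grid Costs in (0, 1]; default `seq(0.05, 0.5, by = 0.05)`.
#' @param group Optional group label carried into the output.
#' @return Data frame with columns `cost`, `e_global`, `e_local`, `group`;
#'   class `efficiency_curve`.
#' @export
efficiency_curves <- function(gc, cost_grid = seq(0.05, 0.5, by = 0.05),
                              group = NA_character_) {
  if (any(cost_grid <= 0 | cost_grid > 1)) stopf("costs must lie in (0, 1]")
  rows <- lapply(cost_grid, function(cst) {
    adj <- threshold_by_cost(gc, cst)
    data.frame(cost = cst,
               e_global = global_efficiency(adj),
               e_local = local_efficiency(adj),
               group = group, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("efficiency_curve", class(out))
  out
}

# Area under an efficiency-vs-cost curve by the trapezoid rule.
curve_area <- function(cost, eff) {
  o <- order(cost)
  sum(diff(cost[o]) * (utils::head(eff[o], -1) + utils::tail(eff[o], -1)) / 2)
}

#' Permutation group comparison of efficiency curves
#'
#' Computes each group's global- and local-efficiency curve from its
#' concatenated GC matrix, summarizes each metric's group difference as the
#' area between the curves (SDI minus control), and permutes subject group
#' labels to obtain one-sided p-values in both directions for each metric.
#'
#' @param panel A conditioned `ts_panel`.
#' @param cost_grid Costs in (0, 1].
#' @param order VAR lag order (fixed across permutations).
#' @param n_perm Number of label permutations (default 500).
#' @param conditioning Passed to the GC computation.
#' @param seed Integer seed.
#' @return List with `curves` (both groups' observed curves), `area_diff`
#'   (named: global, local), `p_greater` / `p_less` (SDI > control and
#'   SDI < control one-sided p per metric), `per_cost` (descriptive per-cost
#'   differences and p-values), `n_perm`, `seed`.
#' @export
compare_curves <- function(panel, cost_grid = seq(0.05, 0.5, by = 0.05),
                           order = 1L, n_perm = 500L,
                           conditioning = "pairwise", seed = 1L) {
  stopifnot(inherits(panel, "ts_panel"))
  groups <- panel_groups_of(panel)
  g1 <- panel$groups[1]
  n1 <- sum(groups == g1)
  if (n1 < 2 || sum(groups != g1) < 2) stopf("need >= 2 subjects per group")
  grams <- panel_grams(panel, order)
  labels <- panel$channel_labels

  stats_for <- function(sel1) {
    f1 <- gc_from_gram(sum_grams(grams[sel1]), conditioning, labels)$f
    f2 <- gc_from_gram(sum_grams(grams[-sel1]), conditioning, labels)$f
    c1 <- efficiency_curves(f1, cost_grid, group = g1)
    c2 <- efficiency_curves(f2, cost_grid, group = panel$groups[2])
    list(
      area = c(global = curve_area(cost_grid, c1$e_global) -
                 curve_area(cost_grid, c2$e_global),
               local = curve_area(cost_grid, c1$e_local) -
                 curve_area(cost_grid, c2$e_local)),
      per_cost = cbind(global = c1$e_global - c2$e_global,
                       local = c1$e_local - c2$e_local),
      curves = rbind(c1, c2)
    )
  }
  idx1 <- which(groups == g1)
  obs <- stats_for(idx1)
  n_sub <- length(grams)
  area_ge <- c(global = 0L, local = 0L)
  area_le <- c(global = 0L, local = 0L)
  cost_ge <- matrix(0L, length(cost_grid), 2,
                    dimnames = list(NULL, c("global", "local")))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      st <- stats_for(sample.int(n_sub, n1))
      area_ge <- area_ge + (st$area >= obs$area)
      area_le <- area_le + (st$area <= obs$area)
      cost_ge <- cost_ge + (st$per_cost >= obs$per_cost)
    }
  })
  list(curves = obs$curves,
       area_diff = obs$area,
       p_greater = area_ge / n_perm,
       p_less = area_le / n_perm,
       per_cost = data.frame(cost = cost_grid,
                             diff_global = obs$per_cost[, "global"],
                             diff_local = obs$per_cost[, "local"],
                             p_global_greater = cost_ge[, "global"] / n_perm,
                             p_local_greater = cost_ge[, "local"] / n_perm),
       n_perm = n_perm, order = order, seed = seed)
}
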