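# Independent oracles used across the suite. Each is deliberately naive
# (closed form, brute force, or enumeration) and shares no code with the
# implementation paths it checks.

# Stationary covariance of a VAR(1): solves the discrete Lyapunov equation
# Sigma = A Sigma A' + Q via the vec identity vec(Sigma) = (I - A (x) A)^-1 vec(Q).
lyapunov_cov <- function(A, Q) {
  n <- nrow(A)
  vecS <- solve(diag(n^2) - kronecker(A, A), as.vector(Q))
  matrix(vecS, n, n)
}

# Naive pairwise Granger F via two independent lm() fits on a single
# uninterrupted series.
naive_gc_pair <- function(x, source, target, p) {
  T_ <- ncol(x)
  rows <- (p + 1):T_
  y <- x[target, rows]
  own <- sapply(seq_len(p), function(l) x[target, rows - l])
  src <- sapply(seq_len(p), function(l) x[source, rows - l])
  fit_r <- lm(y ~ own)
  fit_u <- lm(y ~ own + src)
  rss_r <- sum(resid(fit_r)^2)
  rss_u <- sum(resid(fit_u)^2)
  k_u <- 1 + 2 * p
  ((rss_r - rss_u) / p) / (rss_u / (length(y) - k_u))
}

# Exhaustive BFS shortest-path oracle for tiny binary digraphs.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (dist[w] > dist[v] + 1) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  D <- bfs_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- sapply(seq_len(n), function(v) {
    nb <- setdiff(which(adj[v, ] > 0 | adj[, v] > 0), v)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  })
  mean(vals)
}

# Brute-force BH step-up: tries every candidate threshold explicitly.
bruteforce_bh <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  best <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) best <- k
  if (best == 0) rep(FALSE, m) else p <= ps[best]
}

# Small random binary digraph with no self-loops.
random_digraph <- function(n, density = 0.4) {
  adj <- matrix(as.integer(runif(n * n) < density), n, n)
  diag(adj) <- 0L
  adj
}

# Two-channel test panel with optional coupling difference between groups.
toy_panel <- function(n_per_group = 5, T_ = 120, delta = 0, seed = 1) {
  base <- matrix(c(0.3, 0, 0, 0.3), 2, 2)
  spec0 <- var_spec(base, labels = c("A", "B"))
  spec1 <- var_spec(base + matrix(c(0, delta, 0, 0), 2, 2),
                    labels = c("A", "B"))
  seeds <- 10000 + seq_len(2 * n_per_group)
  subs <- c(
    lapply(seq_len(n_per_group), function(k) {
      list(id = sprintf("s%02d", k), group = "SDI",
           data = simulate_var(spec1, T_, seed = seed * 131 + seeds[k]))
    }),
    lapply(seq_len(n_per_group), function(k) {
      list(id = sprintf("c%02d", k), group = "control",
           data = simulate_var(spec0, T_, seed = seed * 131 + seeds[n_per_group + k]))
    })
  )
  ts_panel(subs, channel_labels = c("A", "B"), tr_seconds = 2)
}

# Stable 14-channel coupling matrix with controllable off-diagonal density,
# used to engineer group differences in graph-efficiency tests.
random_base_coeffs_dense <- function(density, seed) {
  set.seed(seed)
  A <- matrix(0, 14, 14)
  off <- which(diag(14) == 0)
  pick <- sample(off, round(density * length(off)))
  A[pick] <- runif(length(pick), 0.1, 0.3)
  diag(A) <- 0.3
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  A * (0.75 / rho)
}

# Cohort with a planted topological contrast: one group's strong couplings
# are spread over all 14 nodes (integrated), the other's are confined to
# two 7-node modules (clustered). Both coupling matrices share the edge
# count, weight range, and spectral radius, so at any fixed network cost
# only edge placement differs. `flip` swaps which group gets which
# construction while reusing the identical subject realizations, so the
# flipped cohort is the exact mirror of the original.
make_efficiency_coeffs <- function(clustered, seed, n_edges = 50) {
  set.seed(seed)
  A <- matrix(0, 14, 14)
  cand <- if (clustered) {
    do.call(rbind, lapply(list(1:7, 8:14), function(b) {
      eg <- expand.grid(i = b, j = b)
      eg[eg$i != eg$j, ]
    }))
  } else {
    eg <- expand.grid(i = 1:14, j = 1:14)
    eg[eg$i != eg$j, ]
  }
  pick <- cand[sample(nrow(cand), n_edges), ]
  A[cbind(pick$i, pick$j)] <- runif(n_edges, 0.15, 0.3)
  diag(A) <- 0.3
  A * (0.75 / max(Mod(eigen(A, only.values = TRUE)$values)))
}

make_efficiency_panel <- function(flip, seed, n_per_group = 10) {
  spread_spec <- var_spec(make_efficiency_coeffs(FALSE, seed),
                          labels = rsn_symbols())
  clust_spec <- var_spec(make_efficiency_coeffs(TRUE, seed + 50),
                         labels = rsn_symbols())
  seeds <- 8000 + seq_len(2 * n_per_group)
  spread_subs <- lapply(seq_len(n_per_group), function(k) {
    simulate_var(spread_spec, 146, seed = seeds[k])
  })
  clust_subs <- lapply(seq_len(n_per_group), function(k) {
    simulate_var(clust_spec, 146, seed = seeds[n_per_group + k])
  })
  sdi_data <- if (flip) clust_subs else spread_subs
  ctl_data <- if (flip) spread_subs else clust_subs
  subs <- c(
    lapply(seq_len(n_per_group), function(k) {
      list(id = sprintf("s%d", k), group = "SDI", data = sdi_data[[k]])
    }),
    lapply(seq_len(n_per_group), function(k) {
      list(id = sprintf("c%d", k), group = "control", data = ctl_data[[k]])
    })
  )
  ts_panel(subs, rsn_symbols(), 2)
}
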