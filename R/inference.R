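# Permutation-based group inference on GC matrices with FDR control.

#' Benjamini-Hochberg step-up over a set of p-values
#'
#' Finds the largest k with `p_(k) <= k * q / m` and declares every p-value
#' at or below `p_(k)` significant.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA`s excluded
#'   from m and never significant).
#' @param q FDR level (default 0.05).
#' @return List with `mask` (logical, aligned with the input), `threshold`
#'   (the critical p-value, `NA` when nothing is significant),
#'   `n_significant`, `m`.
#' @export
#' @examples
#' fdr_bh(c(0.001, 0.002, rep(0.9, 10)), q = 0.05)$n_significant
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) stopf("empty p-value input")
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  passes <- which(ps <= seq_len(m) * q / m)
  mask <- rep(FALSE, length(p_values))
  if (length(passes)) {
    thr <- ps[max(passes)]
    mask[ok] <- p <= thr
  } else {
    thr <- NA_real_
  }
  list(mask = mask, threshold = thr, n_significant = sum(mask), m = m)
}

#' Convert a one-sided permutation p-value to two-sided
#'
#' Doubles the smaller tail and caps at 1.
#'
#' @param p_one_sided One-sided (upper-tail) p-value(s).
#' @return Two-sided p-value(s).
#' @export
two_sided_option <- function(p_one_sided) {
  pmin(1, 2 * pmin(p_one_sided, 1 - p_one_sided))
}

#' Group-label permutation test of GC differences
#'
#' The observed statistic per directed edge is the SDI-minus-control
#' difference of Granger F values computed on the temporally concatenated
#' group series. The null is built by randomly reassigning subjects to
#' groups (preserving group sizes), re-concatenating, and recomputing both
#' GC matrices at the same fixed lag order. The one-sided p-value of an edge
#' is its percentile position in the null: the proportion of randomizations
#' whose difference is greater than or equal to the observed difference
#' (`add_one = TRUE` switches to the add-one rule `(1 + #{null >= obs}) /
#' (1 + n_perm)`, which bounds p away from zero).
#'
#' @param panel A conditioned `ts_panel` with at least 2 subjects per group.
#' @param order VAR lag order (fixed across permutations), or `"bic"` to
#'   select it once on the pooled series.
#' @param n_perm Number of random label permutations (default 2000).
#' @param q FDR level for the significance mask (default 0.05).
#' @param sided `"one"` (default; SDI > control) or `"two"`.
#' @param conditioning Passed to the GC computation.
#' @param add_one Use the add-one p-value rule (default `FALSE`).
#' @param seed Integer seed; the whole result is deterministic given it.
#' @return An object of class `permutation_result`: `observed_diff` (n x n),
#'   `p_values`, `mc_se`, `fdr` (from [fdr_bh()]), `fdr_mask`, `order`,
#'   `n_perm`, `sided`, `q`, `seed`, `labels`, plus the two observed
#'   `gc_matrix` objects.
#' @export
permute_group_labels <- function(panel, order = 1L, n_perm = 2000L,
                                 q = 0.05, sided = c("one", "two"),
                                 conditioning = "pairwise",
                                 add_one = FALSE, seed = 1L) {
  stopifnot(inherits(panel, "ts_panel"))
  sided <- match.arg(sided)
  if (!is_count(n_perm)) stopf("n_perm must be a positive count")
  groups <- panel_groups_of(panel)
  g1 <- panel$groups[1]  # SDI by convention
  n1 <- sum(groups == g1)
  n2 <- sum(groups != g1)
  if (n1 < 2 || n2 < 2) stopf("need at least 2 subjects per group")
  if (identical(order, "bic")) {
    pooled <- do.call(cbind, lapply(panel$subjects, `[[`, "data"))
    bnd <- cumsum(c(1L, utils::head(
      vapply(panel$subjects, function(s) ncol(s$data), 0L), -1L)))
    order <- select_order(pooled, boundaries = bnd)
  }
  grams <- panel_grams(panel, order)
  n_sub <- length(grams)
  idx1 <- which(groups == g1)
  labels <- panel$channel_labels
  n <- length(labels)

  diff_for <- function(sel1) {
    gm1 <- gc_from_gram(sum_grams(grams[sel1]), conditioning, labels)
    gm2 <- gc_from_gram(sum_grams(grams[-sel1]), conditioning, labels)
    list(diff = gm1$f - gm2$f, gc1 = gm1, gc2 = gm2)
  }
  obs <- diff_for(idx1)
  count_ge <- matrix(0L, n, n)
  count_le <- matrix(0L, n, n)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      sel <- sample.int(n_sub, n1)
      d <- diff_for(sel)$diff
      count_ge <- count_ge + (d >= obs$diff)
      count_le <- count_le + (d <= obs$diff)
    }
  })
  if (add_one) {
    p_upper <- (1 + count_ge) / (1 + n_perm)
    p_lower <- (1 + count_le) / (1 + n_perm)
  } else {
    p_upper <- count_ge / n_perm
    p_lower <- count_le / n_perm
  }
  p <- if (sided == "one") p_upper else pmin(1, 2 * pmin(p_upper, p_lower))
  diag(p) <- NA_real_
  dimnames(p) <- list(labels, labels)
  mc_se <- sqrt(p * (1 - p) / n_perm)
  fdr <- fdr_bh(as.vector(p), q = q)
  fdr_mask <- matrix(fdr$mask, n, n, dimnames = dimnames(p))
  structure(
    list(observed_diff = obs$diff, p_values = p, mc_se = mc_se,
         fdr = fdr, fdr_mask = fdr_mask, order = order, n_perm = n_perm,
         sided = sided, q = q, add_one = add_one, seed = seed,
         labels = labels, gc_sdi = obs$gc1, gc_control = obs$gc2),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  sig <- which(x$fdr_mask, arr.ind = TRUE)
  cat(sprintf(
    "permutation_result: %d perms, order %d, %s-sided, q = %g, %d significant edge(s)\n",
    x$n_perm, x$order, x$sided, x$q, nrow(sig)))
  if (nrow(sig)) {
    for (k in seq_len(nrow(sig))) {
      cat(sprintf("  %s -> %s  (diff %.3f, p %.4g)\n",
                  x$labels[sig[k, 1]], x$labels[sig[k, 2]],
                  x$observed_diff[sig[k, 1], sig[k, 2]],
                  x$p_values[sig[k, 1], sig[k, 2]]))
    }
  }
  unstable <- significance_stability(x)
  if (unstable > 0) {
    warnf("%d edge(s) near the FDR threshold are within 3 Monte Carlo SEs; consider more permutations",
          unstable)
  }
  invisible(x)
}

#' Count edges whose significance call is within Monte Carlo noise
#'
#' An edge is unstable when its p-value lies within 3 Monte Carlo standard
#' errors of the BH critical threshold, so re-running with a different
#' permutation seed could flip its call.
#' @param result A `permutation_result`.
#' @return Integer count of unstable edges.
#' @export
significance_stability <- function(result) {
  stopifnot(inherits(result, "permutation_result"))
  thr <- result$fdr$threshold
  if (is.na(thr)) thr <- result$q / result$fdr$m  # smallest step-up rung
  near <- abs(result$p_values - thr) < 3 * result$mc_se
  sum(near, na.rm = TRUE)
}

#' Within-group edge significance via circular-shift surrogates
#'
#' Tests each directed edge of one group's GC matrix against a surrogate
#' null built by circularly shifting every channel of every subject by an
#' independent uniform offset (at least the lag order). Shifting preserves
#' each channel's autocorrelation but destroys cross-channel lag structure,
#' which is the appropriate null for a lag-based statistic. P-values use the
#' add-one rule, so the smallest attainable value is `1 / (1 + n_perm)`.
#'
#' @param panel A conditioned `ts_panel`.
#' @param group Group label to test.
#' @param order VAR lag order.
#' @param n_perm Number of surrogate draws (>= 19; default 1000).
#' @param alpha Per-edge threshold (default 0.005).
#' @param conditioning Passed to the GC computation.
#' @param seed Integer seed.
#' @return List with `f_obs` (`gc_matrix`), `p_values`, `mask` (p <= alpha),
#'   `alpha`, `n_perm`.
#' @export
within_group_significance <- function(panel, group, order = 1L,
                                      n_perm = 1000L, alpha = 0.005,
                                      conditioning = "pairwise", seed = 1L) {
  stopifnot(inherits(panel, "ts_panel"))
  if (!group %in% panel$groups) stopf("unknown group '%s'", group)
  if (n_perm < 19) stopf("n_perm = %d cannot resolve alpha; need >= 19", n_perm)
  subs <- Filter(function(s) s$group == group, panel$subjects)
  if (!length(subs)) stopf("group '%s' has no subjects", group)
  labels <- panel$channel_labels
  n <- length(labels)
  gram_of <- function(datas) {
    sum_grams(lapply(datas, function(x) {
      design_gram(build_lagged_design(x, order))
    }))
  }
  f_obs <- gc_from_gram(gram_of(lapply(subs, `[[`, "data")),
                        conditioning, labels)
  count <- matrix(0L, n, n)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      shifted <- lapply(subs, function(s) {
        T_ <- ncol(s$data)
        offs <- sample(order:(T_ - order), nrow(s$data), replace = TRUE)
        out <- s$data
        for (ch in seq_len(nrow(out))) {
          o <- offs[ch]
          out[ch, ] <- c(s$data[ch, (T_ - o + 1):T_], s$data[ch, 1:(T_ - o)])
        }
        out
      })
      f_null <- gc_from_gram(gram_of(shifted), conditioning, labels)
      count <- count + (f_null$f >= f_obs$f)
    }
  })
  p <- (1 + count) / (1 + n_perm)
  diag(p) <- NA_real_
  dimnames(p) <- list(labels, labels)
  mask <- !is.na(p) & p <= alpha
  list(f_obs = f_obs, p_values = p, mask = mask, alpha = alpha,
       n_perm = n_perm, group = group, order = order, seed = seed)
}
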