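# End-to-end orchestration: simulate -> condition -> Granger -> permutation
# inference -> graph efficiency -> behavior, with validated configuration
# and provenance sidecars.

#' Build and validate a pipeline configuration
#'
#' @param seed Master seed for every stochastic stage.
#' @param n_per_group,n_timepoints,tr_seconds Cohort design (see
#'   [group_design()]).
#' @param delta_edges Planted group-difference edges (data frame or `NULL`
#'   for exchangeable groups).
#' @param hrf Convolve simulated channels with the canonical hemodynamic
#'   response.
#' @param drop_k,low_hz,high_hz Conditioning parameters.
#' @param order VAR lag order (integer) or `"bic"`.
#' @param conditioning `"pairwise"` or `"conditional"` GC.
#' @param n_perm,q,alpha_within,sided Inference parameters.
#' @param cost_grid Efficiency cost grid.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_per_group = 20L,
                            n_timepoints = 150L, tr_seconds = 2.0,
                            delta_edges = default_delta_edges(),
                            hrf = FALSE, drop_k = 4L,
                            low_hz = 0.008, high_hz = 0.15,
                            order = 1L, conditioning = "pairwise",
                            n_perm = 2000L, q = 0.05,
                            alpha_within = 0.005, sided = "one",
                            cost_grid = seq(0.05, 0.5, by = 0.05),
                            out_dir = NULL) {
  if (!is_count(seed, min = 0L)) stopf("seed must be a non-negative integer")
  if (!is_count(n_per_group)) stopf("n_per_group must be a positive count")
  if (!is_count(n_timepoints)) stopf("n_timepoints must be a positive count")
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  nyquist <- 1 / (2 * tr_seconds)
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyquist)) {
    stopf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
          low_hz, high_hz, nyquist)
  }
  if (!identical(order, "bic") && !is_count(order)) {
    stopf("order must be a positive count or \"bic\"")
  }
  if (!conditioning %in% c("pairwise", "conditional")) {
    stopf("conditioning must be 'pairwise' or 'conditional'")
  }
  if (!is_count(n_perm)) stopf("n_perm must be a positive count")
  if (!(q > 0 && q < 1) || !(alpha_within > 0 && alpha_within < 1)) {
    stopf("q and alpha_within must lie in (0, 1)")
  }
  if (!sided %in% c("one", "two")) stopf("sided must be 'one' or 'two'")
  if (any(cost_grid <= 0 | cost_grid > 1)) stopf("costs must lie in (0, 1]")
  if (is.data.frame(delta_edges) && !nrow(delta_edges)) delta_edges <- NULL
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
         delta_edges = delta_edges, hrf = isTRUE(hrf),
         drop_k = as.integer(drop_k), low_hz = low_hz, high_hz = high_hz,
         order = order, conditioning = conditioning,
         n_perm = as.integer(n_perm), q = q, alpha_within = alpha_within,
         sided = sided, cost_grid = cost_grid, out_dir = out_dir),
    class = c("pipeline_config", "list")
  )
}

#' Run the full effective-connectivity pipeline
#'
#' Simulates a two-group cohort, conditions it, computes both groups' GC
#' matrices, runs the group-label permutation test with FDR control, the
#' within-group surrogate test, the efficiency-curve comparison, and the
#' behavioral regressions. When `config$out_dir` is set, every artifact is
#' written (TSV + JSON sidecar); results are returned invisibly either way.
#'
#' @param config A `pipeline_config` (or arguments for one via `...`).
#' @param panel Optional pre-built `ts_panel`; when supplied the simulate
#'   stage is skipped and the panel is conditioned and analyzed as-is.
#' @param ... Used to build a config when `config` is missing.
#' @return List with `panel`, `gc` (per group), `density` (per group),
#'   `perm` (`permutation_result`), `within` (per group), `curves`
#'   (compare_curves output), `behavior`, `regressions`, `config`.
#' @export
run_pipeline <- function(config = NULL, panel = NULL, ...) {
  if (is.null(config)) config <- pipeline_config(...)
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  if (is.null(panel)) {
    design <- group_design(
      n_per_group = cfg$n_per_group, n_timepoints = cfg$n_timepoints,
      tr_seconds = cfg$tr_seconds,
      delta_edges = cfg$delta_edges %||% default_delta_edges(0),
      hrf = cfg$hrf, seed = cfg$seed
    )
    panel <- generate_group_dataset(design)
  }
  strengths <- panel_strengths(panel)
  conditioned <- preprocess_panel(panel, drop_k = cfg$drop_k,
                                  low_hz = cfg$low_hz, high_hz = cfg$high_hz)

  groups <- concatenate_by_group(conditioned)
  order <- cfg$order
  if (identical(order, "bic")) {
    pooled <- do.call(cbind, lapply(groups, `[[`, "data"))
    bnd <- integer(0); off <- 0L
    for (g in groups) { bnd <- c(bnd, g$boundaries + off); off <- off + ncol(g$data) }
    order <- select_order(pooled, boundaries = bnd)
  }
  gc <- lapply(groups, function(g) {
    gc_matrix(g$data, order = order, boundaries = g$boundaries,
              conditioning = cfg$conditioning)
  })
  density <- vapply(gc, weighted_density, 0)

  seeds <- derive_seeds(cfg$seed, 4L)
  perm <- permute_group_labels(conditioned, order = order,
                               n_perm = cfg$n_perm, q = cfg$q,
                               sided = cfg$sided,
                               conditioning = cfg$conditioning,
                               seed = seeds[1])
  within <- lapply(stats::setNames(nm = conditioned$groups), function(g) {
    within_group_significance(conditioned, g, order = order,
                              n_perm = max(199L, min(cfg$n_perm, 999L)),
                              alpha = cfg$alpha_within,
                              conditioning = cfg$conditioning,
                              seed = seeds[2])
  })
  curves <- compare_curves(conditioned, cost_grid = cfg$cost_grid,
                           order = order,
                           n_perm = min(cfg$n_perm, 1000L),
                           conditioning = cfg$conditioning,
                           seed = seeds[3])
  bspec <- behavior_spec()
  bspec$couplings <- Filter(function(cpl) {
    all(vapply(cpl, function(e) e$network %in% panel$channel_labels, TRUE))
  }, bspec$couplings)
  behavior <- generate_behavior(panel, strengths, bspec, seed = seeds[4])
  nets <- intersect(c("RECN", "dDMN"), panel$channel_labels)
  regressions <- if (length(nets)) {
    behavior_regressions(behavior, strengths, pairs = expand.grid(
      network = nets,
      scale = c("BIS-11", "BAS", "BIS", "Negative Affect"),
      stringsAsFactors = FALSE))
  } else {
    NULL
  }

  result <- list(panel = conditioned, gc = gc, density = density,
                 perm = perm, within = within, curves = curves,
                 behavior = behavior, strengths = strengths,
                 regressions = regressions, order = order, config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg)
  invisible(result)
}

write_pipeline_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  side_cfg <- cfg[setdiff(names(cfg), "delta_edges")]
  write_panel(result$panel, file.path(cfg$out_dir, "panel"))
  for (g in names(result$gc)) {
    write_gc(result$gc[[g]], file.path(cfg$out_dir, sprintf("gc_%s.tsv", g)),
             extra = list(group = g, seed = cfg$seed))
  }
  p <- result$perm
  wm <- function(m, file) {
    df <- cbind(source = p$labels, as.data.frame(m))
    colnames(df) <- c("source", p$labels)
    utils::write.table(df, file.path(cfg$out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wm(p$observed_diff, "diff_observed.tsv")
  wm(p$p_values, "diff_pvalues.tsv")
  wm(p$fdr_mask * 1L, "diff_fdr_mask.tsv")
  write_sidecar(file.path(cfg$out_dir, "diff_fdr_mask.json"), side_cfg,
                cfg$seed,
                extra = list(n_perm = p$n_perm, sided = p$sided, q = p$q,
                             order = p$order,
                             bh_threshold = p$fdr$threshold))
  utils::write.table(result$curves$curves,
                     file.path(cfg$out_dir, "efficiency_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(area_diff = as.list(result$curves$area_diff),
         p_greater = as.list(result$curves$p_greater),
         p_less = as.list(result$curves$p_less),
         density = as.list(result$density)),
    file.path(cfg$out_dir, "graph_comparison.json"),
    auto_unbox = TRUE, digits = NA)
  utils::write.table(result$behavior,
                     file.path(cfg$out_dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$regressions)) {
    utils::write.table(result$regressions,
                       file.path(cfg$out_dir, "behavior_regressions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_sidecar(file.path(cfg$out_dir, "provenance.json"), side_cfg,
                cfg$seed, extra = list(order = result$order))
  invisible(cfg$out_dir)
}
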