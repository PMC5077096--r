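# Synthetic two-group cohort generator. Both groups share a sparse stable
# lag-1 coupling matrix; the patient group ("SDI") additionally receives
# planted increments on a small set of directed edges, which downstream
# stages should recover.

#' Default planted group-difference edges
#'
#' Three directed edges strengthened in the SDI group only: right executive
#' control to dorsal default mode, dorsal default mode to basal ganglia, and
#' sensorimotor to visuospatial.
#'
#' @param delta Coupling increment added to each lag-1 coefficient.
#' @return Data frame with columns `from`, `to`, `delta`.
#' @export
default_delta_edges <- function(delta = 0.15) {
  data.frame(from = c("RECN", "dDMN", "SMN"),
             to = c("dDMN", "BGN", "VSN"),
             delta = delta,
             stringsAsFactors = FALSE)
}

#' Random sparse base coupling shared by both groups
#'
#' Lag-1 matrix with ~`density` of off-diagonal entries drawn U(0.05, 0.15),
#' rescaled so the spectral radius equals `target_radius` (0.7), giving both
#' groups plenty of nonzero within-group connectivity without approaching
#' instability.
#' @noRd
random_base_coeffs <- function(n_channels, density = 0.1,
                               target_radius = 0.7, seed = NULL) {
  with_seed(seed, {
    A <- matrix(0, n_channels, n_channels)
    off <- which(diag(n_channels) == 0)
    pick <- off[stats::runif(length(off)) < density]
    A[pick] <- stats::runif(length(pick), 0.05, 0.15)
    diag(A) <- stats::runif(n_channels, 0.2, 0.4)
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    A * (target_radius / rho)
  })
}

#' Two-group synthetic cohort design
#'
#' @param n_per_group Subjects per group (default 20, the scaled cohort used
#'   throughout the package's tests; the reference study enrolled 50/50).
#' @param n_timepoints Volumes per subject before any are dropped (default
#'   150; the conditioning step removes the first 4, leaving 146).
#' @param tr_seconds Sampling interval (default 2.0 s).
#' @param base_spec `var_spec` shared by both groups; by default a sparse
#'   random lag-1 coupling over 14 labeled channels derived from `seed`.
#' @param delta_edges Data frame (`from`, `to`, `delta`) of directed coupling
#'   increments applied to the SDI group only; default
#'   [default_delta_edges()]. Pass a zero-row data frame for exchangeable
#'   groups.
#' @param hrf If `TRUE`, convolve every channel with the canonical
#'   hemodynamic response before emitting (default `FALSE`).
#' @param noise_sd Innovation standard deviation (default 1).
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   design including this seed.
#' @return An object of class `group_design`.
#' @export
group_design <- function(n_per_group = 20L, n_timepoints = 150L,
                         tr_seconds = 2.0, base_spec = NULL,
                         delta_edges = default_delta_edges(),
                         hrf = FALSE, noise_sd = 1, seed = 1L) {
  if (!is_count(n_per_group)) stopf("n_per_group must be a positive count")
  if (!is_count(n_timepoints)) stopf("n_timepoints must be a positive count")
  if (is.null(base_spec)) {
    base_spec <- var_spec(
      random_base_coeffs(14L, seed = seed),
      noise_sd = noise_sd, labels = rsn_symbols()
    )
  }
  stopifnot(inherits(base_spec, "var_spec"))
  if (n_timepoints <= 10L * base_spec$order) {
    stopf("n_timepoints (%d) must exceed 10 x VAR order (%d)",
          n_timepoints, 10L * base_spec$order)
  }
  sdi_spec <- apply_delta_edges(base_spec, delta_edges)  # validates stationarity
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_timepoints = as.integer(n_timepoints),
         tr_seconds = tr_seconds, base_spec = base_spec,
         sdi_spec = sdi_spec, delta_edges = delta_edges,
         hrf = isTRUE(hrf), seed = as.integer(seed)),
    class = "group_design"
  )
}

#' Add directed coupling increments to a VAR spec's lag-1 matrix
#'
#' Edge (`from`, `to`) increments the lag-1 coefficient by which `from`
#' drives `to`, i.e. entry `[to, from]`. The modified spec must remain
#' stationary.
#' @param spec A `var_spec`.
#' @param delta_edges Data frame with columns `from`, `to`, `delta`.
#' @return The modified `var_spec`.
#' @export
apply_delta_edges <- function(spec, delta_edges) {
  stopifnot(inherits(spec, "var_spec"))
  if (is.null(delta_edges) || !nrow(delta_edges)) return(spec)
  if (!all(c("from", "to", "delta") %in% names(delta_edges))) {
    stopf("delta_edges needs columns from, to, delta")
  }
  A <- spec$coeffs[[1]]
  for (k in seq_len(nrow(delta_edges))) {
    i <- match(delta_edges$to[k], spec$labels)
    j <- match(delta_edges$from[k], spec$labels)
    if (is.na(i) || is.na(j)) {
      stopf("delta edge %s->%s names unknown channels",
            delta_edges$from[k], delta_edges$to[k])
    }
    A[i, j] <- A[i, j] + delta_edges$delta[k]
  }
  coeffs <- spec$coeffs
  coeffs[[1]] <- A
  var_spec(coeffs, noise_sd = spec$noise_sd, labels = spec$labels,
           seed = spec$seed)
}

#' Generate a two-group synthetic cohort
#'
#' Each subject is an independent stationary VAR realization; SDI subjects
#' use the base coupling plus the planted delta edges. The ground-truth edge
#' list is recorded in the panel metadata.
#'
#' @param design A `group_design`.
#' @return A `ts_panel` with `2 * n_per_group` subjects.
#' @export
#' @examples
#' panel <- generate_group_dataset(group_design(n_per_group = 2, seed = 7))
#' panel
generate_group_dataset <- function(design) {
  stopifnot(inherits(design, "group_design"))
  n <- design$n_per_group
  seeds <- derive_seeds(design$seed, 2L * n)
  make_subject <- function(idx, group, spec) {
    x <- simulate_var(spec, design$n_timepoints, seed = seeds[idx])
    if (design$hrf) x <- hrf_convolve(x, design$tr_seconds)
    list(id = sprintf("%s%02d", if (group == "SDI") "sdi" else "ctl",
                      (idx - 1L) %% n + 1L),
         group = group, data = x, seed = seeds[idx])
  }
  subjects <- c(
    lapply(seq_len(n), make_subject, group = "SDI", spec = design$sdi_spec),
    lapply(n + seq_len(n), make_subject, group = "control",
           spec = design$base_spec)
  )
  ts_panel(subjects,
           channel_labels = design$base_spec$labels,
           tr_seconds = design$tr_seconds,
           metadata = list(truth_edges = design$delta_edges,
                           design_seed = design$seed,
                           hrf = design$hrf))
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' The standard two-gamma response (peak near 5 s, undershoot near 15 s,
#' undershoot ratio 1/6), sampled at the repetition time, truncated at 32 s,
#' and renormalized to unit peak.
#'
#' @param tr_seconds Sampling interval (> 0).
#' @param duration_seconds Truncation point, default 32.
#' @return Numeric vector of kernel samples starting at t = 0.
#' @export
hrf_kernel <- function(tr_seconds, duration_seconds = 32) {
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Convolve each channel with the canonical hemodynamic response
#'
#' Causal convolution with zero-padded leading edge; output length equals
#' input length.
#'
#' @param series channels x time matrix.
#' @param tr_seconds Sampling interval in seconds.
#' @return Matrix of the same dimensions.
#' @export
hrf_convolve <- function(series, tr_seconds) {
  stopifnot(is.matrix(series))
  h <- hrf_kernel(tr_seconds)
  T_ <- ncol(series)
  out <- t(apply(series, 1, function(x) {
    full <- stats::convolve(x, rev(h), type = "open")
    full[seq_len(T_)]
  }))
  dimnames(out) <- dimnames(series)
  out
}

#' Behavioral score generation spec
#'
#' Defines, per scale, the two group means and standard deviations and an
#' optional coupling of the score to one or more network strengths. Each
#' coupling is a `(network, sign)` pair; the score is generated as
#' `group mean + sd * (r * sum(sign_k * z_k) + noise)` with the noise scaled
#' so the total variance is approximately the target group variance.
#'
#' @param scales Data frame with columns `scale`, `mean_sdi`, `sd_sdi`,
#'   `mean_control`, `sd_control`; defaults to the 11 reference behavioral
#'   scales (see [behavior_reference()]).
#' @param couplings Named list: scale name -> list of `list(network =, sign =)`
#'   entries; defaults couple impulsivity (BIS-11) negatively to RECN and
#'   positively to dDMN, behavioral approach (BAS) and negative affect
#'   negatively to RECN.
#' @param r Coupling correlation magnitude per network (default 0.5).
#' @return An object of class `behavior_spec`.
#' @export
behavior_spec <- function(scales = NULL, couplings = NULL, r = 0.5) {
  if (is.null(scales)) {
    ref <- behavior_reference()
    scales <- ref[, c("scale", "mean_sdi", "sd_sdi", "mean_control",
                      "sd_control")]
  }
  need <- c("scale", "mean_sdi", "sd_sdi", "mean_control", "sd_control")
  if (!all(need %in% names(scales))) {
    stopf("scales needs columns %s", paste(need, collapse = ", "))
  }
  if (any(scales$sd_sdi <= 0) || any(scales$sd_control <= 0)) {
    stopf("scale SDs must be positive")
  }
  if (is.null(couplings)) {
    couplings <- list(
      "BIS-11" = list(list(network = "RECN", sign = -1),
                      list(network = "dDMN", sign = +1)),
      "BAS" = list(list(network = "RECN", sign = -1)),
      "Negative Affect" = list(list(network = "RECN", sign = -1))
    )
  }
  for (cpl in couplings) {
    for (e in cpl) {
      if (!e$sign %in% c(-1, 0, 1)) stopf("coupling sign must be -1, 0, or +1")
    }
  }
  if (r < 0 || r >= 1) stopf("coupling r must lie in [0, 1)")
  structure(list(scales = scales, couplings = couplings, r = r),
            class = "behavior_spec")
}

#' Generate per-subject behavioral scores coupled to network strengths
#'
#' @param panel A `ts_panel` (supplies subject ids and group labels).
#' @param strengths subjects x networks matrix aligned with the panel (e.g.
#'   [panel_strengths()] output); column names must cover every coupled
#'   network.
#' @param spec A `behavior_spec`.
#' @param seed Integer seed.
#' @return Data frame: `subject_id`, `group`, one numeric column per scale.
#' @export
generate_behavior <- function(panel, strengths, spec = behavior_spec(),
                              seed = 1L) {
  stopifnot(inherits(panel, "ts_panel"), inherits(spec, "behavior_spec"))
  n_sub <- length(panel$subjects)
  if (nrow(strengths) != n_sub) {
    stopf("strengths has %d rows but the panel has %d subjects",
          nrow(strengths), n_sub)
  }
  for (cpl in spec$couplings) {
    for (e in cpl) {
      if (!e$network %in% colnames(strengths)) {
        stopf("coupling names unknown network '%s'", e$network)
      }
    }
  }
  groups <- panel_groups_of(panel)
  is_sdi <- groups == panel$groups[1]
  zs <- scale(strengths)  # population z-score per network
  out <- data.frame(
    subject_id = vapply(panel$subjects, `[[`, "", "id"),
    group = groups, stringsAsFactors = FALSE
  )
  with_seed(seed, {
    for (k in seq_len(nrow(spec$scales))) {
      sc <- spec$scales$scale[k]
      cpl <- spec$couplings[[sc]]
      signal <- numeric(n_sub)
      var_signal <- 0
      if (!is.null(cpl)) {
        for (e in cpl) {
          if (e$sign == 0) next
          signal <- signal + e$sign * spec$r * zs[, e$network]
          var_signal <- var_signal + spec$r^2
        }
      }
      noise <- stats::rnorm(n_sub) * sqrt(max(0, 1 - var_signal))
      unit <- signal + noise
      mu <- ifelse(is_sdi, spec$scales$mean_sdi[k], spec$scales$mean_control[k])
      sdv <- ifelse(is_sdi, spec$scales$sd_sdi[k], spec$scales$sd_control[k])
      out[[sc]] <- mu + sdv * unit
    }
  })
  out
}

#' Render synthetic 4D volumes from spatial maps and time courses
#'
#' Voxel time series are `maps %*% courses` plus isotropic Gaussian noise,
#' reshaped onto a 3D grid to form one 4D array (a synthetic stand-in for a
#' subject's volumetric scan, used to exercise the decomposition path).
#'
#' @param component_maps voxels x components matrix.
#' @param time_courses components x time matrix.
#' @param noise_sd Observation noise standard deviation (>= 0).
#' @param grid_dim Integer length-3 vector; `prod(grid_dim)` must equal the
#'   voxel count.
#' @param tr_seconds Repetition time recorded with the volume.
#' @param seed Integer seed for the noise.
#' @return 4D array with attributes `tr_seconds` and `grid_dim`.
#' @export
render_volumes <- function(component_maps, time_courses, noise_sd = 0,
                           grid_dim = NULL, tr_seconds = 2.0, seed = 1L) {
  stopifnot(is.matrix(component_maps), is.matrix(time_courses))
  if (ncol(component_maps) != nrow(time_courses)) {
    stopf("maps have %d components but courses have %d",
          ncol(component_maps), nrow(time_courses))
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  v <- nrow(component_maps)
  if (is.null(grid_dim)) {
    side <- round(v^(1 / 3))
    grid_dim <- if (side^3 == v) rep(side, 3) else c(v, 1L, 1L)
  }
  if (prod(grid_dim) != v) {
    stopf("grid_dim %s does not match %d voxels",
          paste(grid_dim, collapse = "x"), v)
  }
  y <- component_maps %*% time_courses
  if (noise_sd > 0) {
    y <- y + with_seed(seed, matrix(stats::rnorm(length(y), sd = noise_sd),
                                    nrow(y), ncol(y)))
  }
  arr <- array(y, dim = c(grid_dim, ncol(time_courses)))
  attr(arr, "tr_seconds") <- tr_seconds
  attr(arr, "grid_dim") <- as.integer(grid_dim)
  arr
}
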