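# Network-of-interest definition: PCA reduction, group spatial ICA,
# template matching against canonical maps, dual-regression
# back-reconstruction, and network strength.

#' PCA reduction of the time dimension
#'
#' Projects voxel x time data onto the top-k principal directions of the
#' time dimension (the standard first stage before a group spatial
#' decomposition).
#'
#' @param subject_data voxel x time matrix.
#' @param k Number of components to keep (default 100); capped at the data
#'   rank with a warning.
#' @param center Subtract each time point's voxel mean first (default TRUE).
#' @return List with `reduced` (voxel x k), `basis` (time x k, orthonormal),
#'   `eigenvalues` (all eigenvalues of the time-covariance), `k`.
#' @export
pca_reduce <- function(subject_data, k = 100L, center = TRUE) {
  stopifnot(is.matrix(subject_data))
  if (!is_count(k)) stopf("k must be a positive count")
  X <- if (center) sweep(subject_data, 2, colMeans(subject_data)) else subject_data
  sv <- svd(X)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (k > rank) {
    warnf("k = %d exceeds the data rank %d; capping", k, rank)
    k <- rank
  }
  basis <- sv$v[, seq_len(k), drop = FALSE]
  list(reduced = X %*% basis, basis = basis,
       eigenvalues = sv$d^2 / nrow(X), k = k)
}

#' Estimate the number of signal components by minimum description length
#'
#' Wax-Kailath MDL estimator for the number of Gaussian sources: for each
#' candidate order k the criterion is the log-likelihood-ratio term
#' `-N (m - k) log(GM/AM)` of the smallest `m - k` eigenvalues' geometric to
#' arithmetic mean, plus the parameter-count penalty
#' `0.5 k (2m - k + 1) log N`. Scale-invariant by construction.
#'
#' @param data channels x samples matrix (channels = candidate dimensions).
#' @return The arg-min order (integer, between 0 and channels - 1).
#' @export
estimate_n_components_mdl <- function(data) {
  stopifnot(is.matrix(data))
  m <- nrow(data)
  N <- ncol(data)
  if (N <= m) stopf("need more samples (%d) than channels (%d)", N, m)
  X <- data - rowMeans(data)
  lambda <- sort(eigen(tcrossprod(X) / N, symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  if (any(lambda <= 0)) stopf("degenerate (non-positive) eigenvalues")
  mdl <- vapply(0:(m - 1), function(k) {
    tail_l <- lambda[(k + 1):m]
    gm <- mean(log(tail_l))       # log geometric mean
    am <- log(mean(tail_l))       # log arithmetic mean
    -N * (m - k) * (gm - am) + 0.5 * k * (2 * m - k + 1) * log(N)
  }, 0)
  which.min(mdl) - 1L
}

#' Group spatial independent component analysis
#'
#' Decomposes voxel x dim data into spatially independent component maps
#' and a mixing matrix (FastICA with the logcosh contrast). Maps are
#' z-scored over voxels and sign-aligned so each map's skewness is
#' non-negative (map and mixing column flipped together).
#'
#' @param data voxel x dim matrix (dim = reduced/concatenated time
#'   dimension).
#' @param n_components Number of components (<= dim).
#' @param seed Integer seed for the random unmixing initialization.
#' @param maxit,tol FastICA iteration controls.
#' @return An object of class `component_set`: `maps` (voxel x k, z-scored),
#'   `mixing` (dim x k), `labels` (NULL until template matching),
#'   `n_components`.
#' @export
group_ica <- function(data, n_components, seed = 1L, maxit = 500L,
                      tol = 1e-6) {
  stopifnot(is.matrix(data))
  if (!is_count(n_components) || n_components > ncol(data)) {
    stopf("n_components must be a count <= %d", ncol(data))
  }
  dec <- with_seed(seed, {
    ica::icafast(data, nc = n_components, center = TRUE,
                 maxit = maxit, tol = tol, alg = "par", fun = "logcosh")
  })
  if (!is.null(dec$iter) && dec$iter >= maxit) {
    warnf("ICA did not converge within %d iterations (seed %s)", maxit, seed)
  }
  maps <- dec$S          # voxel x k sources (spatial maps)
  mixing <- dec$M        # dim x k mixing weights
  for (k in seq_len(ncol(maps))) {
    s <- maps[, k]
    skew <- mean((s - mean(s))^3) / stats::sd(s)^3
    if (skew < 0) {
      maps[, k] <- -maps[, k]
      mixing[, k] <- -mixing[, k]
    }
    maps[, k] <- as.vector(scale(maps[, k]))
  }
  structure(
    list(maps = maps, mixing = mixing, labels = NULL,
         n_components = n_components, seed = seed),
    class = "component_set"
  )
}

#' Match group components to canonical network templates
#'
#' Pearson spatial correlation of every component map against every
#' template over an in-brain mask (union of nonzero template voxels), then
#' a greedy one-to-one assignment in descending correlation order. Ties are
#' broken by template order, then component order, so the assignment is
#' deterministic and injective: no symbol labels two components.
#'
#' @param components A `component_set` (or voxel x k map matrix).
#' @param templates voxel x n_templates matrix with template symbols as
#'   column names.
#' @return List with `assignment` (named integer vector: symbol ->
#'   component index, `NA` when unassigned), `correlations`
#'   (n_templates x k matrix), and, when a `component_set` was supplied,
#'   `components` with its `labels` field filled.
#' @export
match_templates <- function(components, templates) {
  maps <- if (inherits(components, "component_set")) components$maps else components
  stopifnot(is.matrix(maps), is.matrix(templates))
  if (nrow(maps) != nrow(templates)) {
    stopf("components and templates must share the voxel grid")
  }
  symbols <- colnames(templates)
  if (is.null(symbols)) stopf("templates must have symbol column names")
  mask <- rowSums(templates != 0) > 0
  if (sum(mask) < 3) stopf("in-brain mask is degenerate")
  cors <- stats::cor(templates[mask, , drop = FALSE],
                     maps[mask, , drop = FALSE])
  n_t <- ncol(templates)
  n_c <- ncol(maps)
  if (n_c < n_t) {
    warnf("only %d components for %d templates; assignment will be partial",
          n_c, n_t)
  }
  assignment <- stats::setNames(rep(NA_integer_, n_t), symbols)
  work <- cors
  for (step in seq_len(min(n_t, n_c))) {
    if (all(is.na(work))) break
    best <- max(work, na.rm = TRUE)
    hits <- which(work == best, arr.ind = TRUE)
    # deterministic tie-break: template order first, then component order
    hit <- hits[order(hits[, 1], hits[, 2])[1], , drop = FALSE]
    assignment[hit[1]] <- hit[2]
    work[hit[1], ] <- NA
    work[, hit[2]] <- NA
  }
  out <- list(assignment = assignment, correlations = cors)
  if (inherits(components, "component_set")) {
    labels <- rep(NA_character_, n_c)
    labels[assignment[!is.na(assignment)]] <- symbols[!is.na(assignment)]
    components$labels <- labels
    out$components <- components
  }
  out
}

#' Dual-regression back-reconstruction of subject maps and time courses
#'
#' Stage 1 (spatial regression): subject time courses are the least-squares
#' regression of the subject's voxel data on the group maps. Stage 2
#' (temporal regression): subject-specific maps are the least-squares
#' regression of the voxel data on those time courses. Collinear group maps
#' trigger a ridge fallback with a warning.
#'
#' @param subject_data voxel x time matrix.
#' @param group_maps voxel x k group component maps.
#' @param ridge Ridge penalty used only on rank deficiency (default 1e-6
#'   relative to the mean diagonal).
#' @return List with `time_courses` (time x k) and `subject_maps`
#'   (voxel x k; the per-voxel beta weights of the temporal regression).
#' @export
back_reconstruct <- function(subject_data, group_maps, ridge = 1e-6) {
  stopifnot(is.matrix(subject_data), is.matrix(group_maps))
  if (nrow(subject_data) != nrow(group_maps)) {
    stopf("subject data and group maps must share the voxel grid")
  }
  solve_ls <- function(A, B, what) {
    G <- crossprod(A)
    if (rcond(G) < 1e-12) {
      warnf("collinear %s; using ridge fallback", what)
      G <- G + diag(ridge * mean(diag(G)), ncol(G))
    }
    solve(G, crossprod(A, B))
  }
  tc <- t(solve_ls(group_maps, subject_data, "group maps"))   # time x k
  sm <- t(solve_ls(tc, t(subject_data), "time courses"))      # voxel x k
  list(time_courses = tc, subject_maps = sm)
}

#' Network strength: mean beta of a subject's component map
#'
#' The subject-level strength of a labeled component is the mean over
#' voxels of the subject-specific map (the per-voxel beta weights from the
#' temporal regression stage of back-reconstruction).
#'
#' @param subject_maps voxel x k matrix from [back_reconstruct()].
#' @param component Component index or label.
#' @param labels Optional component labels (needed when `component` is a
#'   symbol, or to enforce that the component is labeled).
#' @param mask Optional logical voxel mask; defaults to all voxels.
#' @return Scalar strength.
#' @export
noi_strength <- function(subject_maps, component, labels = NULL,
                         mask = NULL) {
  stopifnot(is.matrix(subject_maps))
  if (is.character(component)) {
    if (is.null(labels)) stopf("labels required to resolve '%s'", component)
    idx <- match(component, labels)
    if (is.na(idx)) stopf("no component labeled '%s'", component)
  } else {
    idx <- component
    if (!is.null(labels) && (is.na(labels[idx]) || !nzchar(labels[idx]))) {
      stopf("component %d is unlabeled", idx)
    }
  }
  v <- subject_maps[, idx]
  if (!is.null(mask)) v <- v[mask]
  mean(v)
}
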