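# TimeSeriesPanel container: per-subject multichannel time courses with
# group labels and a shared sampling interval.

#' Construct a time-series panel
#'
#' @param subjects List of subject records, each a list with fields `id`
#'   (character), `group` (one of the two group labels), and `data`
#'   (channels x time matrix).
#' @param channel_labels Ordered channel (network) symbols shared by all
#'   subjects.
#' @param tr_seconds Sampling interval in seconds (fMRI repetition time).
#' @param groups The two admissible group labels, default `c("SDI",
#'   "control")`.
#' @param metadata Optional list carried along (e.g. ground-truth edges).
#' @param log Character vector of preprocessing steps already applied.
#'
#' @return An object of class `ts_panel`.
#' @export
ts_panel <- function(subjects, channel_labels, tr_seconds,
                     groups = c("SDI", "control"),
                     metadata = list(), log = character()) {
  if (!length(subjects)) stopf("a panel needs at least one subject")
  if (length(groups) != 2L || anyDuplicated(groups)) {
    stopf("groups must be exactly two distinct labels")
  }
  n_ch <- length(channel_labels)
  for (s in subjects) {
    if (!all(c("id", "group", "data") %in% names(s))) {
      stopf("each subject needs fields id, group, data")
    }
    if (!s$group %in% groups) {
      stopf("subject %s has group '%s', not one of {%s}",
            s$id, s$group, paste(groups, collapse = ", "))
    }
    if (!is.matrix(s$data) || nrow(s$data) != n_ch) {
      stopf("subject %s data must be a %d-channel matrix", s$id, n_ch)
    }
    if (!all(is.finite(s$data))) {
      stopf("subject %s data contains non-finite values", s$id)
    }
  }
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  structure(
    list(subjects = subjects, channel_labels = channel_labels,
         tr_seconds = tr_seconds, groups = groups,
         metadata = metadata, log = log),
    class = "ts_panel"
  )
}

#' @export
print.ts_panel <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  lens <- vapply(x$subjects, function(s) ncol(s$data), 0L)
  cat(sprintf(
    "ts_panel: %d subjects (%s), %d channels, T = %s, TR = %gs\n",
    length(x$subjects),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    length(x$channel_labels),
    if (length(unique(lens)) == 1L) unique(lens) else "varying",
    x$tr_seconds))
  if (length(x$log)) cat("preprocessing:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

panel_groups_of <- function(panel) {
  vapply(panel$subjects, `[[`, "", "group")
}

#' Apply a per-subject transformation to every subject in a panel
#' @noRd
panel_map <- function(panel, f, log_entry = NULL) {
  panel$subjects <- lapply(panel$subjects, function(s) {
    s$data <- f(s$data, s)
    s
  })
  if (!is.null(log_entry)) panel$log <- c(panel$log, log_entry)
  panel
}

#' Temporally concatenate a panel's subjects by group
#'
#' Subject time courses are concatenated along time within each group, the
#' way group-level Granger analyses pool subjects. Boundary indices record
#' the first time point of every subject (1-based column index into the
#' concatenated matrix) so that downstream lagged regressions never build a
#' lag window that spans two subjects.
#'
#' @param panel A `ts_panel`.
#' @return A named list with one entry per group label, each a list with
#'   `data` (channels x total-time matrix), `boundaries` (integer vector of
#'   subject start columns), and `subject_ids`.
#' @export
#' @examples
#' p <- generate_group_dataset(group_design(n_per_group = 2, seed = 1))
#' g <- concatenate_by_group(p)
#' names(g)
concatenate_by_group <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  out <- list()
  for (g in panel$groups) {
    subs <- Filter(function(s) s$group == g, panel$subjects)
    if (!length(subs)) stopf("group '%s' has no subjects", g)
    lens <- vapply(subs, function(s) ncol(s$data), 0L)
    dat <- do.call(cbind, lapply(subs, `[[`, "data"))
    rownames(dat) <- panel$channel_labels
    out[[g]] <- list(
      data = dat,
      boundaries = as.integer(cumsum(c(1L, lens[-length(lens)]))),
      subject_ids = vapply(subs, `[[`, "", "id")
    )
  }
  out
}

#' Per-subject channel strengths from a panel
#'
#' A simple per-subject, per-channel amplitude summary (sample standard
#' deviation of the channel's time course). In the synthetic, panel-only
#' workflow this plays the role that the mean subject-map beta plays for
#' volumetric data: a subject-level scalar per network against which
#' behavioral scores can be generated and regressed.
#'
#' @param panel A `ts_panel`.
#' @return subjects x channels matrix of strengths, with dimnames.
#' @export
panel_strengths <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  m <- t(vapply(panel$subjects,
                function(s) apply(s$data, 1, stats::sd),
                numeric(length(panel$channel_labels))))
  dimnames(m) <- list(vapply(panel$subjects, `[[`, "", "id"),
                      panel$channel_labels)
  m
}
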