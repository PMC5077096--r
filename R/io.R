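# TSV / JSON / NIfTI input-output and provenance sidecars. Panels travel as
# one TSV per subject (columns = network symbols, rows = time points) plus
# a cohort manifest; GC matrices as TSV plus a JSON sidecar.

#' Write a panel to disk
#'
#' One TSV per subject (rows = time points, columns = channels) and a
#' `manifest.tsv` (subject_id, group, file, seed), plus `panel.json` with
#' tr, labels, log, and any ground-truth metadata.
#'
#' @param panel A `ts_panel`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "ts_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    subject_id = character(), group = character(), file = character(),
    seed = integer(), stringsAsFactors = FALSE
  )
  for (s in panel$subjects) {
    file <- paste0(s$id, ".tsv")
    df <- as.data.frame(t(s$data))
    colnames(df) <- panel$channel_labels
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- rbind(manifest, data.frame(
      subject_id = s$id, group = s$group, file = file,
      seed = s$seed %||% NA_integer_, stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(tr_seconds = panel$tr_seconds, channel_labels = panel$channel_labels,
         groups = panel$groups, log = panel$log, metadata = panel$metadata),
    file.path(dir, "panel.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a panel written by [write_panel()]
#'
#' @param dir Directory containing `manifest.tsv`, per-subject TSVs, and
#'   `panel.json`.
#' @return A `ts_panel`.
#' @export
read_panel <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stopf("no manifest.tsv in %s", dir)
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "panel.json"),
                              simplifyVector = TRUE)
  subjects <- lapply(seq_len(nrow(manifest)), function(k) {
    df <- utils::read.delim(file.path(dir, manifest$file[k]),
                            check.names = FALSE)
    if (!identical(colnames(df), as.character(meta$channel_labels))) {
      stopf("subject file %s: channel header mismatch", manifest$file[k])
    }
    list(id = manifest$subject_id[k], group = manifest$group[k],
         data = t(as.matrix(df)),
         seed = manifest$seed[k])
  })
  ts_panel(subjects, channel_labels = meta$channel_labels,
           tr_seconds = meta$tr_seconds,
           groups = meta$groups,
           metadata = as.list(meta$metadata),
           log = as.character(meta$log))
}

#' Write a GC matrix as TSV plus a JSON sidecar
#'
#' @param gc A `gc_matrix`.
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param extra Additional fields merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_gc <- function(gc, path, extra = list()) {
  stopifnot(inherits(gc, "gc_matrix"))
  df <- as.data.frame(gc$f)
  labs <- gc$labels %||% paste0("ch", seq_len(nrow(gc$f)))
  colnames(df) <- labs
  df <- cbind(source = labs, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- c(list(order = gc$order, dof = gc$dof, n_obs = gc$n_obs,
                    conditioning = gc$conditioning), extra)
  jsonlite::write_json(sidecar, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GC matrix written by [write_gc()]
#'
#' @param path TSV path (sidecar expected alongside).
#' @return A `gc_matrix`.
#' @export
read_gc <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (colnames(df)[1] != "source") stopf("%s: expected 'source' first column", path)
  labs <- df$source
  f <- as.matrix(df[, -1, drop = FALSE])
  rownames(f) <- labs
  side_path <- sub("\\.tsv$", ".json", path)
  if (!file.exists(side_path)) stopf("missing sidecar %s", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  structure(
    list(f = f, order = side$order, dof = side$dof, n_obs = side$n_obs,
         conditioning = side$conditioning, labels = labs),
    class = "gc_matrix"
  )
}

#' Write a synthetic 4D volume as NIfTI-1
#'
#' Records the repetition time in the header's temporal pixdim.
#'
#' @param volume 4D array (e.g. from [render_volumes()]).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param tr_seconds Repetition time; defaults to the array's `tr_seconds`
#'   attribute or 2.
#' @return `path`, invisibly.
#' @export
write_nifti_4d <- function(volume, path, tr_seconds = NULL) {
  if (length(dim(volume)) != 4) stopf("volume must be a 4D array")
  if (is.null(tr_seconds)) tr_seconds <- attr(volume, "tr_seconds") %||% 2
  img <- RNifti::asNifti(unclass(volume))
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, tr_seconds))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI volume
#'
#' @param path NIfTI file path.
#' @return 4D array with `tr_seconds` attribute from the header.
#' @export
read_nifti_4d <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4) stopf("%s is not a 4D volume", path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  attr(arr, "tr_seconds") <- if (length(pd) >= 4) pd[4] else NA_real_
  arr
}

#' Write a JSON provenance sidecar
#'
#' Every numeric artifact the pipeline emits is paired with a sidecar
#' recording the seed, the configuration, and a hash of the serialized
#' configuration.
#'
#' @param path Sidecar path.
#' @param config Configuration list.
#' @param seed Seed in force.
#' @param extra Extra fields.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(path, config, seed, extra = list()) {
  payload <- c(list(
    seed = seed,
    config = config,
    config_hash = config_hash(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("gcnet"))
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  # small stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Validated configuration list (see [pipeline_config()]).
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stopf("config must be YAML or JSON: %s", path)
  }
  do.call(pipeline_config, raw)
}
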