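# Disk interfaces for pipeline artefacts.

#' Save / load a trained MIL model
#'
#' One-file checkpoint holding the configuration and all parameter arrays.
#'
#' @param model a [mil_model()].
#' @param path checkpoint file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_mil_model <- function(model, path) {
  stopifnot(inherits(model, "mil_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_mil_model
#' @export
load_mil_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mil_model"))
  model
}

#' Write per-split train/test manifests
#'
#' @param splits output of [stratify_cohort()].
#' @param dir output directory (created if missing).
#' @return paths of the written JSON manifests, invisibly.
#' @export
write_split_manifests <- function(splits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(splits), function(k) {
    p <- file.path(dir, sprintf("split_%02d.json", k))
    jsonlite::write_json(splits[[k]], p, auto_unbox = FALSE, pretty = TRUE)
    p
  }, "")
  invisible(paths)
}

#' Read split manifests back
#'
#' @param dir directory written by [write_split_manifests()].
#' @return list of splits (`train`, `test` character vectors).
#' @export
read_split_manifests <- function(dir) {
  files <- sort(list.files(dir, pattern = "^split_\\d+\\.json$",
                           full.names = TRUE))
  lapply(files, function(p) {
    s <- jsonlite::read_json(p, simplifyVector = TRUE)
    list(train = as.character(s$train), test = as.character(s$test))
  })
}

#' Write a pipeline report bundle to disk
#'
#' Scores and predictions as CSV, aggregate metrics and the manifest as
#' JSON, comparison tables as CSV -- every number in the bundle traces to a
#' stage output file and the seeds recorded in the manifest.
#'
#' @param bundle output of [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, bundle$predictions),
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(bundle$texture_comparisons))
    utils::write.csv(bundle$texture_comparisons,
                     file.path(dir, "texture_comparisons.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$shape_comparisons))
    utils::write.csv(bundle$shape_comparisons,
                     file.path(dir, "shape_comparisons.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$cells))
    utils::write.csv(bundle$cells[, setdiff(names(bundle$cells), "mask")],
                     file.path(dir, "cell_descriptors.csv"),
                     row.names = FALSE)
  write_split_manifests(bundle$splits, file.path(dir, "splits"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
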