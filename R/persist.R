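#' Write labeling outputs as delimited text
#'
#' Emits `events.csv` (all detected first events, with the first-measurement
#' flag) and `windows.csv` (the manifest: case, category, window bounds,
#' horizon hours, row count) with ISO-8601 UTC timestamps.
#'
#' @param labels a `glyc_labels`
#' @param dir target directory (created if missing)
#' @return the directory, invisibly
#' @export
write_labels <- function(labels, dir) {
  stopifnot(inherits(labels, "glyc_labels"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  iso <- function(df) {
    for (cl in names(df))
      if (inherits(df[[cl]], "POSIXct"))
        df[[cl]] <- format(df[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    df
  }
  write.csv(iso(labels$events), file.path(dir, "events.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(iso(labels$manifest), file.path(dir, "windows.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write the derived feature matrix as a delimited wide table
#'
#' Columns follow the `<analyte>__<stat>` naming convention; missing values
#' are empty fields.
#'
#' @param features a `glyc_features`
#' @param file output path
#' @return the path, invisibly
#' @export
write_features <- function(features, file) {
  stopifnot(inherits(features, "glyc_features"))
  write.csv(as.data.frame(features), file, row.names = FALSE, na = "")
  invisible(file)
}

#' Persist and restore a fitted ensemble
#'
#' `save_ecoc()` writes a versioned bundle: `ensemble.json` (member labels
#' and positive sets, codeword matrix, thresholds, tie-break priority,
#' retained metrics, variable importances, categorical encodings, GA trace,
#' seed) plus one `model_<label>.json` per member in the learner's JSON
#' serialization. `load_ecoc()` restores an object that predicts identically.
#'
#' @param fit a fitted [glyc_ecoc()]
#' @param dir bundle directory (created if missing)
#' @return `save_ecoc`: the directory, invisibly; `load_ecoc`: a `glyc_ecoc`
#' @export
save_ecoc <- function(fit, dir) {
  stopifnot(inherits(fit, "glyc_ecoc"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to persist ensembles", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(
    format_version = 1L,
    members = lapply(fit$models, function(m) list(
      label = m$spec$label, positive_set = m$spec$positive_set,
      metrics = as.list(m$metrics), params = as.list(m$params),
      importance = as.list(importance(m)), seed = m$seed,
      feature_names = m$feature_names)),
    codewords = fit$codewords,
    thresholds = fit$thresholds,
    priority = fit$priority,
    encodings = fit$encodings,
    ga_trace = fit$ga$trace,
    validation_fitness = fit$validation$fitness,
    seed = fit$seed)
  jsonlite::write_json(meta, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (m in fit$models)
    xgboost::xgb.save(m$model,
                      file.path(dir, paste0("model_", m$spec$label, ".json")))
  invisible(dir)
}

#' @rdname save_ecoc
#' @param dir bundle directory written by `save_ecoc()`
#' @export
load_ecoc <- function(dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to restore ensembles", call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
  models <- lapply(meta$members, function(mi) {
    structure(list(
      spec = binary_spec(mi$label, unlist(mi$positive_set)),
      model = xgboost::xgb.load(file.path(dir, paste0("model_", mi$label, ".json"))),
      metrics = unlist(mi$metrics),
      params = as.data.frame(mi$params),
      feature_names = unlist(mi$feature_names),
      seed = mi$seed), class = "trained_binary")
  })
  names(models) <- vapply(models, function(m) m$spec$label, character(1))
  C <- as.matrix(meta$codewords)
  rownames(C) <- as.character(0:4)
  colnames(C) <- names(models)
  storage.mode(C) <- "integer"
  structure(list(
    call = NULL, specs = lapply(models, `[[`, "spec"),
    mask = rep(TRUE, length(models)),
    models = models, codewords = C,
    thresholds = as.numeric(meta$thresholds),
    priority = as.integer(meta$priority),
    validation = list(fitness = meta$validation_fitness),
    ga = list(trace = as.numeric(meta$ga_trace)),
    encodings = meta$encodings, seed = meta$seed
  ), class = "glyc_ecoc")
}
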