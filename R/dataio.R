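#' Read a samples-by-features intensity table
#'
#' Reads a delimited text file holding non-negative feature intensities.
#' The canonical layout has samples as rows (first column = sample ids,
#' header = feature ids); `samples_in_rows = FALSE` transposes on load.
#'
#' NMR peak-height tables are dense, so missing cells usually indicate an
#' extraction problem: the loader rejects them by default. With
#' `missing = "impute_min"` a missing cell is filled with the feature's
#' minimum observed value instead.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter. `NULL` (default) auto-detects comma vs tab
#'   from the first line.
#' @param samples_in_rows Logical; `TRUE` (default) means rows are samples.
#' @param missing How to treat missing cells: `"error"` (default) or
#'   `"impute_min"`.
#' @return A tibble with a `sample_id` character column and one numeric
#'   column per feature.
#' @export
read_feature_table <- function(path, delim = NULL,
                               samples_in_rows = TRUE,
                               missing = c("error", "impute_min")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% detect_delim(path)
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) abort("duplicate feature ids in header")
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE,
                           name_repair = "minimal")
  if (ncol(raw) < 2L) abort("malformed header: need id column plus >= 1 feature")
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  if (!samples_in_rows) {
    ids <- raw$sample_id  # actually feature ids in this orientation
    m <- t(as.matrix(raw[, -1, drop = FALSE]))
    colnames(m) <- ids
    raw <- dplyr::bind_cols(tibble(sample_id = rownames(m)),
                            as_tibble(m, .name_repair = "minimal"))
  }
  validate_feature_table(raw, missing = missing)
}

validate_feature_table <- function(table, missing = "error") {
  if (anyDuplicated(table$sample_id)) abort("duplicate sample ids")
  feats <- feature_ids(table)
  if (anyDuplicated(feats)) abort("duplicate feature ids")
  m <- suppressWarnings(as.matrix(
    as.data.frame(lapply(table[feats], as.numeric))
  ))
  colnames(m) <- feats
  if (any(is.na(m))) {
    if (missing == "error") {
      abort("missing or non-numeric intensity cells (set missing = 'impute_min' to impute)")
    }
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) {
        if (all(nas)) abort(paste0("feature ", feats[j], " has no observed values"))
        m[nas, j] <- min(m[!nas, j])
      }
    }
  }
  if (any(m < 0)) abort("negative intensity")
  out <- as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(out) <- feats
  dplyr::bind_cols(tibble(sample_id = as.character(table$sample_id)), out)
}

detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Write a feature table to delimited text
#'
#' @param table Feature tibble (see [read_feature_table()]).
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, delim = ",") {
  ft_matrix(table)  # validates shape
  readr::write_delim(table, path, delim = delim)
  invisible(path)
}

#' Read per-sample handling metadata
#'
#' Requires columns `sample_id`, `subject_id`, `time_h` (pre-centrifugation
#' delay, hours) and `temperature_c`; an optional `group_label` column holds
#' coarse time levels (e.g. "same day") for legacy material.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; auto-detected when `NULL`.
#' @return A validated tibble of sample metadata.
#' @export
read_sample_meta <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% detect_delim(path)
  meta <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                            progress = FALSE, show_col_types = FALSE)
  need <- c("sample_id", "subject_id", "time_h", "temperature_c")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    abort(paste0("metadata missing column(s): ", paste(missing, collapse = ", ")))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$subject_id <- as.character(meta$subject_id)
  meta$time_h <- as.numeric(meta$time_h)
  meta$temperature_c <- as.numeric(meta$temperature_c)
  check_meta(meta)
  if (any(!is.finite(meta$temperature_c))) abort("temperature_c must be finite")
  as_tibble(meta)
}

#' Report sample-id agreement between a feature table and metadata
#'
#' @param table Feature tibble.
#' @param meta Metadata tibble.
#' @return A list with `matched`, `only_table`, `only_meta` character vectors.
#' @export
match_samples <- function(table, meta) {
  a <- as.character(table$sample_id)
  b <- as.character(meta$sample_id)
  list(matched = intersect(a, b),
       only_table = setdiff(a, b),
       only_meta = setdiff(b, a))
}

# --- model serialization ----------------------------------------------------

SERIAL_VERSION <- "1.0"

#' Serialize a fitted drift model to structured text
#'
#' The document is JSON: spline knots and values per cluster, exclusions,
#' and the configuration snapshot. Human-inspectable and diffable; a
#' mandatory version field guards cross-version reads.
#'
#' @param model A [fit_drift_model()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drift_model <- function(model, path) {
  stopifnot(inherits(model, "drift_model"))
  doc <- list(
    format = "benchdrift_drift_model",
    version = SERIAL_VERSION,
    temperature_c = model$temperature_c,
    t_ref = model$t_ref,
    time_points = model$time_points,
    clusters = lapply(model$clusters, function(cl) {
      list(cluster_id = cl$cluster_id,
           member_features = cl$member_features,
           cluster_profile = unname(cl$cluster_profile),
           drift_fn = list(knots = cl$drift_fn$knots,
                           values = cl$drift_fn$values,
                           t_ref = cl$drift_fn$t_ref,
                           method = cl$drift_fn$method))
    }),
    excluded = model$excluded,
    config = model$config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_drift_model
#' @export
read_drift_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(paste0("cannot parse model file: ",
                                                   conditionMessage(e))))
  if (!identical(doc$format, "benchdrift_drift_model")) {
    abort("not a benchdrift drift model document")
  }
  if (is.null(doc$version)) abort("model document lacks version field")
  clusters <- lapply(seq_along(doc$clusters$cluster_id), function(i) {
    fn <- new_drift_fn(knots = doc$clusters$drift_fn$knots[[i]],
                       values = doc$clusters$drift_fn$values[[i]],
                       t_ref = doc$clusters$drift_fn$t_ref[[i]],
                       method = doc$clusters$drift_fn$method[[i]])
    list(cluster_id = doc$clusters$cluster_id[[i]],
         member_features = doc$clusters$member_features[[i]],
         cluster_profile = setNames(doc$clusters$cluster_profile[[i]],
                                    doc$time_points),
         drift_fn = fn)
  })
  excluded <- as_tibble(doc$excluded)
  if (nrow(excluded) == 0L) {
    excluded <- tibble(feature_id = character(), reason = character())
  }
  new_drift_model(temperature_c = doc$temperature_c, t_ref = doc$t_ref,
                  time_points = doc$time_points, clusters = clusters,
                  excluded = excluded, config = doc$config)
}

#' Serialize a fitted rdCV prediction model to structured text
#'
#' Random-forest ensembles have no portable text form, so the document
#' stores what regenerates the consensus forest exactly: the task, the
#' configuration (including its seed), the selected variables, and the
#' training data. On read the forest is refit deterministically, so
#' predictions round-trip without loss.
#'
#' @param model A [rdcv_fit()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rdcv_model <- function(model, path) {
  stopifnot(inherits(model, "rdcv_model"))
  doc <- list(
    format = "benchdrift_rdcv_model",
    version = SERIAL_VERSION,
    task = model$task,
    config = unclass(model$config),
    selected_variables = model$selected_variables,
    var_counts = model$var_counts,
    outcome = if (model$task == "classification") as.character(model$outcome)
              else model$outcome,
    performance = model$performance,
    per_sample = model$per_sample,
    train = c(list(sample_id = rownames(model$train_x)),
              as.list(as.data.frame(model$train_x)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rdcv_model
#' @export
read_rdcv_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(paste0("cannot parse model file: ",
                                                   conditionMessage(e))))
  if (!identical(doc$format, "benchdrift_rdcv_model")) {
    abort("not a benchdrift rdCV model document")
  }
  if (is.null(doc$version)) abort("model document lacks version field")
  train <- doc$train
  ids <- train$sample_id
  train$sample_id <- NULL
  x <- as.matrix(as.data.frame(train))
  rownames(x) <- ids
  outcome <- if (doc$task == "classification") factor(doc$outcome) else doc$outcome
  config <- do.call(rdcv_config, doc$config[intersect(names(doc$config),
                                                      names(formals(rdcv_config)))])
  ens <- fit_consensus_forest(x, outcome, doc$selected_variables$mid,
                              config, doc$task)
  structure(list(task = doc$task, config = config,
                 selected_variables = doc$selected_variables,
                 var_counts = doc$var_counts,
                 outcome = outcome, train_x = x,
                 per_sample = if (!is.null(doc$per_sample)) as_tibble(doc$per_sample),
                 performance = doc$performance,
                 fitted_ensemble = ens),
            class = "rdcv_model")
}
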