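#' Correct feature intensities to the reference handling state
#'
#' Divides each intensity by its cluster's drift factor at the sample's
#' pre-centrifugation time: `x'_if = x_if / g_c(t_i)`. Features excluded
#' from the drift model (irreproducible or zero-reference) pass through
#' unchanged. Times outside the model's fitted range are clamped to the
#' boundary with a warning.
#'
#' @param table Feature tibble to correct.
#' @param model A fitted [fit_drift_model()] result.
#' @param times Per-sample pre-centrifugation times: either a numeric vector
#'   (one per row of `table`, in order) or a metadata tibble with
#'   `sample_id` and `time_h`.
#' @param time_source Label recorded in the provenance table
#'   (`"metadata"` or `"predicted"`).
#' @param feature_tolerance Minimum fraction of model features that must be
#'   present in `table` (default 0.95); below it the correction aborts.
#' @return The corrected feature tibble. Attribute `"provenance"` holds a
#'   per-sample tibble (`sample_id`, `time_used`, `time_source`, `clamped`);
#'   attribute `"passthrough"` lists uncorrected feature ids.
#' @export
correct_drift <- function(table, model, times, time_source = "metadata",
                          feature_tolerance = 0.95) {
  stopifnot(inherits(model, "drift_model"))
  x <- ft_matrix(table)
  if (is.data.frame(times)) {
    check_meta(times)
    times <- align_meta(table, times)$time_h
  }
  times <- as.numeric(times)
  if (length(times) != nrow(x)) abort("one time per sample required")
  if (any(is.na(times))) abort("time missing for a sample")
  if (any(times <= 0)) abort("times must be positive")

  model_feats <- c(unlist(lapply(model$clusters, `[[`, "member_features")),
                   model$excluded$feature_id)
  present <- intersect(model_feats, colnames(x))
  if (length(present) < feature_tolerance * length(model_feats)) {
    abort(paste0("only ", length(present), "/", length(model_feats),
                 " model features present in table (tolerance ",
                 feature_tolerance, ")"))
  }

  lo <- min(model$time_points); hi <- max(model$time_points)
  clamped <- times < lo | times > hi
  if (any(clamped)) {
    warn(paste0(sum(clamped), " sample time(s) outside [", lo, ", ", hi,
                "] h; clamped to the model boundary"))
  }
  t_used <- pmin(pmax(times, lo), hi)

  out <- x
  for (cl in model$clusters) {
    feats <- intersect(cl$member_features, colnames(x))
    if (length(feats) == 0L) next
    g <- predict(cl$drift_fn, t_used)
    out[, feats] <- x[, feats, drop = FALSE] / g
  }
  passthrough <- intersect(model$excluded$feature_id, colnames(x))
  if (length(passthrough)) {
    inform(paste0(length(passthrough),
                  " excluded feature(s) passed through uncorrected"))
  }
  res <- ft_tibble(out)
  attr(res, "provenance") <- tibble(sample_id = rownames(x),
                                    time_used = t_used,
                                    time_source = time_source,
                                    clamped = clamped)
  attr(res, "passthrough") <- passthrough
  res
}

#' Correct a table with predicted handling conditions
#'
#' The legacy-sample pipeline: classify each sample's pre-centrifugation
#' temperature, predict its pre-centrifugation time with the
#' temperature-matched regression model, clamp the time to the drift model's
#' range, and apply [correct_drift()] with the temperature-matched drift
#' model. Intended for archived samples whose handling metadata are missing.
#'
#' @param table Feature tibble.
#' @param temp_model Classification `rdcv_model` for temperature.
#' @param time_models Named list of regression `rdcv_model`s, names =
#'   temperature labels (e.g. `"4"`, `"22"`).
#' @param drift_models Named list of `drift_model`s with the same names.
#' @param ... Passed to [correct_drift()].
#' @return List with `corrected` (feature tibble) and `provenance` (tibble
#'   `sample_id`, `pred_temperature`, `pred_time_h`, `clamped`).
#' @export
correct_predicted <- function(table, temp_model, time_models, drift_models,
                              ...) {
  stopifnot(inherits(temp_model, "rdcv_model"))
  pred_temp <- as.character(predict(temp_model, table)$prediction)
  unknown <- setdiff(unique(pred_temp), names(drift_models))
  if (length(unknown)) {
    abort(paste0("predicted temperature class without a drift model: ",
                 paste(unknown, collapse = ", ")))
  }
  x <- ft_matrix(table)
  out <- x
  prov <- tibble(sample_id = rownames(x), pred_temperature = pred_temp,
                 pred_time_h = NA_real_, clamped = NA)
  for (tc in unique(pred_temp)) {
    rows <- pred_temp == tc
    sub <- table[rows, , drop = FALSE]
    tm <- time_models[[tc]]
    if (is.null(tm)) abort(paste0("no time model for temperature ", tc))
    pt <- predict(tm, sub)$prediction
    corr <- correct_drift(sub, drift_models[[tc]], times = pmax(pt, 1e-6),
                          time_source = "predicted", ...)
    out[rows, ] <- ft_matrix(corr)[, colnames(out), drop = FALSE]
    pv <- attr(corr, "provenance")
    prov$pred_time_h[rows] <- pv$time_used
    prov$clamped[rows] <- pv$clamped
  }
  list(corrected = ft_tibble(out), provenance = prov)
}
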