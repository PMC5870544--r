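new_drift_model <- function(temperature_c, t_ref, time_points, clusters,
                            excluded, config) {
  structure(list(temperature_c = temperature_c, t_ref = t_ref,
                 time_points = time_points, clusters = clusters,
                 excluded = excluded, config = config),
            class = "drift_model")
}

#' Fit a drift model for one pre-centrifugation temperature
#'
#' Runs the full drift-modeling chain on a feature table restricted to one
#' storage temperature: per-subject fold-change profiles relative to the
#' reference time ([compute_drift_profiles()]), exclusion of features whose
#' drift is irreproducible between subjects ([filter_irreproducible()]),
#' hierarchical clustering of the remaining mean profiles
#' ([cluster_drift_profiles()]), and an anchored cubic-spline drift function
#' per cluster ([fit_drift_fn()]). Every input feature ends up exactly once:
#' in a cluster or in the exclusion list.
#'
#' @param table Feature tibble (typically PQN-normalized).
#' @param meta Metadata tibble covering a single temperature.
#' @param t_ref Reference time (hours, default 1).
#' @param repro_threshold,flat_tol Passed to [filter_irreproducible()].
#' @param k_range Passed to [cluster_drift_profiles()].
#' @return A `drift_model` object.
#' @export
fit_drift_model <- function(table, meta, t_ref = 1, repro_threshold = 0.5,
                            flat_tol = 0.05, k_range = 2:30) {
  meta <- align_meta(table, meta)
  if (length(unique(meta$temperature_c)) != 1L) {
    abort("single temperature required")
  }
  times <- sort(unique(meta$time_h))
  if (length(times) < 4L) abort("insufficient time points")
  profiles <- compute_drift_profiles(table, meta, t_ref = t_ref)
  flagged <- attr(profiles, "flagged")
  filt <- filter_irreproducible(profiles, threshold = repro_threshold,
                                flat_tol = flat_tol)
  assignment <- cluster_drift_profiles(filt$kept, k_range = k_range)
  clusters <- lapply(sort(unique(assignment$cluster_id)), function(cid) {
    members <- assignment$feature_id[assignment$cluster_id == cid]
    prof_mat <- do.call(rbind,
      filt$kept$mean_profile[match(members, filt$kept$feature_id)])
    cluster_profile <- colMeans(prof_mat)
    names(cluster_profile) <- times
    list(cluster_id = cid, member_features = members,
         cluster_profile = cluster_profile,
         drift_fn = fit_drift_fn(cluster_profile, times, t_ref = t_ref))
  })
  excluded <- bind_rows(
    dplyr::select(filt$excluded, "feature_id", "reason"),
    tibble(feature_id = flagged,
           reason = rep("zero_reference", length(flagged)))
  )
  if (nrow(excluded) == 0L) {
    excluded <- tibble(feature_id = character(), reason = character())
  }
  model <- new_drift_model(
    temperature_c = unique(meta$temperature_c), t_ref = t_ref,
    time_points = times, clusters = clusters, excluded = excluded,
    config = list(t_ref = t_ref, repro_threshold = repro_threshold,
                  flat_tol = flat_tol, k_range = range(k_range))
  )
  # accounting invariant: clustered + excluded = all features, no duplicates
  all_assigned <- c(unlist(lapply(clusters, `[[`, "member_features")),
                    excluded$feature_id)
  if (anyDuplicated(all_assigned) ||
      !setequal(all_assigned, feature_ids(table)) ||
      length(all_assigned) != length(feature_ids(table))) {
    abort("internal error: feature accounting is not a partition")
  }
  model
}

#' @export
print.drift_model <- function(x, ...) {
  cat("<drift_model> ", x$temperature_c, " degC, ", length(x$clusters),
      " clusters, ", sum(lengths(lapply(x$clusters, `[[`, "member_features"))),
      " modeled features, ", nrow(x$excluded), " excluded\n", sep = "")
  cat("  time points (h): ", paste(x$time_points, collapse = ", "),
      "; anchored at t = ", x$t_ref, " h\n", sep = "")
  invisible(x)
}

#' Tidy a drift model into per-cluster profile rows
#'
#' @param x A `drift_model`.
#' @param ... Unused.
#' @return Tibble with `cluster_id`, `n_features`, `time_h`, `profile`
#'   (cluster-mean fold-change) and `fitted` (anchored spline value).
#' @exportS3Method generics::tidy
tidy.drift_model <- function(x, ...) {
  bind_rows(lapply(x$clusters, function(cl) {
    tibble(cluster_id = cl$cluster_id,
           n_features = length(cl$member_features),
           time_h = x$time_points,
           profile = unname(cl$cluster_profile),
           fitted = predict(cl$drift_fn, x$time_points))
  }))
}

#' @exportS3Method generics::glance
glance.drift_model <- function(x, ...) {
  n_mod <- sum(lengths(lapply(x$clusters, `[[`, "member_features")))
  tibble(temperature_c = x$temperature_c,
         n_clusters = length(x$clusters),
         n_modeled = n_mod,
         n_excluded = nrow(x$excluded),
         n_features = n_mod + nrow(x$excluded),
         t_ref = x$t_ref)
}

#' Plot cluster drift functions
#'
#' @param object A `drift_model`.
#' @param ... Unused.
#' @return A ggplot: one panel per cluster, cluster-mean fold-changes as
#'   points and the anchored drift spline as a curve.
#' @exportS3Method ggplot2::autoplot
autoplot.drift_model <- function(object, ...) {
  pts <- tidy(object)
  grid <- seq(min(object$time_points), max(object$time_points), length.out = 120)
  curves <- bind_rows(lapply(object$clusters, function(cl) {
    tibble(cluster_id = cl$cluster_id, time_h = grid,
           g = predict(cl$drift_fn, grid))
  }))
  ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 1, colour = "grey80") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$time_h, y = .data$g)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$time_h, y = .data$profile),
                        colour = "grey40") +
    ggplot2::facet_wrap(~cluster_id, scales = "free_y") +
    ggplot2::labs(x = "pre-centrifugation time (h)",
                  y = "drift factor g(t), anchored at reference",
                  title = paste0("Cluster drift functions at ",
                                 object$temperature_c, " degC"))
}
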