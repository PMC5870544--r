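#' Coefficient of variation
#'
#' Sample standard deviation divided by mean; the data-quality metric used
#' throughout the correction reports. Scale-free: `feature_cv(k * x) ==
#' feature_cv(x)` for `k > 0`.
#'
#' @param values Positive numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
feature_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) abort("need at least 2 values")
  m <- mean(values)
  if (m <= 0) abort("zero or negative mean")
  sd(values) / m
}

#' Per-cluster and global data-quality report for a correction
#'
#' Computes, per feature, the coefficient of variation over the 1-36 h
#' handling design before and after correction, aggregates by drift
#' cluster, and tests the per-cluster improvement with a two-sided Wilcoxon
#' signed-rank over the member features' paired CVs. Global rows summarise
#' modeled, irreproducible and all features, including the proportion of
#' features with CV > 0.30.
#'
#' By default the CV is computed within each subject (across that subject's
#' time course) and averaged over subjects, so it reflects handling-induced
#' plus analytical variation without between-person level differences; the
#' `"pooled"` mode computes one CV over all samples instead.
#'
#' @param original Uncorrected feature tibble.
#' @param corrected_meta Table corrected with recorded (metadata) times.
#' @param corrected_pred Optional table corrected with predicted times.
#' @param model The `drift_model` that produced the corrections.
#' @param meta Sample metadata (required for `cv_mode = "per_subject"`).
#' @param cv_mode `"per_subject"` (default) or `"pooled"`.
#' @param cv_threshold Threshold for the "high-CV" proportion (default 0.30).
#' @return A `correction_report`: list of tibbles `per_feature`,
#'   `per_cluster`, `global`.
#' @export
correction_report <- function(original, corrected_meta, corrected_pred = NULL,
                              model, meta = NULL,
                              cv_mode = c("per_subject", "pooled"),
                              cv_threshold = 0.30) {
  stopifnot(inherits(model, "drift_model"))
  cv_mode <- match.arg(cv_mode)
  if (cv_mode == "per_subject" && is.null(meta)) {
    abort("meta is required for per-subject CVs (or use cv_mode = 'pooled')")
  }
  x0 <- ft_matrix(original)
  xm <- ft_matrix(corrected_meta)
  if (!identical(dim(x0), dim(xm)) ||
      !identical(colnames(x0), colnames(xm)) ||
      !identical(rownames(x0), rownames(xm))) {
    abort("original and corrected tables must share samples and features")
  }
  xp <- NULL
  if (!is.null(corrected_pred)) {
    xp <- ft_matrix(corrected_pred)
    if (!identical(colnames(x0), colnames(xp)) ||
        !identical(rownames(x0), rownames(xp))) {
      abort("original and corrected tables must share samples and features")
    }
  }

  subj <- NULL
  if (cv_mode == "per_subject") {
    meta_al <- align_meta(ft_tibble(x0), meta)
    subj <- meta_al$subject_id
  }
  col_cv <- function(x) {
    if (is.null(subj)) return(apply(x, 2, feature_cv))
    apply(x, 2, function(v) {
      mean(vapply(split(v, subj), feature_cv, numeric(1)))
    })
  }
  cluster_of <- setNames(rep(NA_integer_, ncol(x0)), colnames(x0))
  for (cl in model$clusters) {
    cluster_of[intersect(cl$member_features, names(cluster_of))] <- cl$cluster_id
  }
  per_feature <- tibble(
    feature_id = colnames(x0),
    cluster_id = unname(cluster_of),
    cv_original = col_cv(x0),
    cv_corrected_metadata = col_cv(xm),
    cv_corrected_predicted = if (!is.null(xp)) col_cv(xp) else NA_real_
  )

  wilcox_p <- function(a, b) {
    d <- b - a
    if (length(d) < 2L) return(NA_real_)
    if (all(d == 0)) return(1)
    tryCatch(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value,
             error = function(e) NA_real_)
  }
  per_cluster <- per_feature %>%
    filter(!is.na(.data$cluster_id)) %>%
    tidyr::nest(data = -"cluster_id") %>%
    mutate(
      n = vapply(.data$data, nrow, integer(1)),
      cv_original = vapply(.data$data, function(d) mean(d$cv_original),
                           numeric(1)),
      cv_corrected_metadata = vapply(.data$data,
        function(d) mean(d$cv_corrected_metadata), numeric(1)),
      cv_corrected_predicted = vapply(.data$data,
        function(d) mean(d$cv_corrected_predicted), numeric(1)),
      p_metadata = vapply(.data$data,
        function(d) wilcox_p(d$cv_original, d$cv_corrected_metadata),
        numeric(1)),
      p_predicted = vapply(.data$data, function(d) {
        if (all(is.na(d$cv_corrected_predicted))) NA_real_
        else wilcox_p(d$cv_original, d$cv_corrected_predicted)
      }, numeric(1))
    ) %>%
    select(-"data") %>%
    arrange(.data$cluster_id) %>%
    mutate(stars_metadata = p_stars(.data$p_metadata),
           stars_predicted = p_stars(.data$p_predicted))

  modeled <- per_feature %>% filter(!is.na(.data$cluster_id))
  irr <- per_feature %>% filter(is.na(.data$cluster_id))
  global_row <- function(df, label) {
    tibble(group = label, n = nrow(df),
           cv_original = mean(df$cv_original),
           cv_corrected_metadata = mean(df$cv_corrected_metadata),
           cv_corrected_predicted = mean(df$cv_corrected_predicted),
           prop_high_cv_original = mean(df$cv_original > cv_threshold),
           prop_high_cv_metadata = mean(df$cv_corrected_metadata > cv_threshold),
           prop_high_cv_predicted = mean(df$cv_corrected_predicted > cv_threshold))
  }
  global <- bind_rows(global_row(modeled, "modeled"),
                      if (nrow(irr)) global_row(irr, "irreproducible"),
                      global_row(per_feature, "total"))

  structure(list(per_feature = per_feature, per_cluster = per_cluster,
                 global = global, cv_threshold = cv_threshold,
                 cv_mode = cv_mode),
            class = "correction_report")
}

p_stars <- function(p) {
  case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
            p < 0.05 ~ "*", TRUE ~ "")
}

#' @export
print.correction_report <- function(x, ...) {
  cat("<correction_report> ", nrow(x$per_feature), " features, ",
      nrow(x$per_cluster), " clusters\n", sep = "")
  tot <- x$global[x$global$group == "total", ]
  cat(sprintf("  total mean CV: %.3f -> %.3f (metadata)",
              tot$cv_original, tot$cv_corrected_metadata))
  if (!is.na(tot$cv_corrected_predicted)) {
    cat(sprintf(" / %.3f (predicted)", tot$cv_corrected_predicted))
  }
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.correction_report <- function(x, ...) x$per_cluster

#' @exportS3Method generics::glance
glance.correction_report <- function(x, ...) {
  tot <- x$global[x$global$group == "total", ]
  mod <- x$global[x$global$group == "modeled", ]
  tibble(n_features = nrow(x$per_feature),
         n_clusters = nrow(x$per_cluster),
         mean_cv_original = tot$cv_original,
         mean_cv_metadata = tot$cv_corrected_metadata,
         mean_cv_predicted = tot$cv_corrected_predicted,
         cv_change_metadata = tot$cv_corrected_metadata / tot$cv_original - 1,
         modeled_cv_change_metadata =
           mod$cv_corrected_metadata / mod$cv_original - 1,
         prop_high_cv_original = tot$prop_high_cv_original,
         prop_high_cv_metadata = tot$prop_high_cv_metadata)
}

#' Percentile surface of relative deviation from the reference state
#'
#' For every sample and feature, the relative deviation from the subject's
#' own reference-time sample, `x / x_ref - 1`, is pooled across subjects and
#' features per time point; the requested percentiles per time form the
#' surface (the isobaric-line view of feature stability).
#'
#' @param table Feature tibble.
#' @param meta Metadata tibble (single temperature; every subject needs a
#'   `t_ref` sample).
#' @param t_ref Reference time (hours, default 1).
#' @param percentile_levels Percentiles in (0, 1).
#' @return A `deviation_surface` tibble: `time_h`, `percentile`, `deviation`.
#' @export
deviation_surface <- function(table, meta, t_ref = 1,
                              percentile_levels = c(0.05, 0.25, 0.5,
                                                    0.75, 0.95)) {
  stopifnot(all(percentile_levels > 0 & percentile_levels < 1))
  meta <- align_meta(table, meta)
  x <- ft_matrix(table)
  times <- sort(unique(meta$time_h))
  if (!t_ref %in% times) abort("missing reference sample")
  ref_rows <- meta$time_h == t_ref
  subj_ref <- meta$subject_id[ref_rows]
  if (anyDuplicated(subj_ref)) abort("duplicate reference sample for a subject")
  if (!all(unique(meta$subject_id) %in% subj_ref)) {
    abort("missing reference sample")
  }
  ref <- x[ref_rows, , drop = FALSE]
  rownames(ref) <- subj_ref
  rows <- lapply(times, function(t) {
    sel <- which(meta$time_h == t)
    dev <- x[sel, , drop = FALSE] / ref[meta$subject_id[sel], , drop = FALSE] - 1
    q <- quantile(as.numeric(dev), probs = percentile_levels, names = FALSE)
    tibble(time_h = t, percentile = percentile_levels, deviation = q)
  })
  out <- bind_rows(rows)
  class(out) <- c("deviation_surface", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.deviation_surface <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_h, y = .data$deviation,
                               group = .data$percentile,
                               colour = factor(.data$percentile))) +
    ggplot2::geom_hline(yintercept = c(-0.3, -0.2, 0.2, 0.3),
                        colour = "grey85") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pre-centrifugation time (h)",
                  y = "relative deviation from reference",
                  colour = "percentile",
                  title = "Feature-intensity deviation percentiles")
}

#' Compare predicted times across coarse handling groups
#'
#' One-way ANOVA of predicted pre-centrifugation times over group labels
#' (e.g. "same day" / "next day" / "two days"), with all pairwise
#' comparisons Tukey-HSD adjusted. This is the check applied to legacy
#' samples whose true times are known only as coarse levels.
#'
#' @param predicted_times Numeric vector.
#' @param group_label Factor (or coercible) of the same length; >= 2 groups
#'   with >= 2 members each.
#' @return List with `p_overall`, `pairwise` (tibble `comparison`,
#'   `diff`, `p_adjusted`) and the fitted `aov` object.
#' @export
compare_predicted_groups <- function(predicted_times, group_label) {
  group_label <- factor(group_label)
  if (nlevels(group_label) < 2L) abort("need at least 2 groups")
  if (any(table(group_label) < 2L)) abort("every group needs >= 2 members")
  d <- data.frame(y = as.numeric(predicted_times), g = group_label)
  fit <- aov(y ~ g, data = d)
  p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$g
  pairwise <- tibble(comparison = rownames(tk),
                     diff = tk[, "diff"],
                     p_adjusted = tk[, "p adj"])
  list(p_overall = p_overall, pairwise = pairwise, fit = fit)
}
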