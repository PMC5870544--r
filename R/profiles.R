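#' Per-feature drift profiles relative to the reference time
#'
#' For each feature and subject, intensities are scaled to the subject's own
#' sample at the reference time (`t_ref`, default 1 h), giving fold-change
#' kinetics that are free of between-subject level differences. The mean
#' profile averages these fold-changes over subjects; reproducibility is the
#' median pairwise Pearson correlation of the subjects' log fold-change
#' profiles (0 when a profile is flat, i.e. has zero variance).
#'
#' @param table Feature tibble for a single temperature.
#' @param meta Metadata tibble (`sample_id`, `subject_id`, `time_h`,
#'   `temperature_c`); must cover exactly one temperature and contain a
#'   `t_ref` sample for every subject.
#' @param t_ref Reference time in hours (default 1).
#' @return A `drift_profiles` tibble: one row per feature with columns
#'   `feature_id`, `reproducibility`, `mean_profile` (list of named numeric,
#'   one value per time point) and `per_subject` (list of subjects x times
#'   fold-change matrices). Features with a zero intensity at `t_ref` are
#'   dropped and recorded in `attr(, "flagged")`.
#' @export
compute_drift_profiles <- function(table, meta, t_ref = 1) {
  meta <- align_meta(table, meta)
  if (length(unique(meta$temperature_c)) != 1L) {
    abort("single temperature required")
  }
  x <- ft_matrix(table)
  times <- sort(unique(meta$time_h))
  if (!t_ref %in% times) abort("no sample at the reference time")
  subjects <- sort(unique(meta$subject_id))
  # subjects x times index into rows of x
  idx <- matrix(NA_integer_, length(subjects), length(times),
                dimnames = list(subjects, times))
  for (i in seq_len(nrow(meta))) {
    s <- match(meta$subject_id[i], subjects)
    t <- match(meta$time_h[i], times)
    if (!is.na(idx[s, t])) abort("duplicate (subject, time) sample")
    idx[s, t] <- i
  }
  if (any(is.na(idx[, match(t_ref, times)]))) {
    abort("subject missing reference-time sample")
  }

  feats <- colnames(x)
  flagged <- character()
  rows <- vector("list", length(feats))
  for (j in seq_along(feats)) {
    v <- x[, j]
    fc <- matrix(NA_real_, length(subjects), length(times),
                 dimnames = list(subjects, times))
    ref_vals <- v[idx[, match(t_ref, times)]]
    if (any(ref_vals == 0)) {
      flagged <- c(flagged, feats[j])
      next
    }
    for (t in seq_along(times)) {
      ii <- idx[, t]
      ok <- !is.na(ii)
      fc[ok, t] <- v[ii[ok]] / ref_vals[ok]
    }
    mean_profile <- colMeans(fc, na.rm = TRUE)
    names(mean_profile) <- times
    rows[[j]] <- tibble(
      feature_id = feats[j],
      reproducibility = profile_reproducibility(fc),
      mean_profile = list(mean_profile),
      per_subject = list(fc)
    )
  }
  out <- bind_rows(rows)
  structure(out,
            class = c("drift_profiles", class(out)),
            time_points = times, t_ref = t_ref,
            temperature_c = unique(meta$temperature_c),
            subjects = subjects, flagged = flagged)
}

# Median pairwise Pearson correlation of subjects' log fold-change profiles.
# A zero-variance (flat) profile has no defined correlation; those pairs
# contribute 0, so a feature flat in every subject scores 0.
profile_reproducibility <- function(fc) {
  lp <- log(fc)
  ns <- nrow(lp)
  if (ns < 2L) return(NA_real_)
  cors <- numeric(0)
  for (a in seq_len(ns - 1L)) {
    for (b in seq(a + 1L, ns)) {
      pa <- lp[a, ]; pb <- lp[b, ]
      ok <- is.finite(pa) & is.finite(pb)
      if (sum(ok) < 3L || sd(pa[ok]) == 0 || sd(pb[ok]) == 0) {
        cors <- c(cors, 0)
      } else {
        cors <- c(cors, cor(pa[ok], pb[ok]))
      }
    }
  }
  median(cors)
}

#' Split drift profiles into reproducible and irreproducible sets
#'
#' A feature is excluded only when its between-subject reproducibility falls
#' below `threshold` *and* its mean profile actually drifts (departs from
#' flat by more than `flat_tol` on the log scale at some time point):
#' flat-but-noisy features stay in, as "stable".
#'
#' @param profiles A [compute_drift_profiles()] result.
#' @param threshold Reproducibility threshold (default 0.5).
#' @param flat_tol Flatness tolerance on |log fold-change| (default 0.05).
#' @return List with `kept` (a `drift_profiles` subset) and `excluded`
#'   (tibble `feature_id`, `reason`, `reproducibility`).
#' @export
filter_irreproducible <- function(profiles, threshold = 0.5, flat_tol = 0.05) {
  stopifnot(inherits(profiles, "drift_profiles"))
  drifts <- vapply(profiles$mean_profile,
                   function(p) max(abs(log(p))), numeric(1))
  excl <- !is.na(profiles$reproducibility) &
    profiles$reproducibility < threshold & drifts > flat_tol
  kept <- profiles[!excl, , drop = FALSE]
  for (a in c("time_points", "t_ref", "temperature_c", "subjects", "flagged")) {
    attr(kept, a) <- attr(profiles, a)
  }
  class(kept) <- class(profiles)
  list(kept = kept,
       excluded = tibble(feature_id = profiles$feature_id[excl],
                         reason = "irreproducible",
                         reproducibility = profiles$reproducibility[excl]))
}

#' @exportS3Method generics::tidy
tidy.drift_profiles <- function(x, ...) {
  times <- attr(x, "time_points")
  tidyr::unnest(
    tibble(feature_id = x$feature_id,
           reproducibility = x$reproducibility,
           time_h = list(times),
           fold_change = lapply(x$mean_profile, unname)),
    c("time_h", "fold_change")
  )
}
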