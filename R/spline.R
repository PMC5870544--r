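# Anchored cubic-spline drift functions.
#
# A drift function g_c(t) is stored as (knots, values, t_ref, method) and
# evaluated as the natural cubic interpolant of the values, divided by its
# own value at t_ref so that g_c(t_ref) = 1 exactly. Storing knot values
# rather than spline coefficients makes the serialized form (dataio module)
# exact and human-readable. Evaluation outside [min(knots), max(knots)]
# clamps to the boundary: extrapolating a cubic outside the observed delay
# range is unsafe, clamping is conservative.

new_drift_fn <- function(knots, values, t_ref, method = "natural") {
  stopifnot(length(knots) == length(values), !is.unsorted(knots))
  structure(list(knots = as.numeric(knots), values = as.numeric(values),
                 t_ref = as.numeric(t_ref), method = method),
            class = "drift_fn")
}

#' Fit an anchored drift function to a cluster profile
#'
#' Fits a natural cubic spline through the cluster-mean fold-change values:
#' interpolating when there are at most 5 time points (the typical handling
#' design), smoothing with generalized cross-validation when there are more.
#' The curve is re-anchored by division with its value at `t_ref`, so
#' `g_c(t_ref) = 1`. If the anchored curve dips to zero or below anywhere on
#' a dense grid, the cluster is refit with a monotone-between-knots
#' piecewise-linear fallback (drift factors must stay positive for
#' multiplicative correction) and a warning is raised.
#'
#' @param cluster_profile Numeric vector of mean fold-changes, one per time
#'   point; all positive.
#' @param time_points Strictly increasing time points (hours); at least 4.
#' @param t_ref Reference time (must lie within the time range).
#' @return A `drift_fn` object; evaluate it with [predict()][predict.drift_fn].
#' @export
fit_drift_fn <- function(cluster_profile, time_points, t_ref = 1) {
  time_points <- as.numeric(time_points)
  cluster_profile <- as.numeric(cluster_profile)
  if (anyDuplicated(time_points)) abort("duplicate time points")
  if (is.unsorted(time_points)) abort("time points must be increasing")
  if (length(time_points) < 4L) abort("insufficient time points (need >= 4)")
  if (length(cluster_profile) != length(time_points)) {
    abort("profile and time points differ in length")
  }
  if (any(cluster_profile <= 0)) abort("non-positive profile values")
  if (t_ref < min(time_points) || t_ref > max(time_points)) {
    abort("t_ref outside the observed time range")
  }
  if (length(time_points) > 5L) {
    sm <- smooth.spline(time_points, cluster_profile, cv = FALSE)
    values <- predict(sm, time_points)$y
    method <- "natural"  # natural interpolant of the GCV-smoothed knot values
  } else {
    values <- cluster_profile
    method <- "natural"
  }
  fn <- new_drift_fn(time_points, values, t_ref, method)
  grid <- seq(min(time_points), max(time_points), length.out = 512)
  if (any(predict(fn, grid) <= 0)) {
    warn("anchored spline non-positive; falling back to piecewise-linear drift")
    fn <- new_drift_fn(time_points, values, t_ref, method = "linear")
    if (any(predict(fn, grid) <= 0)) abort("drift function non-positive")
  }
  fn
}

#' Evaluate an anchored drift function
#'
#' @param object A `drift_fn`.
#' @param t Times (hours); values outside the fitted range are clamped to
#'   the boundary.
#' @param ... Unused.
#' @return Numeric vector `g_c(t)` with `g_c(t_ref) = 1`.
#' @export
predict.drift_fn <- function(object, t, ...) {
  t <- pmin(pmax(as.numeric(t), min(object$knots)), max(object$knots))
  raw <- eval_raw_spline(object, t)
  ref <- eval_raw_spline(object, object$t_ref)
  raw / ref
}

eval_raw_spline <- function(fn, t) {
  if (identical(fn$method, "linear")) {
    approx(fn$knots, fn$values, xout = t, rule = 2)$y
  } else {
    spline(fn$knots, fn$values, xout = t, method = "natural")$y
  }
}

#' @export
print.drift_fn <- function(x, ...) {
  cat("<drift_fn> ", x$method, " spline, ", length(x$knots),
      " knots on [", min(x$knots), ", ", max(x$knots), "] h, anchored at t = ",
      x$t_ref, " h\n", sep = "")
  invisible(x)
}
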