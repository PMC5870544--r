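#' Probabilistic quotient normalization
#'
#' Removes sample-level dilution-like intensity effects (Dieterle et al.
#' 2006). For each sample the quotients intensity/reference are formed over
#' features positive in both the sample and the reference; the sample is
#' divided by the median quotient. The default reference spectrum is the
#' feature-wise median across samples; an external reference vector lets a
#' later batch be normalized against the reference of a training batch,
#' bridging batch effects in peak shape.
#'
#' @param table Feature tibble (`sample_id` + numeric feature columns).
#' @param reference `"median"` (default; feature-wise median of `table`) or
#'   `"external"`.
#' @param ref_vector Named numeric vector of reference intensities (names =
#'   feature ids) when `reference = "external"`.
#' @return A `pqn_result`: list with `normalized` (feature tibble),
#'   `factors` (tibble `sample_id`, `factor`) and `reference` (tibble
#'   `feature_id`, `value`).
#' @examples
#' tab <- tibble::tibble(sample_id = c("a", "b"),
#'                       f1 = c(1, 3), f2 = c(2, 6))
#' pqn_normalize(tab)$factors
#' @export
pqn_normalize <- function(table, reference = c("median", "external"),
                          ref_vector = NULL) {
  reference <- match.arg(reference)
  x <- ft_matrix(table)
  if (nrow(x) == 0L) abort("empty feature table")
  if (reference == "median") {
    r <- apply(x, 2, median)
  } else {
    if (is.null(ref_vector)) abort("ref_vector required for external reference")
    missing <- setdiff(colnames(x), names(ref_vector))
    if (length(missing)) {
      abort(paste0("reference lacks ", length(missing), " feature(s)"))
    }
    r <- as.numeric(ref_vector[colnames(x)])
  }
  factors <- vapply(seq_len(nrow(x)), function(i) {
    ok <- r > 0 & x[i, ] > 0
    if (!any(ok)) {
      abort(paste0("sample ", rownames(x)[i],
                   " has no positive overlap with the reference"))
    }
    median(x[i, ok] / r[ok])
  }, numeric(1))
  norm <- x / factors
  structure(list(
    normalized = ft_tibble(norm),
    factors = tibble(sample_id = rownames(x), factor = factors),
    reference = tibble(feature_id = colnames(x), value = unname(r))
  ), class = "pqn_result")
}

#' @export
print.pqn_result <- function(x, ...) {
  cat("<pqn_result> ", nrow(x$factors), " samples, ",
      nrow(x$reference), " features\n", sep = "")
  cat("  dilution factors: median ", signif(median(x$factors$factor), 4),
      ", range [", signif(min(x$factors$factor), 4), ", ",
      signif(max(x$factors$factor), 4), "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pqn_result <- function(x, ...) x$factors

#' @exportS3Method generics::glance
glance.pqn_result <- function(x, ...) {
  tibble(n_samples = nrow(x$factors), n_features = nrow(x$reference),
         median_factor = median(x$factors$factor),
         min_factor = min(x$factors$factor),
         max_factor = max(x$factors$factor))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pqn_result <- function(object, ...) {
  ggplot2::ggplot(object$factors,
                  ggplot2::aes(x = .data$factor)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "PQN dilution factor", y = "samples",
                  title = "Per-sample probabilistic quotient factors")
}
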