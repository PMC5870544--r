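#' Cluster reproducible drift profiles
#'
#' Hierarchical agglomerative clustering (average linkage, Euclidean distance
#' on log-transformed mean profiles). The number of clusters is chosen
#' automatically within `k_range` by maximum mean silhouette width; ties go
#' to the smallest k. Degenerate inputs (all profiles identical) collapse to
#' a single cluster.
#'
#' @param profiles A `drift_profiles` object (usually the `kept` element of
#'   [filter_irreproducible()]).
#' @param k_range Candidate cluster counts (default `2:30`).
#' @return A tibble `feature_id`, `cluster_id`, with the chosen `k` and mean
#'   silhouette widths in attributes.
#' @export
cluster_drift_profiles <- function(profiles, k_range = 2:30) {
  stopifnot(inherits(profiles, "drift_profiles"))
  n <- nrow(profiles)
  if (n < 2L) abort("need at least 2 profiles to cluster")
  if (n < min(k_range)) abort("fewer profiles than min(k_range)")
  m <- do.call(rbind, lapply(profiles$mean_profile, log))
  rownames(m) <- profiles$feature_id
  d <- dist(m)
  if (max(d) < 1e-12) {
    out <- tibble(feature_id = profiles$feature_id, cluster_id = 1L)
    attr(out, "k") <- 1L
    attr(out, "silhouette") <- NA_real_
    return(out)
  }
  hc <- hclust(d, method = "average")
  ks <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(ks) == 0L) ks <- 2L
  sil <- vapply(ks, function(k) {
    ct <- cutree(hc, k = k)
    mean_silhouette(ct, d)
  }, numeric(1))
  best <- ks[which.max(sil)]  # which.max takes the first, i.e. smallest k, on ties
  ct <- cutree(hc, k = best)
  # relabel clusters by decreasing size for stable, readable ids
  sizes <- sort(table(ct), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  out <- tibble(feature_id = profiles$feature_id,
                cluster_id = as.integer(relab[as.character(ct)]))
  attr(out, "k") <- best
  attr(out, "silhouette") <- setNames(sil, ks)
  out
}

# Mean silhouette width; undefined widths (zero distances both within and
# between) count as 0.
mean_silhouette <- function(labels, d) {
  if (length(unique(labels)) < 2L) return(-Inf)
  s <- cluster::silhouette(labels, d)
  w <- s[, "sil_width"]
  w[!is.finite(w)] <- 0
  mean(w)
}
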