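# Shared fixtures: all synthetic, built in code.

# A compact handling-study config: 8 subjects, 60 features, four archetypes
# plus a few irreproducible features. Small enough for fast tests, large
# enough for clustering and correction to be meaningful.
small_sim_config <- function(seed = 1, noise_sd = 0.05,
                             subject_level_sd = 0.3, dilution_sd = 0.1,
                             n_subjects = 8) {
  sim_config(
    n_subjects = n_subjects, n_features = 60,
    cluster_spec = tibble::tibble(
      archetype = c("increase", "decrease", "stable", "excursion_3h"),
      n_features = c(16, 15, 15, 10),
      effect = c(1, 0.8, 0, 0.6),
      tau_warm = c(6, 18, 12, 12),
      tau_cold = c(30, 9, 12, 12)
    ),
    frac_irreproducible = 4 / 60,
    noise_sd = noise_sd, subject_level_sd = subject_level_sd,
    dilution_sd = dilution_sd, seed = seed
  )
}

# Noise-free config with three planted clusters: every estimate must equal
# truth to numerical precision.
noiseless_sim_config <- function(seed = 5) {
  sim_config(
    n_subjects = 6, n_features = 40,
    cluster_spec = tibble::tibble(
      archetype = c("increase", "decrease", "stable"),
      n_features = c(14, 13, 13), effect = c(1, 0.8, 0)
    ),
    frac_irreproducible = 0,
    noise_sd = 0, subject_level_sd = 0, dilution_sd = 0, seed = seed
  )
}

# Split a simulated study into the single-temperature table + metadata the
# drift functions expect.
sim_at_temp <- function(sim, temperature, table = sim$table) {
  meta <- sim$meta[sim$meta$temperature_c == temperature, ]
  list(table = table[table$sample_id %in% meta$sample_id, ], meta = meta)
}

# Effective-truth adjusted Rand index for a fitted drift model.
model_truth_ari <- function(model, truth, temperature) {
  lab <- truth_labels(truth, temperature)
  names(lab) <- truth$features$feature_id
  asg <- do.call(rbind, lapply(model$clusters, function(cl) {
    data.frame(feature_id = cl$member_features, cluster = cl$cluster_id)
  }))
  keep <- !is.na(lab[asg$feature_id])
  mclust::adjustedRandIndex(asg$cluster[keep], lab[asg$feature_id][keep])
}

# A tiny hand-sized feature tibble.
toy_table <- function(m, ids = NULL) {
  if (!is.null(ids)) rownames(m) <- ids
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    rownames(m) <- paste0("s", seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  out <- tibble::as_tibble(as.data.frame(m))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
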