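test_that("feature_cv matches hand computation and is scale-free", {
  expect_equal(feature_cv(rep(7, 5)), 0)
  expect_equal(feature_cv(c(1, 2, 3)), 0.5)  # sd 1, mean 2
  x <- rlnorm(20)
  expect_equal(feature_cv(1000 * x), feature_cv(x))
  expect_error(feature_cv(3), "at least 2")
  expect_error(feature_cv(c(-1, 1)), "mean")
})

small_report_fixture <- function(seed = 2) {
  sim <- simulate_handling_study(small_sim_config(seed = seed, n_subjects = 16))
  pq <- pqn_normalize(sim$table)
  d <- sim_at_temp(sim, 22, pq$normalized)
  model <- fit_drift_model(d$table, d$meta)
  corr <- suppressMessages(correct_drift(d$table, model, times = d$meta))
  list(sim = sim, table = d$table, meta = d$meta, model = model, corr = corr)
}

test_that("an identity correction yields p = 1 and zero improvement", {
  f <- small_report_fixture()
  rep <- correction_report(f$table, f$table, model = f$model, meta = f$meta)
  expect_true(all(rep$per_cluster$p_metadata == 1))
  expect_equal(rep$per_feature$cv_original,
               rep$per_feature$cv_corrected_metadata)
})

test_that("correction reports show the expected improvement structure", {
  f <- small_report_fixture()
  rep <- correction_report(f$table, f$corr, model = f$model, meta = f$meta)
  g <- glance(rep)
  expect_lt(g$mean_cv_metadata, g$mean_cv_original)
  # strongly drifting clusters flagged highly significant
  drifting <- vapply(f$model$clusters, function(cl)
    max(abs(log(cl$cluster_profile))) > 0.2, logical(1))
  ids <- vapply(f$model$clusters, `[[`, integer(1), "cluster_id")[drifting]
  pc <- rep$per_cluster[rep$per_cluster$cluster_id %in% ids, ]
  expect_true(all(pc$p_metadata < 0.001))
  # aggregation consistency at 1e-12
  for (i in seq_len(nrow(rep$per_cluster))) {
    members <- f$model$clusters[[i]]$member_features
    pf <- rep$per_feature[rep$per_feature$feature_id %in% members, ]
    expect_equal(rep$per_cluster$cv_original[i], mean(pf$cv_original),
                 tolerance = 1e-12)
  }
  tot <- rep$global[rep$global$group == "total", ]
  expect_equal(tot$cv_original, mean(rep$per_feature$cv_original),
               tolerance = 1e-12)
})

test_that("single-feature clusters are reported without a p-value", {
  times <- c(1, 3, 8, 24, 36)
  meta <- tidyr::expand_grid(subject_id = paste0("p", 1:4), time_h = times)
  meta <- tibble::tibble(sample_id = sprintf("s%02d", seq_len(nrow(meta))),
                         subject_id = meta$subject_id, time_h = meta$time_h,
                         temperature_c = 22)
  up <- 2^((times - 1) / 35)
  x <- matrix(1, nrow(meta), 5,
              dimnames = list(meta$sample_id, paste0("f", 1:5)))
  for (i in seq_len(nrow(meta))) {
    ti <- match(meta$time_h[i], times)
    x[i, 1:4] <- up[ti]
    x[i, 5] <- rev(up)[ti] * 2
  }
  model <- fit_drift_model(toy_table(x), meta, k_range = 2:3)
  sizes <- lengths(lapply(model$clusters, `[[`, "member_features"))
  expect_true(any(sizes == 1))
  corr <- suppressMessages(correct_drift(toy_table(x), model, times = meta))
  rep <- correction_report(toy_table(x), corr, model = model, meta = meta)
  expect_true(any(is.na(rep$per_cluster$p_metadata[sizes == 1])))
})

test_that("deviation surfaces match forced values and brute-force quantiles", {
  f <- small_report_fixture()
  # noiseless flat data: all percentiles zero
  cfg0 <- noiseless_sim_config()
  sim0 <- simulate_handling_study(cfg0)
  d0 <- sim_at_temp(sim0, 22)
  flat_cols <- sim0$truth$features$feature_id[
    sim0$truth$features$archetype == "stable"]
  tab0 <- d0$table[, c("sample_id", flat_cols)]
  s0 <- deviation_surface(tab0, d0$meta)
  expect_true(all(abs(s0$deviation) < 1e-12))

  # forced 1.2x at t = 8 only
  tab8 <- tab0
  rows <- d0$meta$time_h == 8
  tab8[rows, -1] <- tab8[rows, -1] * 1.2
  s8 <- deviation_surface(tab8, d0$meta)
  expect_equal(s8$deviation[s8$time_h == 8], rep(0.2, 5), tolerance = 1e-12)

  # brute-force quantile oracle on real noisy data
  s <- deviation_surface(f$table, f$meta, percentile_levels = c(0.25, 0.5, 0.9))
  x <- benchdrift:::ft_matrix(f$table)
  ref <- x[f$meta$time_h == 1, , drop = FALSE]
  rownames(ref) <- f$meta$subject_id[f$meta$time_h == 1]
  for (t in unique(f$meta$time_h)) {
    sel <- f$meta$time_h == t
    devs <- as.numeric(x[sel, ] / ref[f$meta$subject_id[sel], ] - 1)
    expect_equal(s$deviation[s$time_h == t],
                 unname(quantile(devs, c(0.25, 0.5, 0.9))))
  }
  # monotone in percentile level within each time
  for (t in unique(s$time_h)) {
    expect_true(!is.unsorted(s$deviation[s$time_h == t]))
  }
})

test_that("group comparisons detect separated predicted times", {
  set.seed(50)
  y <- c(rnorm(30, 5, 2), rnorm(30, 15, 2), rnorm(30, 27, 2))
  g <- rep(c("same day", "next day", "later"), each = 30)
  res <- compare_predicted_groups(y, g)
  expect_lt(res$p_overall, 0.001)
  expect_true(all(res$pairwise$p_adjusted < 0.001))
  expect_error(compare_predicted_groups(1:2, c("a", "b")), "2 members")
  expect_error(compare_predicted_groups(1:5, rep("a", 5)), "2 groups")
})

test_that("group comparison p-values are calibrated under the null", {
  ps <- sapply(1:40, function(s) {
    set.seed(700 + s)
    compare_predicted_groups(rnorm(60), rep(c("a", "b", "c"), 20))$p_overall
  })
  expect_gte(median(ps), 0.25)
  expect_lte(median(ps), 0.75)
})
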