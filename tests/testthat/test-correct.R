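fit_small_model <- function(seed = 2) {
  sim <- simulate_handling_study(small_sim_config(seed = seed))
  pq <- pqn_normalize(sim$table)
  d <- sim_at_temp(sim, 22, pq$normalized)
  list(sim = sim, table = d$table, meta = d$meta,
       model = fit_drift_model(d$table, d$meta))
}

test_that("correcting at the reference time is the identity", {
  f <- fit_small_model()
  out <- suppressMessages(
    correct_drift(f$table, f$model, times = rep(1, nrow(f$table))))
  expect_equal(benchdrift:::ft_matrix(out), benchdrift:::ft_matrix(f$table),
               tolerance = 1e-12)
})

test_that("a perfectly modeled feature becomes time-constant", {
  sim <- simulate_handling_study(noiseless_sim_config())
  d <- sim_at_temp(sim, 22)
  model <- fit_drift_model(d$table, d$meta)
  out <- correct_drift(d$table, model, times = d$meta)
  x <- benchdrift:::ft_matrix(out)
  for (s in unique(d$meta$subject_id)) {
    rows <- d$meta$subject_id == s
    ranges <- apply(x[rows, , drop = FALSE], 2, function(v) diff(range(v)))
    expect_lte(max(ranges / colMeans(x[rows, , drop = FALSE])), 1e-10)
  }
})

test_that("correction commutes with per-feature scaling", {
  f <- fit_small_model()
  k <- 42.5
  scaled <- f$table
  scaled[[3]] <- scaled[[3]] * k
  a <- suppressMessages(correct_drift(f$table, f$model, times = f$meta))
  b <- suppressMessages(correct_drift(scaled, f$model, times = f$meta))
  expect_equal(b[[3]], a[[3]] * k, tolerance = 1e-12)
})

test_that("correction reduces the CV of drifting features", {
  cfg <- small_sim_config(seed = 6, noise_sd = 0.05, n_subjects = 16)
  sim <- simulate_handling_study(cfg)
  pq <- pqn_normalize(sim$table)
  d <- sim_at_temp(sim, 22, pq$normalized)
  model <- fit_drift_model(d$table, d$meta)
  out <- suppressMessages(correct_drift(d$table, model, times = d$meta))
  tf <- sim$truth$features
  drifting <- tf$feature_id[tf$archetype %in% c("increase", "decrease")]
  # brute-force per-subject CV oracle
  cv_of <- function(tab) {
    x <- benchdrift:::ft_matrix(tab)[, drifting, drop = FALSE]
    sapply(drifting, function(f) {
      mean(tapply(x[, f], d$meta$subject_id,
                  function(v) sd(v) / mean(v)))
    })
  }
  improved <- cv_of(out) < cv_of(d$table)
  expect_gte(mean(improved), 0.9)
})

test_that("time handling contracts hold", {
  f <- fit_small_model()
  expect_error(correct_drift(f$table, f$model,
                             times = rep(NA_real_, nrow(f$table))),
               "missing")
  expect_error(correct_drift(f$table, f$model, times = c(1, 2)), "one time")
  expect_warning(
    suppressMessages(correct_drift(f$table, f$model,
                                   times = rep(40, nrow(f$table)))),
    "clamped")
  # feature mismatch beyond tolerance
  few <- f$table[, 1:10]
  expect_error(suppressMessages(correct_drift(few, f$model, times = f$meta)),
               "tolerance")
})

test_that("refitting on corrected data finds (almost) no drift left", {
  cfg <- small_sim_config(seed = 9, noise_sd = 0.05)
  sim <- simulate_handling_study(cfg)
  pq <- pqn_normalize(sim$table)
  d <- sim_at_temp(sim, 22, pq$normalized)
  model <- fit_drift_model(d$table, d$meta)
  out <- suppressMessages(correct_drift(d$table, model, times = d$meta))
  refit <- fit_drift_model(out, d$meta)
  for (cl in refit$clusters) {
    expect_lte(max(abs(cl$cluster_profile - 1)), 3 * 0.05)
  }
})

test_that("prediction-routed correction matches sample temperature", {
  # default archetype mix (temperature-specific kinetics included), reduced size
  cfg <- sim_config(n_subjects = 8, n_features = 120, seed = 4)
  sim <- simulate_handling_study(cfg)
  pq <- pqn_normalize(sim$table)
  rcfg <- rdcv_config(n_rep = 2, n_outer = 4, n_inner = 3, n_trees = 150,
                      seed = 17)
  temp_model <- rdcv_fit(pq$normalized, factor(sim$meta$temperature_c), rcfg,
                         subjects = sim$meta$subject_id)
  models <- list(); time_models <- list()
  for (temp in c(4, 22)) {
    d <- sim_at_temp(sim, temp, pq$normalized)
    models[[as.character(temp)]] <- fit_drift_model(d$table, d$meta)
    time_models[[as.character(temp)]] <-
      rdcv_fit(d$table, d$meta$time_h, rcfg, subjects = d$meta$subject_id)
  }
  d22 <- sim_at_temp(sim, 22, pq$normalized)
  res <- suppressMessages(
    correct_predicted(d22$table, temp_model, time_models, models))
  expect_gte(mean(res$provenance$pred_temperature == "22"), 0.95)
  expect_equal(nrow(res$corrected), nrow(d22$table))

  # single sample in, single row out
  one <- suppressMessages(
    correct_predicted(d22$table[1, ], temp_model, time_models, models))
  expect_equal(nrow(one$corrected), 1L)
})
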