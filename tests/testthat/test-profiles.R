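make_meta <- function(subjects, times, temp = 22) {
  grid <- expand.grid(subject_id = subjects, time_h = times,
                      stringsAsFactors = FALSE)
  tibble::tibble(sample_id = sprintf("s%02d", seq_len(nrow(grid))),
                 subject_id = grid$subject_id, time_h = grid$time_h,
                 temperature_c = temp)
}

test_that("profiles capture fold-change kinetics relative to the reference", {
  meta <- make_meta(c("p1", "p2"), c(1, 3, 8))
  # f_const: constant; f_lin: doubles identically in both subjects
  lin <- c(1, 2, 4)
  x <- matrix(0, nrow(meta), 2, dimnames = list(meta$sample_id,
                                                c("f_const", "f_lin")))
  for (i in seq_len(nrow(meta))) {
    base <- if (meta$subject_id[i] == "p1") 10 else 7
    x[i, "f_const"] <- base
    x[i, "f_lin"] <- base * lin[match(meta$time_h[i], c(1, 3, 8))]
  }
  pr <- compute_drift_profiles(toy_table(x), meta)
  const <- pr[pr$feature_id == "f_const", ]
  expect_equal(unname(const$mean_profile[[1]]), c(1, 1, 1))
  expect_equal(const$reproducibility, 0)  # flat: zero variance handled as 0
  linr <- pr[pr$feature_id == "f_lin", ]
  expect_equal(unname(linr$mean_profile[[1]]), lin)
  expect_equal(linr$reproducibility, 1)
})

test_that("hand-computed fold-changes and correlation match", {
  meta <- make_meta(c("p1", "p2"), c(1, 3, 8))
  vals <- c(p1 = NA, p2 = NA)
  x <- matrix(NA_real_, nrow(meta), 1, dimnames = list(meta$sample_id, "f"))
  by_subj <- list(p1 = c(2, 3, 8), p2 = c(5, 20, 30))
  for (i in seq_len(nrow(meta))) {
    x[i, 1] <- by_subj[[meta$subject_id[i]]][match(meta$time_h[i], c(1, 3, 8))]
  }
  pr <- compute_drift_profiles(toy_table(x), meta)
  fc1 <- c(1, 3 / 2, 4)     # hand: 2,3,8 over 2
  fc2 <- c(1, 4, 6)         # hand: 5,20,30 over 5
  expect_equal(unname(pr$per_subject[[1]]["p1", ]), fc1)
  expect_equal(unname(pr$per_subject[[1]]["p2", ]), fc2)
  expect_equal(unname(pr$mean_profile[[1]]), (fc1 + fc2) / 2)
  expect_equal(pr$reproducibility, cor(log(fc1), log(fc2)))
})

test_that("reference-time problems are flagged or rejected", {
  meta <- make_meta(c("p1", "p2"), c(1, 3, 8))
  x <- matrix(1, nrow(meta), 2, dimnames = list(meta$sample_id, c("fa", "fb")))
  x[meta$subject_id == "p1" & meta$time_h == 1, "fb"] <- 0
  pr <- compute_drift_profiles(toy_table(x), meta)
  expect_equal(attr(pr, "flagged"), "fb")
  expect_equal(pr$feature_id, "fa")

  meta2 <- meta[!(meta$subject_id == "p2" & meta$time_h == 1), ]
  x2 <- x[meta2$sample_id, , drop = FALSE]
  expect_error(compute_drift_profiles(toy_table(x2), meta2),
               "missing reference-time")

  meta3 <- meta
  meta3$temperature_c[1] <- 4
  expect_error(compute_drift_profiles(toy_table(x), meta3),
               "single temperature")
})

test_that("irreproducibility filtering keeps flat-but-noisy features", {
  sim <- simulate_handling_study(small_sim_config(seed = 21, n_subjects = 16))
  pq <- pqn_normalize(sim$table)
  d <- sim_at_temp(sim, 22, pq$normalized)
  pr <- compute_drift_profiles(d$table, d$meta)

  # vacuous threshold excludes nothing
  all_kept <- filter_irreproducible(pr, threshold = -1)
  expect_equal(nrow(all_kept$excluded), 0L)

  filt <- filter_irreproducible(pr)
  tf <- sim$truth$features
  excl_arch <- tf$archetype[match(filt$excluded$feature_id, tf$feature_id)]
  # features with subject-wise random drift sign have no between-subject
  # agreement; reproducible drifting archetypes are near-perfectly correlated
  irr_ids <- tf$feature_id[tf$archetype == "irreproducible"]
  expect_gte(mean(pr$reproducibility[pr$feature_id %in% irr_ids] < 0.5), 0.75)
  expect_false(any(excl_arch %in% c("increase", "decrease")))
  # exclusion requires both low reproducibility and visible drift
  expect_true(all(pr$reproducibility[pr$feature_id %in%
                                       filt$excluded$feature_id] < 0.5))
  # partition of the profile set
  expect_setequal(c(filt$kept$feature_id, filt$excluded$feature_id),
                  pr$feature_id)
})

test_that("identical kinetics across subjects exclude nothing", {
  cfg <- noiseless_sim_config()
  sim <- simulate_handling_study(cfg)
  d <- sim_at_temp(sim, 22)
  pr <- compute_drift_profiles(d$table, d$meta)
  filt <- filter_irreproducible(pr)
  expect_equal(nrow(filt$excluded), 0L)
})
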