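sep_class_data <- function(n = 40, p = 60, shift = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n,
              dimnames = list(paste0("s", seq_len(n)), paste0("f", seq_len(p))))
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "b", 1:5] <- x[y == "b", 1:5] + shift
  list(x = x, y = y)
}

# latent-factor regression data: 5 informative features each track the
# outcome (the structure drift features have with respect to time)
lin_reg_data <- function(n = 80, p = 200, noise = 0.1, seed = 2) {
  set.seed(seed)
  y <- rnorm(n)
  x <- matrix(rnorm(n * p), n,
              dimnames = list(paste0("s", seq_len(n)), paste0("f", seq_len(p))))
  x[, 1:5] <- y + matrix(rnorm(n * 5, 0, noise), n, 5)
  list(x = x, y = as.numeric(y + rnorm(n, 0, noise * sd(y))))
}

fast_cfg <- function(seed = 3) {
  rdcv_config(n_rep = 1, n_outer = 4, n_inner = 3, n_trees = 80, seed = seed)
}

test_that("well-separated classes are classified without error", {
  d <- sep_class_data()
  m <- rdcv_fit(d$x, d$y, fast_cfg())
  expect_equal(m$performance$n_misclassified, 0)
  # the consensus set contains informative variables only (parsimony can
  # stop at fewer than all five, since two already separate the classes)
  expect_true(all(m$selected_variables$mid %in% paste0("f", 1:5)))
})

test_that("a linear signal is regressed with high cross-validated Q2", {
  d <- lin_reg_data()
  m <- rdcv_fit(d$x, d$y, rdcv_config(n_rep = 2, n_outer = 4, n_inner = 3,
                                      n_trees = 150, seed = 5))
  expect_gte(m$performance$Q2, 0.8)
  expect_gte(m$performance$R2, m$performance$Q2)  # PRESS >= fit residuals
})

test_that("degenerate outcomes are rejected", {
  d <- sep_class_data()
  expect_error(rdcv_fit(d$x, factor(rep("a", nrow(d$x))), fast_cfg()),
               "degenerate")
  expect_error(rdcv_fit(d$x, rep(3.3, nrow(d$x)), fast_cfg()), "degenerate")
  y_small <- factor(c(rep("a", 37), rep("b", 3)))
  expect_error(rdcv_fit(d$x, y_small, rdcv_config(n_outer = 6, seed = 1)),
               "n_outer")
})

test_that("identical seed, config and data give identical models", {
  d <- sep_class_data(seed = 7)
  m1 <- rdcv_fit(d$x, d$y, fast_cfg(seed = 11))
  m2 <- rdcv_fit(d$x, d$y, fast_cfg(seed = 11))
  expect_identical(m1$selected_variables, m2$selected_variables)
  expect_identical(m1$per_sample, m2$per_sample)
  # a different seed changes folds, hence continuous predictions
  dr <- lin_reg_data(n = 40, p = 30, seed = 8)
  r1 <- rdcv_fit(dr$x, dr$y, fast_cfg(seed = 11))
  r2 <- rdcv_fit(dr$x, dr$y, fast_cfg(seed = 12))
  expect_false(identical(r1$per_sample$prediction, r2$per_sample$prediction))
})

test_that("permuted outcomes cannot be predicted (leakage guard)", {
  for (s in 1:3) {
    d <- lin_reg_data(n = 40, p = 30, seed = 100 + s)
    set.seed(s); y_perm <- sample(d$y)
    m <- rdcv_fit(d$x, y_perm, fast_cfg(seed = s))
    expect_lte(m$performance$Q2, 0.1)
  }
  dc <- sep_class_data(n = 40, p = 30, seed = 200)
  set.seed(9); y_perm <- sample(dc$y)
  mc <- rdcv_fit(dc$x, y_perm, fast_cfg(seed = 9))
  expect_lte(abs(mc$performance$accuracy - 0.5), 0.1 + 1e-9)
})

test_that("separation never hurts accuracy (monotone sanity)", {
  accs <- sapply(c(0.5, 2, 6), function(shift) {
    d <- sep_class_data(n = 40, p = 30, shift = shift, seed = 33)
    rdcv_fit(d$x, d$y, fast_cfg(seed = 21))$performance$accuracy
  })
  expect_true(all(diff(accs) >= 0))
})

test_that("external prediction generalizes and handles edge inputs", {
  d <- sep_class_data(seed = 15)
  m <- rdcv_fit(d$x, d$y, fast_cfg(seed = 15))
  fresh <- sep_class_data(seed = 16)
  pred <- predict(m, fresh$x)
  acc <- mean(pred$prediction == as.character(fresh$y))
  expect_lte(abs(acc - m$performance$accuracy), 0.05)

  one <- predict(m, fresh$x[1, , drop = FALSE])
  expect_equal(nrow(one), 1L)

  const <- fresh$x; const[] <- 1
  expect_warning(predict(m, const), "constant")

  missing_cols <- fresh$x[, setdiff(colnames(fresh$x),
                                    m$selected_variables$mid[1]),
                          drop = FALSE]
  expect_error(predict(m, missing_cols), "lacks required")
})

test_that("subject-aware folds keep a subject's samples together", {
  subj <- rep(paste0("p", 1:8), each = 5)
  y <- rnorm(40) + rep(1:8, each = 5)
  folds <- benchdrift:::make_folds(y, 4, subjects = subj, seed = 2)
  expect_true(all(tapply(folds, subj, function(f) length(unique(f))) == 1))
  # stratification: classification folds carry both classes
  yc <- factor(rep(c("a", "b"), 20))
  f2 <- benchdrift:::make_folds(yc, 4, seed = 3)
  expect_true(all(table(f2, yc) == 5))
})
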