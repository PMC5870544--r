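#' Configuration for repeated double cross-validation
#'
#' @param n_rep Number of repetitions of the double-CV loop (default 20).
#' @param n_outer Outer segments per repetition (default 6).
#' @param n_inner Inner segments for variable selection (default
#'   `n_outer - 1`).
#' @param var_ratio Fraction of variables kept at each recursive elimination
#'   step (default 0.75).
#' @param n_trees Trees per random forest (default 500).
#' @param fitness Inner-loop fitness: `"auto"` (misclassification count for
#'   classification, RMSEP for regression), `"misclassification"` or
#'   `"rmsep"`.
#' @param seed Integer seed; every random draw in the procedure derives from
#'   it, so identical seed + data + config reproduce results exactly.
#' @return An `rdcv_config` list.
#' @export
rdcv_config <- function(n_rep = 20, n_outer = 6, n_inner = n_outer - 1,
                        var_ratio = 0.75, n_trees = 500,
                        fitness = c("auto", "misclassification", "rmsep"),
                        seed = 1) {
  fitness <- match.arg(fitness)
  stopifnot(n_rep >= 1, n_outer >= 2, n_inner >= 2,
            var_ratio > 0, var_ratio < 1, n_trees >= 1)
  structure(list(n_rep = as.integer(n_rep), n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner), var_ratio = var_ratio,
                 n_trees = as.integer(n_trees), fitness = fitness,
                 seed = as.integer(seed)),
            class = "rdcv_config")
}

# Snapshot the global RNG state; returns a restorer function.
preserve_rng <- function() {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  function() {
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# Evaluate `code` under a temporary RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Stratified fold assignment. Classification: per-class round-robin after a
# shuffle. Regression: samples sorted by outcome (random tie-break), fold
# labels permuted within consecutive blocks, so every fold spans the outcome
# range. With `subjects`, all samples of a subject land in the same fold
# (repeated-measures leakage guard); subjects are stratified by their
# majority class / mean outcome.
make_folds <- function(outcome, n_folds, subjects = NULL, seed = 1) {
  with_seed(seed, {
    if (!is.null(subjects)) {
      us <- unique(subjects)
      uo <- if (is.factor(outcome)) {
        factor(vapply(us, function(s) {
          names(which.max(table(outcome[subjects == s])))
        }, character(1)), levels = levels(outcome))
      } else {
        vapply(us, function(s) mean(outcome[subjects == s]), numeric(1))
      }
      uf <- make_folds(uo, n_folds, subjects = NULL,
                       seed = sample.int(2^30, 1))
      return(uf[match(subjects, us)])
    }
    n <- length(outcome)
    folds <- integer(n)
    if (is.factor(outcome)) {
      for (cl in levels(outcome)) {
        idx <- sample(which(outcome == cl))
        folds[idx] <- rep(sample.int(n_folds), length.out = length(idx))
      }
    } else {
      ord <- order(outcome + runif(n) * 1e-9 * max(1, sd(outcome)))
      pos <- 0L
      while (pos < n) {
        block <- ord[seq(pos + 1L, min(pos + n_folds, n))]
        folds[block] <- sample.int(n_folds)[seq_along(block)]
        pos <- pos + n_folds
      }
    }
    folds
  })
}

# Recursive-elimination variable-count sequence p, ceil(r*p), ..., 2.
nv_sequence <- function(p, ratio) {
  out <- integer(0)
  n <- p
  while (n > 2L) {
    out <- c(out, n)
    n <- min(n - 1L, as.integer(ceiling(ratio * n)))
  }
  c(out, 2L)
}

fit_forest <- function(x, y, n_trees, seed, probability = FALSE,
                       importance = "none") {
  ranger::ranger(x = as.data.frame(x), y = y, num.trees = n_trees,
                 seed = seed, num.threads = 1, probability = probability,
                 importance = importance, verbose = FALSE)
}

predict_forest <- function(fit, x) {
  # an explicit seed keeps ranger's predict from consuming the R RNG stream
  stats::predict(fit, data = as.data.frame(x), num.threads = 1,
                 seed = 1, verbose = FALSE)$predictions
}

fit_consensus_forest <- function(x, outcome, vars, config, task) {
  fit_forest(x[, vars, drop = FALSE], outcome, config$n_trees,
             seed = config$seed, probability = (task == "classification"))
}

inner_fitness <- function(pred, truth, task) {
  if (task == "classification") sum(pred != truth) else
    sqrt(mean((pred - truth)^2))
}

#' Random-forest prediction in repeated double cross-validation
#'
#' Fits a random-forest classifier (factor outcome) or regressor (numeric
#' outcome) inside a repeated double cross-validation scheme with recursive
#' variable elimination. Per repetition, samples are split into `n_outer`
#' stratified outer segments; for each outer segment, inner `n_inner`-fold
#' CV on the remaining samples ranks variables by forest importance and
#' recursively keeps the top `var_ratio` fraction down to 2 variables; the
#' variable count minimizing inner fitness wins, and the held-out outer
#' segment is predicted at that count. Variable ranking never sees the outer
#' segment ("unbiased variable selection"); per-sample predictions are
#' purely cross-validated.
#'
#' @param table Feature tibble or numeric matrix.
#' @param outcome Factor (classification) or numeric vector (regression),
#'   one value per sample.
#' @param config An [rdcv_config()].
#' @param subjects Optional subject ids (one per sample): all samples of a
#'   subject are kept in the same fold.
#' @return An `rdcv_model` with per-sample cross-validated predictions,
#'   performance (`misclass_rate` or `R2`/`Q2`/`RMSEP`), consensus variable
#'   sets of minimal/middle/maximal size, and a consensus forest refit on
#'   the full data for external prediction.
#' @export
rdcv_fit <- function(table, outcome, config = rdcv_config(), subjects = NULL) {
  restore <- preserve_rng()
  on.exit(restore())
  x <- if (is.matrix(table)) table else ft_matrix(table)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  n <- nrow(x); p <- ncol(x)
  if (length(outcome) != n) abort("one outcome value per sample required")
  if (p < 2L) abort("need at least 2 features")

  if (is.factor(outcome) || is.character(outcome)) {
    task <- "classification"
    outcome <- factor(outcome)
    tab <- table(outcome)
    if (nlevels(outcome) < 2L || any(tab == 0)) abort("degenerate outcome")
    if (any(tab < config$n_outer)) {
      abort("n_outer exceeds the size of a class")
    }
  } else {
    task <- "regression"
    outcome <- as.numeric(outcome)
    if (sd(outcome) == 0) abort("degenerate outcome")
    if (length(unique(outcome)) < config$n_outer) {
      abort("need at least n_outer distinct outcome values")
    }
  }

  nv_seq <- nv_sequence(p, config$var_ratio)
  picks <- integer(0)
  freq <- setNames(numeric(p), colnames(x))
  rank_sum <- setNames(numeric(p), colnames(x))
  rank_n <- setNames(numeric(p), colnames(x))
  if (task == "classification") {
    prob_sum <- matrix(0, n, nlevels(outcome),
                       dimnames = list(rownames(x), levels(outcome)))
    pred_n <- numeric(n)
  } else {
    pred_sum <- numeric(n)
    pred_n <- numeric(n)
  }

  for (r in seq_len(config$n_rep)) {
    folds <- make_folds(outcome, config$n_outer, subjects = subjects,
                        seed = sub_seed(config$seed, 11, r))
    for (o in seq_len(config$n_outer)) {
      test <- which(folds == o)
      train <- which(folds != o)
      if (length(test) == 0L) next
      inner <- make_folds(outcome[train], config$n_inner,
                          subjects = subjects[train],
                          seed = sub_seed(config$seed, 13, r, o))
      vars <- colnames(x)  # current ranking, best first
      fitnesses <- setNames(rep(NA_real_, length(nv_seq)), nv_seq)
      var_sets <- vector("list", length(nv_seq))
      for (si in seq_along(nv_seq)) {
        nv <- nv_seq[si]
        vars_nv <- vars[seq_len(nv)]
        var_sets[[si]] <- vars_nv
        imp <- setNames(numeric(nv), vars_nv)
        pred_all <- truth_all <- NULL
        for (iv in seq_len(config$n_inner)) {
          itr <- train[inner != iv]
          iva <- train[inner == iv]
          if (length(iva) == 0L || length(itr) < 2L) next
          fit <- fit_forest(x[itr, vars_nv, drop = FALSE], outcome[itr],
                            config$n_trees,
                            seed = sub_seed(config$seed, 17, r, o, si, iv),
                            importance = "impurity")
          pr <- predict_forest(fit, x[iva, vars_nv, drop = FALSE])
          pred_all <- c(pred_all, as.character(pr))
          truth_all <- c(truth_all, as.character(outcome[iva]))
          imp <- imp + fit$variable.importance
        }
        if (task == "classification") {
          fitnesses[si] <- sum(pred_all != truth_all)
        } else {
          fitnesses[si] <- sqrt(mean((as.numeric(pred_all) -
                                        as.numeric(truth_all))^2))
        }
        vars <- names(sort(imp, decreasing = TRUE))
      }
      best_si <- max(which(fitnesses == min(fitnesses)))  # smallest nv on ties
      best_vars <- var_sets[[best_si]]
      picks <- c(picks, length(best_vars))
      freq[best_vars] <- freq[best_vars] + 1
      rank_sum[best_vars] <- rank_sum[best_vars] + seq_along(best_vars)
      rank_n[best_vars] <- rank_n[best_vars] + 1

      fit <- fit_forest(x[train, best_vars, drop = FALSE], outcome[train],
                        config$n_trees,
                        seed = sub_seed(config$seed, 19, r, o),
                        probability = (task == "classification"))
      pr <- predict_forest(fit, x[test, best_vars, drop = FALSE])
      if (task == "classification") {
        prob_sum[test, colnames(pr)] <- prob_sum[test, colnames(pr)] + pr
        pred_n[test] <- pred_n[test] + 1
      } else {
        pred_sum[test] <- pred_sum[test] + pr
        pred_n[test] <- pred_n[test] + 1
      }
    }
  }

  # consensus variable counts and ranking
  var_counts <- list(min = min(picks),
                     mid = as.integer(round(exp(mean(log(picks))))),
                     max = max(picks))
  mean_rank <- ifelse(rank_n > 0, rank_sum / pmax(rank_n, 1), Inf)
  ranking <- names(freq)[order(-freq, mean_rank, names(freq))]
  selected <- list(min = ranking[seq_len(var_counts$min)],
                   mid = ranking[seq_len(var_counts$mid)],
                   max = ranking[seq_len(var_counts$max)])

  if (task == "classification") {
    probs <- prob_sum / pmax(pred_n, 1)
    # ties broken toward the majority training class
    maj_order <- order(-as.numeric(table(outcome)[levels(outcome)]))
    pcls <- apply(probs[, levels(outcome)[maj_order], drop = FALSE], 1,
                  function(z) levels(outcome)[maj_order][which.max(z)])
    per_sample <- dplyr::bind_cols(
      tibble(sample_id = rownames(x),
             observed = as.character(outcome),
             prediction = pcls),
      as_tibble(probs, .name_repair = ~ paste0("vote_", .x))
    )
    miss <- sum(pcls != as.character(outcome))
    performance <- list(n_misclassified = miss,
                        misclass_rate = miss / n,
                        accuracy = 1 - miss / n)
  } else {
    preds <- pred_sum / pmax(pred_n, 1)
    per_sample <- tibble(sample_id = rownames(x), observed = outcome,
                         prediction = preds)
    press <- sum((preds - outcome)^2)
    tss <- sum((outcome - mean(outcome))^2)
    performance <- list(Q2 = 1 - press / tss,
                        RMSEP = sqrt(press / n))
  }

  ens <- fit_consensus_forest(x, outcome, selected$mid, config, task)
  if (task == "regression") {
    fitted <- predict_forest(ens, x[, selected$mid, drop = FALSE])
    performance$R2 <- 1 - sum((fitted - outcome)^2) /
      sum((outcome - mean(outcome))^2)
  }

  structure(list(task = task, config = config,
                 selected_variables = selected, var_counts = var_counts,
                 var_picks = picks, outcome = outcome, train_x = x,
                 per_sample = per_sample, performance = performance,
                 fitted_ensemble = ens),
            class = "rdcv_model")
}

#' Predict handling conditions for new samples
#'
#' Applies the consensus forest (refit on the full training data at the
#' middle consensus variable count) to new samples. Classification returns
#' the majority vote with ties broken toward the majority training class;
#' regression returns the ensemble mean.
#'
#' @param object An `rdcv_model`.
#' @param newdata Feature tibble or matrix containing the model's selected
#'   variables.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `prediction`, and vote fractions per
#'   class for classification.
#' @export
predict.rdcv_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else ft_matrix(newdata)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  vars <- object$selected_variables$mid
  missing <- setdiff(vars, colnames(x))
  if (length(missing)) {
    abort(paste0("newdata lacks required feature(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  xm <- x[, vars, drop = FALSE]
  if (nrow(xm) > 1L && all(apply(xm, 2, sd) == 0)) {
    warn("all selected features constant in newdata; predictions fall back to training structure")
  }
  pr <- predict_forest(object$fitted_ensemble, xm)
  if (object$task == "classification") {
    lv <- levels(object$outcome)
    maj_order <- order(-as.numeric(table(object$outcome)[lv]))
    pcls <- apply(pr[, lv[maj_order], drop = FALSE], 1,
                  function(z) lv[maj_order][which.max(z)])
    dplyr::bind_cols(
      tibble(sample_id = rownames(x), prediction = pcls),
      as_tibble(pr, .name_repair = ~ paste0("vote_", .x))
    )
  } else {
    tibble(sample_id = rownames(x), prediction = as.numeric(pr))
  }
}

#' @export
print.rdcv_model <- function(x, ...) {
  cat("<rdcv_model> ", x$task, ", ", nrow(x$train_x), " samples x ",
      ncol(x$train_x), " features\n", sep = "")
  cat("  consensus variables (min/mid/max): ", x$var_counts$min, "/",
      x$var_counts$mid, "/", x$var_counts$max, "\n", sep = "")
  if (x$task == "classification") {
    cat("  cross-validated misclassification: ",
        x$performance$n_misclassified, " (",
        signif(100 * x$performance$misclass_rate, 3), "%)\n", sep = "")
  } else {
    cat("  Q2 = ", signif(x$performance$Q2, 3), ", R2 = ",
        signif(x$performance$R2, 3), ", RMSEP = ",
        signif(x$performance$RMSEP, 3), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rdcv_model <- function(x, ...) x$per_sample

#' @exportS3Method generics::glance
glance.rdcv_model <- function(x, ...) {
  as_tibble(c(list(task = x$task,
                   n_samples = nrow(x$train_x),
                   n_features = ncol(x$train_x),
                   n_selected = x$var_counts$mid),
              x$performance))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rdcv_model <- function(object, ...) {
  ps <- object$per_sample
  if (object$task == "regression") {
    ggplot2::ggplot(ps, ggplot2::aes(x = .data$observed,
                                     y = .data$prediction)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
      ggplot2::geom_jitter(width = 0.3, height = 0, alpha = 0.6) +
      ggplot2::labs(x = "actual pre-centrifugation time (h)",
                    y = "cross-validated prediction (h)",
                    title = sprintf("rdCV regression, Q2 = %.2f",
                                    object$performance$Q2))
  } else {
    vote_cols <- grep("^vote_", names(ps), value = TRUE)
    long <- tidyr::pivot_longer(ps, dplyr::all_of(vote_cols),
                                names_to = "class", values_to = "vote")
    long$class <- sub("^vote_", "", long$class)
    ggplot2::ggplot(long, ggplot2::aes(x = .data$observed, y = .data$vote,
                                       fill = .data$class)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "actual class", y = "cross-validated vote fraction",
                    title = sprintf("rdCV classification, accuracy = %.1f%%",
                                    100 * object$performance$accuracy))
  }
}
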