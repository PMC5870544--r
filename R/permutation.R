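#' Permutation test of an rdCV model's fitness
#'
#' Rebuilds the full repeated double cross-validation procedure on
#' outcome-permuted data `n_perm` times, producing a null distribution of
#' the fitness measure (misclassification count for classification, RMSEP
#' for regression; lower is better). Reports the empirical p-value
#' `(#{null <= observed} + 1) / (n_perm + 1)` and, because a genuinely
#' strong model can beat every permutation (floor `1/(n_perm+1)`), a
#' parametric one-sided tail probability from a Student-t fit to the
#' standardized null.
#'
#' Null refits may use fewer repetitions than the observed model
#' (`perm_n_rep`, default 5) to keep the test tractable; the reduction is
#' recorded in the result.
#'
#' @param table Feature tibble or matrix.
#' @param outcome Factor or numeric outcome.
#' @param config [rdcv_config()] for the observed model.
#' @param n_perm Number of permutations (default 100; must be >= 2).
#' @param perm_n_rep Repetitions per null refit (default `min(n_rep, 5)`).
#' @param subjects Optional subject ids (see [rdcv_fit()]).
#' @param model Optional pre-fitted observed model (skips one rdCV run).
#' @return A `perm_test` list: `observed`, `null_values`, `p_empirical`,
#'   `p_parametric`, `n_perm`, `perm_n_rep`, `fitness`.
#' @export
rdcv_permutation <- function(table, outcome, config = rdcv_config(),
                             n_perm = 100,
                             perm_n_rep = min(config$n_rep, 5L),
                             subjects = NULL, model = NULL) {
  if (n_perm < 2) abort("n_perm must be >= 2")
  x <- if (is.matrix(table)) table else ft_matrix(table)
  if (is.null(model)) model <- rdcv_fit(x, outcome, config, subjects)
  observed <- model_fitness(model)
  null_cfg <- config
  null_cfg$n_rep <- as.integer(perm_n_rep)
  null_values <- vapply(seq_len(n_perm), function(b) {
    perm <- with_seed(sub_seed(config$seed, 101, b),
                      sample(seq_along(outcome)))
    null_cfg_b <- null_cfg
    null_cfg_b$seed <- sub_seed(config$seed, 103, b)
    m <- rdcv_fit(x, outcome[perm], null_cfg_b,
                  subjects = subjects)
    model_fitness(m)
  }, numeric(1))
  p_emp <- (sum(null_values <= observed) + 1) / (n_perm + 1)
  z <- (observed - mean(null_values)) / sd(null_values)
  p_par <- pt(z, df = n_perm - 1)
  structure(list(observed = observed, null_values = null_values,
                 p_empirical = p_emp, p_parametric = p_par,
                 n_perm = n_perm, perm_n_rep = perm_n_rep,
                 fitness = if (model$task == "classification")
                   "misclassification" else "rmsep",
                 task = model$task, model = model),
            class = "perm_test")
}

model_fitness <- function(model) {
  if (model$task == "classification") {
    model$performance$n_misclassified
  } else {
    model$performance$RMSEP
  }
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$task, " fitness (", x$fitness, "): observed ",
      signif(x$observed, 4), "\n", sep = "")
  cat("  null (n = ", x$n_perm, ", ", x$perm_n_rep, " rep each): mean ",
      signif(mean(x$null_values), 4), "\n", sep = "")
  cat("  p_empirical = ", signif(x$p_empirical, 4),
      ", p_parametric = ", format(x$p_parametric, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble(permutation = seq_len(x$n_perm), null_fitness = x$null_values)
}

#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) {
  tibble(task = x$task, fitness = x$fitness, observed = x$observed,
         null_mean = mean(x$null_values), null_sd = sd(x$null_values),
         n_perm = x$n_perm, p_empirical = x$p_empirical,
         p_parametric = x$p_parametric)
}

#' @exportS3Method ggplot2::autoplot
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_fitness)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = paste0("null ", object$fitness),
                  y = "permutations",
                  title = sprintf("Permutation null (p_emp = %.3g)",
                                  object$p_empirical))
}
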