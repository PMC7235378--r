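# broom-style tidiers for fitted objects.

#' Tidy generic
#'
#' One row per estimated quantity; re-exported broom convention.
#' @param x object to tidy.
#' @param ... method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Glance generic
#'
#' One-row model summary; re-exported broom convention.
#' @param x object to summarize.
#' @param ... method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_acc), accuracy = x$fold_acc)
}

#' @rdname glance
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    mean_acc = x$mean_acc, ci_lo = x$ci95[1], ci_hi = x$ci95[2],
    t = x$t_stat, df = x$df, p_value = x$p_value, n = x$n, seed = x$seed,
    folds = x$hyperparameters$folds, cost = x$hyperparameters$cost,
    gamma = x$hyperparameters$gamma
  )
}

#' @rdname tidy
#' @export
tidy.mlr_fit <- function(x, ...) {
  tibble::tibble(
    term = x$predictors,
    estimate = unname(x$coefficients[-1]),
    std_beta = unname(x$std_betas),
    std_error = unname(x$std_errors),
    std_beta_se = unname(x$std_beta_se),
    p_value = unname(x$p_values)
  )
}

#' @rdname glance
#' @export
glance.mlr_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, r2_adj = x$r2_adj, aic = x$aic, n = x$n,
                 n_predictors = length(x$predictors), rss = x$rss)
}
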