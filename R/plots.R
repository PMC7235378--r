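# ggplot2 visualisations for fitted result types.

#' Subset-selection membership plot
#'
#' One horizontal line per model (top models of each size, sizes stacked
#' bottom-to-top); bars mark the predictors included in the model, shaded
#' by the model's adjusted R-squared.
#'
#' @param object a [best_subsets()] report.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.subset_report <- function(object, ...) {
  preds <- attr(object, "predictors")
  df <- tidyr::pivot_longer(
    dplyr::mutate(object,
                  model = paste0("k", .data$size, "_r", .data$rank),
                  row = dplyr::row_number()),
    cols = dplyr::all_of(paste0("in_", preds)),
    names_to = "predictor", values_to = "member"
  )
  df$predictor <- sub("^in_", "", df$predictor)
  df <- df[df$member == 1, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$predictor, levels = preds),
    y = stats::reorder(.data$model, .data$row),
    fill = .data$r2_adj
  )) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(low = "grey85", high = "black",
                                 name = expression(R[adj]^2)) +
    ggplot2::labs(x = NULL, y = "model (size, rank)",
                  title = paste("Best subsets for",
                                attr(object, "response"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' Fold-accuracy plot for a cross-validation result
#'
#' @param object a [cv_svm_accuracy()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$mean_acc, colour = "steelblue") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ci95[1], ymax = object$ci95[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(y = "fold accuracy",
                  title = sprintf("Mean accuracy %.1f%% (chance 50%%)",
                                  100 * object$mean_acc)) +
    ggplot2::theme_minimal()
}

#' Standardized-coefficient plot for a regression fit
#'
#' @param object an [fit_mlr()] result.
#' @param alpha significance threshold used to colour coefficients.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mlr_fit <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$p_value < alpha
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$term, .data$std_beta),
    y = .data$std_beta, fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = expression(beta[i]),
                  title = sprintf("%s: R2_adj = %.3f", object$response,
                                  object$r2_adj)) +
    ggplot2::theme_minimal()
}
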