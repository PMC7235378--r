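#' Tercile high/low labelling of rated images
#'
#' Ranks images by a rating term and bins them into three equally sized
#' clusters; the lowest and highest thirds become the binary classes and
#' the intermediate third is discarded. Ties are broken by stable
#' (rating, id) order. The labelling is flagged degenerate when more than
#' 5% of the labelled items share a boundary rating value (or all ratings
#' are equal).
#'
#' @param ratings a ratings tibble (see [read_ratings()]).
#' @param term name of the rating column to split on.
#' @return A tibble with columns `id`, `rating`, `class`
#'   (factor low/mid/high); attributes `term` and `degenerate`.
#' @export
tercile_split <- function(ratings, term) {
  stopifnot(is.data.frame(ratings), "id" %in% names(ratings))
  if (!term %in% names(ratings)) stop("no rating term '", term, "' in table", call. = FALSE)
  df <- tibble::tibble(id = as.character(ratings$id), rating = ratings[[term]])
  df <- df[!is.na(df$rating), ]
  n <- nrow(df)
  if (n < 30) stop("tercile split needs at least 30 rated images, got ", n, call. = FALSE)
  df <- df[order(df$rating, df$id), ]
  k <- n %/% 3L
  cls <- rep("mid", n)
  cls[seq_len(k)] <- "low"
  cls[seq.int(n - k + 1L, n)] <- "high"
  df$class <- factor(cls, levels = c("low", "mid", "high"))
  lo_b <- df$rating[k]; hi_b <- df$rating[n - k + 1L]
  # labelled items sharing a boundary rating beyond the two boundary
  # holders themselves: these could swap with the middle under re-ranking
  n_tied <- sum(df$rating %in% c(lo_b, hi_b)) - length(unique(c(lo_b, hi_b)))
  degenerate <- n_tied > 0.05 * 2 * k
  if (degenerate) {
    warning("degenerate: tie-dominated tercile boundaries (", n_tied,
            " labelled items share a boundary rating)", call. = FALSE)
  }
  attr(df, "term") <- term
  attr(df, "degenerate") <- degenerate
  df
}

#' Construct a binary labelling directly
#'
#' @param low_ids,high_ids disjoint character vectors of image ids.
#' @param term label for the rating term.
#' @return A labelling tibble compatible with [cv_svm_accuracy()].
#' @export
binary_labeling <- function(low_ids, high_ids, term = "label") {
  stopifnot(!anyDuplicated(c(low_ids, high_ids)))
  df <- tibble::tibble(
    id = as.character(c(low_ids, high_ids)),
    rating = NA_real_,
    class = factor(rep(c("low", "high"), c(length(low_ids), length(high_ids))),
                   levels = c("low", "mid", "high"))
  )
  attr(df, "term") <- term
  attr(df, "degenerate") <- FALSE
  df
}

#' Cross-validated SVM-RBF classification of high vs low ratings
#'
#' Stratified, seeded 10-fold cross-validation of a radial-basis-function
#' support vector machine on the 13-feature table. Within each fold the
#' features are z-scored using training-fold statistics only; the kernel
#' width is `1 / (d * mean training variance)` with `d` the number of
#' features (on z-scored data this is `1/d`), and the cost parameter is 1.
#' Chance accuracy for balanced classes is 50%.
#'
#' @param features tibble with `id` and the 13 feature columns.
#' @param labels labelling tibble from [tercile_split()] or
#'   [binary_labeling()]; rows with class `mid` are ignored.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment (mandatory, recorded
#'   in the result).
#' @param cost SVM cost parameter (default 1).
#' @param repeats repeated cross-validation rounds (default 1); fold
#'   accuracies from all rounds are pooled.
#' @param feature_cols feature columns to use (default [feature_names()],
#'   intersected with the available columns).
#' @return An object of class `cv_result`: list with `fold_acc`,
#'   `mean_acc`, `ci95`, `t_stat`, `df`, `p_value`, `n`, `seed`,
#'   `hyperparameters`. See [tidy.cv_result()] / [glance.cv_result()].
#' @export
cv_svm_accuracy <- function(features, labels, folds = 10, seed, cost = 1,
                            repeats = 1, feature_cols = NULL) {
  stopifnot(is.data.frame(features), "id" %in% names(features))
  if (missing(seed)) stop("a seed is required for reproducible fold assignment", call. = FALSE)
  if (is.null(feature_cols)) feature_cols <- intersect(feature_names(), names(features))
  lab <- labels[labels$class %in% c("low", "high"), ]
  idx <- match(lab$id, features$id)
  if (anyNA(idx)) {
    stop("no feature row for id(s): ",
         paste(utils::head(lab$id[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(features[idx, feature_cols])
  bad <- !stats::complete.cases(X)
  if (any(bad)) {
    stop("missing feature values for id(s): ",
         paste(utils::head(lab$id[bad], 5), collapse = ", "), call. = FALSE)
  }
  y <- droplevels(lab$class)
  d <- ncol(X)
  set.seed(seed)
  fold_acc <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- integer(nrow(X))
    for (cl in levels(y)) {
      members <- sample(which(y == cl))
      fold[members] <- rep_len(seq_len(folds), length(members))
    }
    for (f in seq_len(folds)) {
      tr <- fold != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd[sd == 0] <- 1
      Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd, "/")
      Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sd, "/")
      mv <- mean(apply(Ztr, 2, stats::var))
      gamma <- if (mv > 0) 1 / (d * mv) else 1 / d
      fit <- e1071::svm(Ztr, y[tr], kernel = "radial", cost = cost,
                        gamma = gamma, scale = FALSE)
      pred <- stats::predict(fit, Zte)
      fold_acc <- c(fold_acc, mean(pred == y[!tr]))
    }
  }
  m <- mean(fold_acc)
  df_t <- length(fold_acc) - 1L
  se <- stats::sd(fold_acc) / sqrt(length(fold_acc))
  t_stat <- if (se > 0) (m - 0.5) / se else Inf * sign(m - 0.5)
  ci <- m + c(-1, 1) * stats::qt(0.975, df_t) * se
  structure(
    list(fold_acc = fold_acc, mean_acc = m, ci95 = ci, t_stat = t_stat,
         df = df_t, p_value = 2 * stats::pt(-abs(t_stat), df_t),
         n = nrow(X), seed = seed,
         hyperparameters = list(cost = cost, gamma = 1 / d, folds = folds,
                                repeats = repeats)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean accuracy %.1f%% (95%% CI %.1f-%.1f%%), t[%d] = %.2f, p = %.4g (n = %d, seed %d)\n",
              100 * x$mean_acc, 100 * x$ci95[1], 100 * x$ci95[2],
              x$df, x$t_stat, x$p_value, x$n, x$seed))
  invisible(x)
}

#' Compare two cross-validation results
#'
#' Pooled-variance two-sample t-test over the per-fold accuracies of two
#' [cv_svm_accuracy()] runs (10 + 10 folds give 18 degrees of freedom).
#'
#' @param a,b `cv_result` objects.
#' @return A one-row tibble with `t`, `df`, `p_value` and the two mean
#'   accuracies.
#' @export
compare_cv <- function(a, b) {
  stopifnot(inherits(a, "cv_result"), inherits(b, "cv_result"))
  x <- a$fold_acc; y <- b$fold_acc
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mean(x) - mean(y)
  t <- if (se > 0) diff / se else if (diff == 0) 0 else Inf * sign(diff)
  df <- n1 + n2 - 2L
  tibble::tibble(
    t = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
    mean_acc_a = mean(x), mean_acc_b = mean(y)
  )
}
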