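#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares of a rating on a set of feature columns, with
#' adjusted R-squared, standardized coefficients
#' (`beta_i = b_i * sd(x_i) / sd(y)`), AIC in the
#' `n * ln(RSS/n) + 2 * (p + 1)` convention, and two-sided per-coefficient
#' t p-values. The p-values are reported unadjusted across coefficients.
#'
#' @param data data frame holding the response and predictor columns.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names; default:
#'   every feature column of [feature_names()] found in `data`.
#' @return An object of class `mlr_fit` wrapping the `lm` fit, with
#'   elements `predictors`, `coefficients`, `std_betas`, `r2`, `r2_adj`,
#'   `aic`, `p_values`, `n`, `rss`. See [tidy.mlr_fit()] /
#'   [glance.mlr_fit()].
#' @export
fit_mlr <- function(data, response, predictors = NULL) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (is.null(predictors)) predictors <- intersect(feature_names(), names(data))
  stopifnot(length(predictors) >= 1, all(predictors %in% names(data)))
  df <- data[, c(response, predictors)]
  if (anyNA(df)) stop("missing values in response or predictors", call. = FALSE)
  n <- nrow(df); p <- length(predictors)
  if (n <= p + 2) stop("need n > p + 2 observations (n = ", n, ", p = ", p, ")", call. = FALSE)
  fm <- stats::as.formula(paste(
    "`", response, "` ~ ", paste0("`", predictors, "`", collapse = " + "),
    sep = ""
  ))
  fit <- stats::lm(fm, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("exact collinearity among predictors: ",
         paste(gsub("`", "", names(cf)[is.na(cf)]), collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  b <- cf[-1]
  sx <- vapply(df[predictors], stats::sd, numeric(1))
  sy <- stats::sd(df[[response]])
  rss <- sum(stats::residuals(fit)^2)
  structure(
    list(
      fit = fit, data = df, response = response, predictors = predictors,
      coefficients = cf,
      std_betas = stats::setNames(unname(b) * sx / sy, predictors),
      std_errors = stats::setNames(sm$coefficients[-1, 2], predictors),
      std_beta_se = stats::setNames(unname(sm$coefficients[-1, 2]) * sx / sy,
                                    predictors),
      p_values = stats::setNames(sm$coefficients[-1, 4], predictors),
      r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
      aic = n * log(rss / n) + 2 * (p + 1),
      n = n, rss = rss
    ),
    class = "mlr_fit"
  )
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat(sprintf("<mlr_fit> %s ~ %d predictor(s): R2 = %.3f, R2_adj = %.3f, AIC = %.1f (n = %d)\n",
              x$response, length(x$predictors), x$r2, x$r2_adj, x$aic, x$n))
  invisible(x)
}

# AIC (same convention as fit_mlr) of an OLS on a predictor subset.
.subset_aic <- function(df, response, predictors) {
  f <- fit_mlr(df, response, predictors)
  f$aic
}

#' Backward stepwise elimination by AIC
#'
#' Starting from the full model, repeatedly removes the single predictor
#' whose removal most decreases the AIC, stopping as soon as no removal
#' decreases it. The reduced model is refitted, so its standardized
#' coefficients and adjusted R-squared are recomputed on the retained
#' predictors. The elimination path (AIC after each step) is attached.
#'
#' @param fit an [fit_mlr()] object (or `data` + `response` +
#'   `predictors` as in [fit_mlr()]).
#' @param data,response,predictors alternative direct specification.
#' @return A reduced `mlr_fit` with attribute `path`: tibble of
#'   `step`, `dropped`, `aic` (strictly decreasing).
#' @export
backward_aic <- function(fit = NULL, data = NULL, response = NULL, predictors = NULL) {
  if (is.null(fit)) fit <- fit_mlr(data, response, predictors)
  stopifnot(inherits(fit, "mlr_fit"))
  df <- fit$data; response <- fit$response
  current <- fit$predictors
  path <- tibble::tibble(step = 0L, dropped = NA_character_, aic = fit$aic)
  repeat {
    if (length(current) <= 1L) break
    cand <- vapply(current, function(drop_var) {
      .subset_aic(df, response, setdiff(current, drop_var))
    }, numeric(1))
    best <- which.min(cand)
    if (cand[best] >= utils::tail(path$aic, 1)) break
    dropped <- current[best]
    current <- setdiff(current, dropped)
    path <- dplyr::bind_rows(path, tibble::tibble(
      step = nrow(path), dropped = dropped, aic = cand[best]
    ))
  }
  out <- fit_mlr(df, response, current)
  attr(out, "path") <- path
  out
}

#' Exhaustive best-subset regression
#'
#' Enumerates every predictor subset of each size `k = 1 ... max_k`,
#' ranks subsets by adjusted R-squared (for fixed k this ordering equals
#' ranking by R-squared) and reports the top `top` subsets per size,
#' together with a 0/1 membership matrix suitable for a subset-selection
#' plot shaded by adjusted R-squared.
#'
#' Fits are evaluated from precomputed cross-product matrices, so the
#' 2^p enumeration is fast for the guard limit `p <= 20`.
#'
#' @param data data frame with response and predictors.
#' @param response response column name.
#' @param predictors predictor column names (default: the 13 features
#'   present in `data`).
#' @param max_k largest model size (default: number of predictors).
#' @param top how many best subsets to keep per size (default 10).
#' @return An object of class `subset_report`: tibble with columns `size`,
#'   `rank`, `r2`, `r2_adj`, `predictors` (list column), plus one 0/1
#'   membership column per predictor (prefixed `in_`).
#' @export
best_subsets <- function(data, response, predictors = NULL, max_k = NULL, top = 10) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (is.null(predictors)) predictors <- intersect(feature_names(), names(data))
  p <- length(predictors)
  if (p > 20) stop("exhaustive enumeration limited to p <= 20 predictors; ",
                   "screen the predictor set first", call. = FALSE)
  if (is.null(max_k)) max_k <- p
  max_k <- min(max_k, p)
  df <- data[, c(response, predictors)]
  if (anyNA(df)) stop("missing values in response or predictors", call. = FALSE)
  n <- nrow(df)
  X <- cbind(`(Intercept)` = 1, as.matrix(df[predictors]))
  y <- df[[response]]
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  tss <- sum((y - mean(y))^2)
  rows <- list()
  for (k in seq_len(max_k)) {
    combos <- utils::combn(p, k)
    rss <- apply(combos, 2, function(s) {
      ii <- c(1L, s + 1L)
      b <- tryCatch(solve(XtX[ii, ii], Xty[ii, ]), error = function(e) NULL)
      if (is.null(b)) return(Inf)
      yty - sum(b * Xty[ii, ])
    })
    r2 <- 1 - rss / tss
    r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
    keep <- utils::head(order(r2_adj, decreasing = TRUE), top)
    rows[[k]] <- tibble::tibble(
      size = k,
      rank = seq_along(keep),
      r2 = r2[keep],
      r2_adj = r2_adj[keep],
      predictors = lapply(keep, function(j) predictors[combos[, j]])
    )
  }
  out <- dplyr::bind_rows(rows)
  memb <- vapply(predictors, function(v) {
    vapply(out$predictors, function(s) as.integer(v %in% s), integer(1))
  }, integer(nrow(out)))
  colnames(memb) <- paste0("in_", predictors)
  out <- dplyr::bind_cols(out, tibble::as_tibble(memb))
  attr(out, "predictors") <- predictors
  attr(out, "response") <- response
  class(out) <- c("subset_report", class(out))
  out
}

#' Spearman correlation matrix of rating terms
#'
#' Pairwise Spearman rank correlations (average ranks for ties) with
#' two-sided p-values for every pair of rating terms.
#'
#' @param ratings ratings tibble (see [read_ratings()]).
#' @param terms rating columns to correlate; default: all numeric
#'   non-id columns.
#' @return A tibble with columns `term1`, `term2`, `r`, `p_value`
#'   (one row per unordered pair, plus the diagonal where r is 1).
#' @export
spearman_matrix <- function(ratings, terms = NULL) {
  stopifnot(is.data.frame(ratings))
  if (is.null(terms)) {
    terms <- setdiff(names(ratings), "id")
    terms <- terms[vapply(ratings[terms], is.numeric, logical(1))]
  }
  if (length(terms) < 2) stop("need at least 2 rating terms", call. = FALSE)
  combos <- utils::combn(terms, 2)
  pairs <- dplyr::bind_rows(lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    ok <- stats::complete.cases(ratings[[a]], ratings[[b]])
    ct <- suppressWarnings(
      stats::cor.test(ratings[[a]][ok], ratings[[b]][ok],
                      method = "spearman", exact = FALSE)
    )
    tibble::tibble(term1 = a, term2 = b, r = unname(ct$estimate),
                   p_value = ct$p.value)
  }))
  diag <- tibble::tibble(term1 = terms, term2 = terms, r = 1, p_value = 0)
  dplyr::bind_rows(diag, pairs)
}

#' Compare feature distributions across image groups
#'
#' Per feature: a Kruskal-Wallis test across groups, followed by pairwise
#' Wilcoxon rank-sum post-hoc tests with Holm step-down correction across
#' the pairwise family within that feature.
#'
#' @param features feature tibble (with the columns of [feature_names()]
#'   or any numeric columns).
#' @param groups factor or character vector, one group label per row.
#' @param feature_cols columns to test (default: the 13 features present).
#' @return A list with `omnibus` (tibble: feature, kw_stat, df, p_value)
#'   and `posthoc` (tibble: feature, group1, group2, p_raw, p_holm).
#' @export
compare_feature_distributions <- function(features, groups, feature_cols = NULL) {
  stopifnot(is.data.frame(features), length(groups) == nrow(features))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 5)) stop("every group needs at least 5 rows", call. = FALSE)
  if (is.null(feature_cols)) feature_cols <- intersect(feature_names(), names(features))
  omnibus <- dplyr::bind_rows(lapply(feature_cols, function(fc) {
    kw <- stats::kruskal.test(features[[fc]], groups)
    tibble::tibble(feature = fc, kw_stat = unname(kw$statistic),
                   df = unname(kw$parameter), p_value = kw$p.value)
  }))
  lv <- levels(groups)
  combos <- utils::combn(lv, 2)
  posthoc <- dplyr::bind_rows(lapply(feature_cols, function(fc) {
    p_raw <- vapply(seq_len(ncol(combos)), function(i) {
      a <- features[[fc]][groups == combos[1, i]]
      b <- features[[fc]][groups == combos[2, i]]
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }, numeric(1))
    tibble::tibble(feature = fc, group1 = combos[1, ], group2 = combos[2, ],
                   p_raw = p_raw, p_holm = stats::p.adjust(p_raw, method = "holm"))
  }))
  list(omnibus = omnibus, posthoc = posthoc)
}
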