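# End-to-end orchestration: the run_* functions reproduce the study's
# analysis shape (feature table, per-group description, rating
# correlations, classification report, regression reports, subset
# selection) with deterministic, config-stamped tabular outputs. A thin
# command-line dispatcher over these functions ships in inst/cli/.

run_manifest <- function(config) {
  config$package_version <- as.character(utils::packageVersion("imaffect"))
  config$config_hash <- rlang::hash(config)
  config
}

write_report <- function(tbl, path, config = NULL) {
  if (is.null(path)) return(invisible(tbl))
  readr::write_csv(tbl, path, progress = FALSE)
  if (!is.null(config)) {
    manifest <- run_manifest(config)
    json <- paste0(
      "{", paste(sprintf('"%s": %s', names(manifest),
                         vapply(manifest, function(v) {
                           if (is.character(v)) sprintf('"%s"', v)
                           else paste0("[", paste(unlist(v), collapse = ", "), "]")
                         }, character(1))), collapse = ", "), "}"
    )
    writeLines(json, paste0(path, ".manifest.json"))
  }
  invisible(tbl)
}

#' Run the full feature-extraction stage
#'
#' Extracts the 13 properties for every image in a directory (or path
#' vector) and writes the feature table; failures are flagged per image
#' and the run continues.
#'
#' @param images image directory, path vector or list of images (see
#'   [extract_features()]).
#' @param out optional output CSV path.
#' @param ... passed to [extract_features()].
#' @return The feature tibble, invisibly when written.
#' @export
run_extract <- function(images, out = NULL, ...) {
  feats <- extract_features(images, ...)
  if (!is.null(out)) write_features(feats, out)
  if (is.null(out)) feats else invisible(feats)
}

#' Describe feature distributions per group
#'
#' Per-feature group means and SDs plus Kruskal-Wallis omnibus tests and
#' Holm-corrected pairwise post-hoc tests.
#'
#' @param features feature tibble.
#' @param groups group label per row.
#' @param out optional output CSV path (summary table).
#' @return A list with `summary` (feature x group mean/sd tibble),
#'   `omnibus` and `posthoc` (see [compare_feature_distributions()]).
#' @export
run_describe <- function(features, groups, out = NULL) {
  groups <- factor(groups)
  cols <- intersect(feature_names(), names(features))
  summary <- dplyr::bind_rows(lapply(cols, function(fc) {
    dplyr::bind_cols(
      tibble::tibble(feature = fc),
      dplyr::summarise(
        dplyr::group_by(tibble::tibble(g = groups, x = features[[fc]]), .data$g),
        mean = mean(.data$x, na.rm = TRUE), sd = stats::sd(.data$x, na.rm = TRUE),
        .groups = "drop"
      ) |>
        tidyr::pivot_wider(names_from = "g",
                           values_from = c("mean", "sd"))
    )
  }))
  tests <- compare_feature_distributions(features, groups, feature_cols = cols)
  write_report(summary, out, config = list(stage = "describe",
                                           n = nrow(features)))
  list(summary = summary, omnibus = tests$omnibus, posthoc = tests$posthoc)
}

#' Correlate rating terms
#'
#' Spearman rank correlations with p-values for all pairs of rating terms.
#'
#' @param ratings ratings tibble.
#' @param out optional output CSV path.
#' @return Tibble from [spearman_matrix()].
#' @export
run_correlate <- function(ratings, out = NULL) {
  res <- spearman_matrix(ratings)
  write_report(res, out, config = list(stage = "correlate", n = nrow(ratings)))
  res
}

#' Run the high/low classification stage
#'
#' For each rating term: tercile split, stratified 10-fold SVM-RBF
#' cross-validation, and a one-row report with the mean accuracy (%), its
#' 95% confidence interval, the t statistic against the 50% chance rate
#' and its p-value, plus seed and hyperparameters.
#'
#' @param features feature tibble.
#' @param ratings ratings tibble.
#' @param terms rating terms to analyse (default: all).
#' @param folds,seed,cost,repeats see [cv_svm_accuracy()].
#' @param out optional output CSV path.
#' @return A tibble with columns `term`, `n`, `mean_pct`, `ci_lo_pct`,
#'   `ci_hi_pct`, `t`, `df`, `p_value`, `seed`, `folds`, `cost`, `gamma`.
#' @export
run_classify <- function(features, ratings, terms = NULL, folds = 10,
                         seed = 1, cost = 1, repeats = 1, out = NULL) {
  if (is.null(terms)) {
    terms <- setdiff(names(ratings), "id")
    terms <- terms[vapply(ratings[terms], is.numeric, logical(1))]
  }
  res <- dplyr::bind_rows(lapply(terms, function(tm) {
    lab <- tercile_split(ratings, tm)
    cv <- cv_svm_accuracy(features, lab, folds = folds, seed = seed,
                          cost = cost, repeats = repeats)
    tibble::tibble(
      term = tm, n = cv$n,
      mean_pct = 100 * cv$mean_acc,
      ci_lo_pct = 100 * cv$ci95[1], ci_hi_pct = 100 * cv$ci95[2],
      t = cv$t_stat, df = cv$df, p_value = cv$p_value,
      seed = seed, folds = folds, cost = cost,
      gamma = cv$hyperparameters$gamma
    )
  }))
  write_report(res, out, config = list(stage = "classify", seed = seed,
                                       folds = folds, cost = cost,
                                       repeats = repeats))
  res
}

#' Run the regression stage
#'
#' For each rating term, fits the full 13-predictor linear model and the
#' backward-AIC-reduced model, reporting standardized coefficients with
#' significance stars (unadjusted p-values; interpret across 13
#' coefficients with care) and per-model adjusted R-squared and AIC.
#'
#' @param features feature tibble.
#' @param ratings ratings tibble.
#' @param terms rating terms (default: all numeric).
#' @param out optional output CSV path.
#' @return A tibble with columns `term`, `model` (full/reduced),
#'   `predictor`, `std_beta`, `p_value`, `stars`, `r2_adj`, `aic`, `n`.
#' @export
run_regress <- function(features, ratings, terms = NULL, out = NULL) {
  if (is.null(terms)) {
    terms <- setdiff(names(ratings), "id")
    terms <- terms[vapply(ratings[terms], is.numeric, logical(1))]
  }
  data <- dplyr::inner_join(features, ratings, by = "id")
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  res <- dplyr::bind_rows(lapply(terms, function(tm) {
    full <- fit_mlr(data, tm)
    red <- backward_aic(full)
    row_of <- function(fit, label) {
      td <- tidy(fit)
      tibble::tibble(
        term = tm, model = label, predictor = td$term,
        std_beta = td$std_beta, p_value = td$p_value,
        stars = stars(td$p_value),
        r2_adj = fit$r2_adj, aic = fit$aic, n = fit$n
      )
    }
    dplyr::bind_rows(row_of(full, "full"), row_of(red, "reduced"))
  }))
  write_report(res, out, config = list(stage = "regress"))
  res
}

#' Run the subset-selection stage
#'
#' Exhaustive best-subset search for one rating term; the returned report
#' carries the 0/1 membership matrix used by the subset-selection plot.
#'
#' @param features feature tibble.
#' @param ratings ratings tibble.
#' @param term rating term.
#' @param top best models kept per size.
#' @param out optional output CSV path.
#' @return A [best_subsets()] report.
#' @export
run_subsets <- function(features, ratings, term, top = 10, out = NULL) {
  data <- dplyr::inner_join(features, ratings, by = "id")
  rep <- best_subsets(data, term, top = top)
  flat <- dplyr::select(tibble::as_tibble(rep), -"predictors")
  write_report(flat, out, config = list(stage = "subsets", term = term,
                                        top = top))
  rep
}

#' Simulate a synthetic study to disk
#'
#' Writes a directory of PNG images, a ratings table and a manifest
#' (recipes, seed, generating coefficients) for a [gen_study()] corpus.
#'
#' @param out_dir output directory (created).
#' @param n_images,betas,noise_sd,target_r2,scale,size,seed,term passed to
#'   [gen_study()].
#' @return The `synthetic_study`, invisibly.
#' @export
run_simulate <- function(out_dir, n_images = 100, betas = c(s_mean = 0.5),
                         noise_sd = 1, target_r2 = NULL, scale = c(1, 9),
                         size = 128, seed = 1, term = "valence") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- gen_study(n_images = n_images, betas = betas, noise_sd = noise_sd,
                     target_r2 = target_r2, scale = scale, size = size,
                     seed = seed, term = term, keep_images = TRUE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  for (img in study$images) {
    write_image(img, file.path(img_dir, paste0(img$id, ".png")))
  }
  readr::write_csv(study$ratings, file.path(out_dir, "ratings.csv"),
                   progress = FALSE)
  write_features(study$features, file.path(out_dir, "features.csv"))
  manifest <- list(stage = "simulate", n_images = n_images, seed = seed,
                   noise_sd = study$noise_sd, scale = scale, size = size,
                   term = term, betas = as.list(study$betas),
                   rng = "Mersenne-Twister")
  writeLines(
    paste0("{", paste(sprintf('"%s": %s', names(manifest),
                              vapply(manifest, function(v) {
                                if (is.character(v)) sprintf('"%s"', v)
                                else if (is.list(v)) paste0("{", paste(sprintf('"%s": %g', names(v), unlist(v)), collapse = ", "), "}")
                                else paste0("[", paste(v, collapse = ", "), "]")
                              }, character(1))), collapse = ", "), "}"),
    file.path(out_dir, "manifest.json")
  )
  invisible(study)
}
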