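sim_xy <- function(n, p, seed, betas = NULL, noise = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  if (is.null(betas)) betas <- rep(0, p)
  y <- as.numeric(X %*% betas + rnorm(n, 0, noise))
  dplyr::bind_cols(tibble::tibble(y = y), tibble::as_tibble(X))
}

test_that("an exact linear combination is fitted with R2 = 1 and zero residuals", {
  d <- sim_xy(50, 3, seed = 1)
  d$y <- 2 * d$x1 - d$x2
  fit <- fit_mlr(d, "y", c("x1", "x2", "x3"))
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-20)
  expect_equal(unname(fit$coefficients[2]), 2, tolerance = 1e-9)
})

test_that("single-predictor standardized beta equals the Pearson correlation", {
  d <- sim_xy(80, 1, seed = 2, betas = 0.7)
  fit <- fit_mlr(d, "y", "x1")
  expect_equal(unname(fit$std_betas), cor(d$x1, d$y), tolerance = 1e-10)
})

test_that("coefficients match a normal-equations oracle on random instances", {
  for (s in 1:20) {
    d <- sim_xy(50, 5, seed = 100 + s, betas = rnorm(5))
    fit <- fit_mlr(d, "y", paste0("x", 1:5))
    X <- cbind(1, as.matrix(d[paste0("x", 1:5)]))
    b_oracle <- solve(t(X) %*% X, t(X) %*% d$y)
    expect_lt(max(abs(unname(fit$coefficients) - as.numeric(b_oracle))), 1e-8)
    # adjusted R2 identity
    n <- nrow(d); p <- 5
    expect_equal(fit$r2_adj, 1 - (1 - fit$r2) * (n - 1) / (n - p - 1),
                 tolerance = 1e-12)
  }
})

test_that("standardized betas are invariant to affine rescaling", {
  d <- sim_xy(100, 3, seed = 7, betas = c(1, -0.5, 0))
  f1 <- fit_mlr(d, "y", paste0("x", 1:3))
  d2 <- d
  d2$x1 <- 10 * d2$x1 + 3
  d2$y <- 0.2 * d2$y - 5
  f2 <- fit_mlr(d2, "y", paste0("x", 1:3))
  expect_equal(abs(unname(f1$std_betas)), abs(unname(f2$std_betas)),
               tolerance = 1e-10)
})

test_that("exact collinearity is reported with the offending column", {
  d <- sim_xy(40, 2, seed = 3)
  d$x3 <- d$x1 + d$x2
  expect_error(fit_mlr(d, "y", c("x1", "x2", "x3")), "collinearity.*x3")
})

test_that("backward AIC removes noise and keeps strong predictors, path decreasing", {
  d <- sim_xy(500, 6, seed = 11, betas = c(1, rep(0, 5)), noise = 1)
  red <- backward_aic(data = d, response = "y", predictors = paste0("x", 1:6))
  expect_true("x1" %in% red$predictors)
  path <- attr(red, "path")
  expect_true(all(diff(path$aic) < 0))

  # all-strong model: nothing is dropped
  d2 <- sim_xy(400, 5, seed = 12, betas = rep(1, 5), noise = 0.5)
  red2 <- backward_aic(data = d2, response = "y", predictors = paste0("x", 1:5))
  expect_setequal(red2$predictors, paste0("x", 1:5))

  # full vs reduced adjusted R2 nearly identical on well-specified data
  full2 <- fit_mlr(d2, "y", paste0("x", 1:5))
  expect_lt(abs(full2$r2_adj - red2$r2_adj), 0.02)
})

test_that("backward AIC agrees with the MASS stepAIC oracle", {
  skip_if_not_installed("MASS")
  d <- sim_xy(200, 6, seed = 21, betas = c(1.2, 0.8, 0, 0, 0.5, 0), noise = 1)
  red <- backward_aic(data = d, response = "y", predictors = paste0("x", 1:6))
  lm_full <- lm(y ~ ., data = d)
  oracle <- MASS::stepAIC(lm_full, direction = "backward", trace = 0)
  expect_setequal(red$predictors, names(coef(oracle))[-1])
})

test_that("best subsets equal brute-force lm enumeration", {
  d <- sim_xy(60, 3, seed = 31, betas = c(1, 0.3, 0))
  rep_ <- best_subsets(d, "y", paste0("x", 1:3), top = 10)
  # oracle: all subsets via lm
  preds <- paste0("x", 1:3)
  oracle <- dplyr::bind_rows(lapply(1:3, function(k) {
    combos <- combn(preds, k)
    dplyr::bind_rows(lapply(seq_len(ncol(combos)), function(j) {
      f <- lm(stats::reformulate(combos[, j], "y"), data = d)
      tibble::tibble(size = k, r2_adj = summary(f)$adj.r.squared,
                     set = paste(sort(combos[, j]), collapse = "+"))
    }))
  }))
  for (k in 1:3) {
    ours <- rep_[rep_$size == k, ]
    ref <- oracle[oracle$size == k, ]
    ref <- ref[order(-ref$r2_adj), ]
    expect_equal(ours$r2_adj, ref$r2_adj[seq_len(nrow(ours))], tolerance = 1e-10)
    expect_equal(vapply(ours$predictors, function(s) paste(sort(s), collapse = "+"), ""),
                 ref$set[seq_len(nrow(ours))])
  }
  # k = p: single subset equals the full model
  kp <- rep_[rep_$size == 3, ]
  expect_equal(nrow(kp), 1)
  expect_equal(kp$r2_adj, fit_mlr(d, "y", preds)$r2_adj, tolerance = 1e-12)
})

test_that("a dominant predictor appears in every top-10 subset", {
  d <- sim_xy(300, 6, seed = 41, betas = c(3, rep(0, 5)), noise = 1)
  rep_ <- best_subsets(d, "y", paste0("x", 1:6), top = 10)
  # the best model of every size contains x1, and x1 is a member of more
  # listed models than any other predictor (only C(p-1, k-1) subsets of
  # size k contain a given variable, so low ranks of small sizes must
  # sometimes omit it)
  expect_true(all(rep_$in_x1[rep_$rank == 1] == 1))
  memb_counts <- colSums(rep_[, paste0("in_x", 1:6)])
  expect_equal(unname(which.max(memb_counts)), 1)
  # unadjusted best r2 non-decreasing in model size
  best_r2 <- vapply(split(rep_$r2, rep_$size), max, numeric(1))
  expect_true(all(diff(best_r2) >= -1e-12))
  d20 <- sim_xy(40, 2, seed = 1)
  d20[paste0("z", 1:21)] <- replicate(21, rnorm(40))
  expect_error(best_subsets(d20, "y", paste0("z", 1:21)), "p <= 20")
})

test_that("spearman matrix matches rank-then-Pearson with ties", {
  set.seed(51)
  rt <- tibble::tibble(id = as.character(1:50),
                       a = sample(1:10, 50, TRUE),
                       b = sample(1:10, 50, TRUE))
  rt$c <- -rt$a
  sm <- spearman_matrix(rt)
  get <- function(t1, t2) sm[sm$term1 == t1 & sm$term2 == t2, ]
  expect_equal(get("a", "a")$r, 1)
  expect_equal(get("a", "c")$r, -1, tolerance = 1e-12)
  oracle_r <- cor(rank(rt$a), rank(rt$b))
  expect_equal(get("a", "b")$r, oracle_r, tolerance = 1e-12)
})

test_that("group comparisons: identical groups null, shifted groups significant, Holm exact", {
  set.seed(61)
  base <- tibble::as_tibble(matrix(rnorm(200 * 13), 200,
                                   dimnames = list(NULL, feature_names())))
  same <- compare_feature_distributions(dplyr::bind_rows(base, base),
                                        rep(c("g1", "g2"), each = 200))
  expect_true(all(same$omnibus$kw_stat < 1e-6))

  shifted <- base
  shifted$h_mean <- shifted$h_mean + 5
  res <- compare_feature_distributions(dplyr::bind_rows(base[1:100, ], shifted[1:100, ]),
                                       rep(c("g1", "g2"), each = 100))
  expect_lt(res$posthoc$p_holm[res$posthoc$feature == "h_mean"], 1e-4)

  p <- c(0.001, 0.04, 0.03, 0.6, 0.2)
  expect_equal(p.adjust(p, "holm"), oracle_holm(p), tolerance = 1e-12)
  three <- compare_feature_distributions(
    dplyr::bind_rows(base[1:40, ], base[41:80, ], shifted[1:40, ]),
    rep(c("g1", "g2", "g3"), each = 40)
  )
  hm <- three$posthoc[three$posthoc$feature == "s_mean", ]
  expect_equal(hm$p_holm, oracle_holm(hm$p_raw), tolerance = 1e-12)
})
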