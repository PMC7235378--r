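make_ratings <- function(vals, ids = sprintf("s%04d", seq_along(vals))) {
  tibble::tibble(id = ids, valence = vals)
}

test_that("tercile split keeps the extreme thirds and discards the middle", {
  rt <- make_ratings(c(31:60)) # n = 30, ratings 31..60
  sp <- tercile_split(rt, "valence")
  expect_equal(sum(sp$class == "low"), 10)
  expect_equal(sum(sp$class == "high"), 10)
  expect_true(all(sp$rating[sp$class == "low"] <= sp$rating[sp$class == "mid"][1]))
  expect_equal(sort(sp$rating[sp$class == "high"]), 51:60)

  # floor rule: n = 31 -> 10 per class, 11 discarded
  sp31 <- tercile_split(make_ratings(1:31), "valence")
  expect_equal(as.numeric(table(sp31$class)), c(10, 11, 10))

  expect_error(tercile_split(make_ratings(1:20), "valence"), "at least 30")
  expect_warning(tercile_split(make_ratings(rep(5, 33)), "valence"), "tie-dominated")
})

test_that("well-separated clusters are classified almost perfectly", {
  n <- 300
  ft <- random_feature_table(2 * n, seed = 101)
  X <- as.matrix(ft[, feature_names()])
  X[seq_len(n), ] <- X[seq_len(n), ] + 6 # delta-mu = 6 sd
  ft[, feature_names()] <- X
  lab <- binary_labeling(ft$id[seq_len(n)], ft$id[n + seq_len(n)])
  cv <- cv_svm_accuracy(ft, lab, seed = 7)
  expect_gte(cv$mean_acc, 0.95)
  expect_equal(cv$df, 9)
  expect_true(cv$ci95[1] <= cv$mean_acc && cv$mean_acc <= cv$ci95[2])
})

test_that("constant features yield chance accuracy with balanced labels", {
  ft <- random_feature_table(100, seed = 5)
  ft[, feature_names()] <- 0
  lab <- binary_labeling(ft$id[1:50], ft$id[51:100])
  cv <- cv_svm_accuracy(ft, lab, seed = 3)
  expect_equal(cv$mean_acc, 0.5, tolerance = 0.05)
})

test_that("results are bit-reproducible given features, labels and seed", {
  ft <- random_feature_table(120, seed = 8)
  lab <- binary_labeling(ft$id[1:60], ft$id[61:120])
  cv1 <- cv_svm_accuracy(ft, lab, seed = 42)
  cv2 <- cv_svm_accuracy(ft, lab, seed = 42)
  expect_identical(cv1$fold_acc, cv2$fold_acc)
  cv3 <- cv_svm_accuracy(ft, lab, seed = 43)
  expect_false(identical(cv1$fold_acc, cv3$fold_acc))
})

test_that("accuracy is invariant to affine rescaling of one feature column", {
  ft <- random_feature_table(120, seed = 9)
  set.seed(1); shift <- rnorm(120)
  ft$h_mean <- ft$h_mean + shift # make column informative-ish
  lab <- binary_labeling(ft$id[1:60], ft$id[61:120])
  cv1 <- cv_svm_accuracy(ft, lab, seed = 11)
  ft2 <- ft
  ft2$h_mean <- 100 * ft2$h_mean - 7
  cv2 <- cv_svm_accuracy(ft2, lab, seed = 11)
  expect_equal(cv1$fold_acc, cv2$fold_acc, tolerance = 1e-9)
})

test_that("missing features are reported with offending ids", {
  ft <- random_feature_table(60, seed = 2)
  ft$v_mean[3] <- NA
  lab <- binary_labeling(ft$id[1:30], ft$id[31:60])
  expect_error(cv_svm_accuracy(ft, lab, seed = 1), ft$id[3])
})

test_that("compare_cv matches the pooled-variance t-test", {
  a <- structure(list(fold_acc = c(.6, .62, .58, .61, .63, .59, .6, .64, .57, .6)),
                 class = "cv_result")
  b <- structure(list(fold_acc = c(.52, .55, .5, .53, .56, .51, .54, .5, .52, .53)),
                 class = "cv_result")
  got <- compare_cv(a, b)
  ref <- t.test(a$fold_acc, b$fold_acc, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, 18)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  same <- compare_cv(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  c_ <- structure(list(fold_acc = a$fold_acc * 0 + 0.6), class = "cv_result")
  d_ <- structure(list(fold_acc = c_$fold_acc + 0.1), class = "cv_result")
  lim <- compare_cv(d_, c_)
  expect_true(lim$t > 0 && lim$p_value < 1e-12)
})

test_that("chance calibration: permuted labels rarely reject the 50% null", {
  ft <- random_feature_table(200, seed = 55)
  n_reject <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    perm <- sample(ft$id)
    lab <- binary_labeling(perm[1:100], perm[101:200])
    cv <- cv_svm_accuracy(ft, lab, seed = s)
    if (cv$p_value < 0.05) n_reject <- n_reject + 1
  }
  expect_lte(n_reject / 20, 0.10)
})
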