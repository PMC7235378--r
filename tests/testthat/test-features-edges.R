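test_that("constant images produce zero edge magnitude and zero density", {
  em <- gabor_edge_map(to_gray(const_img(0.5, n = 32)))
  expect_true(all(em$magnitude == 0))
  expect_equal(edge_density(em), 0)
  expect_error(orientation_histogram(em), "no edges")
})

test_that("a vertical step edge is detected at vertical orientation", {
  em <- gabor_edge_map(to_gray(step_edge_img(64)))
  # strongest interior responses on the edge column (the circular boundary
  # creates a second, wrap-around edge at the image border), orientation
  # near 90 deg (doubled angle 180)
  interior <- 8:56
  peak_col <- interior[which.max(colSums(em$magnitude[, interior]))]
  expect_true(abs(peak_col - 32) <= 2)
  strong <- em$magnitude > 0.5 * max(em$magnitude)
  expect_true(mean(abs(em$orientation[strong] - 180) <= 15) > 0.9)
})

test_that("rotating the image by 90 degrees rotates edge orientations", {
  img <- gen_oriented_texture(64, "single", mu_deg = 0, n_segments = 40, seed = 3)
  g <- to_gray(img)
  rot <- t(g)[ncol(g):1, ] # 90 deg rotation
  h1 <- orientation_histogram(gabor_edge_map(g))
  h2 <- orientation_histogram(gabor_edge_map(structure(rot, class = class(g))))
  # dominant doubled orientation shifts by 180 deg = B/2 bins
  b1 <- which.max(h1$mass); b2 <- which.max(h2$mass)
  expect_equal((b2 - b1) %% 24, 12)
})

test_that("edge density is linear in contrast and decreases under blurring", {
  set.seed(4)
  m <- matrix(runif(64 * 64, 0.3, 0.7), 64, 64)
  g1 <- structure(m, class = c("gray_image", "matrix", "array"))
  g2 <- structure(0.5 + 2 * (m - 0.5), class = class(g1)) # doubled contrast
  d1 <- edge_density(gabor_edge_map(g1))
  d2 <- edge_density(gabor_edge_map(g2))
  expect_equal(d2, 2 * d1, tolerance = 1e-9)

  cb <- checkerboard_img(64, cell = 2)
  blur <- EBImage::gblur(matrix(unclass(to_gray(cb)), 64, 64), sigma = 2)
  d_sharp <- edge_density(gabor_edge_map(to_gray(cb)))
  d_blur <- edge_density(gabor_edge_map(matrix(as.numeric(blur), 64, 64)))
  expect_gt(d_sharp, d_blur)
})

test_that("edge density is invariant to mirroring", {
  img <- gen_powerlaw_image(64, -2, seed = 17)
  d <- edge_density(gabor_edge_map(to_gray(img)))
  d_lr <- edge_density(gabor_edge_map(to_gray(mirror_image(img, "lr"))))
  d_ud <- edge_density(gabor_edge_map(to_gray(mirror_image(img, "ud"))))
  expect_equal(d, d_lr, tolerance = 1e-9)
  expect_equal(d, d_ud, tolerance = 1e-9)
})

test_that("orientation histograms behave on gratings and under shuffling", {
  em <- gabor_edge_map(to_gray(gen_grating(64, 90, 8)))
  h <- orientation_histogram(em)
  expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  expect_gt(max(h$mass), 0.99) # single orientation -> one bin
  # oblique gratings keep a dominant bin, though response nodes of the
  # odd-symmetric kernels leak some mass into neighbouring orientations
  h30 <- orientation_histogram(gabor_edge_map(to_gray(gen_grating(64, 30, 8))))
  expect_gt(max(h30$mass), 0.8)

  # histogram depends only on (magnitude, orientation) pairs, not positions
  set.seed(8)
  n <- 40
  mag <- matrix(rexp(n * n), n, n)
  ori <- matrix(runif(n * n, 0, 360), n, n)
  perm <- sample(n * n)
  h1 <- orientation_histogram(edge_map(mag, ori))
  h2 <- orientation_histogram(edge_map(matrix(mag[perm], n, n),
                                       matrix(ori[perm], n, n)))
  expect_equal(h1$mass, h2$mass, tolerance = 1e-12)
})

test_that("first-order entropy attains its closed-form extremes", {
  B <- 24
  uni <- tibble::tibble(mass = rep(1 / B, B))
  expect_equal(first_order_entropy(uni), log2(B), tolerance = 1e-12)
  one <- tibble::tibble(mass = c(1, rep(0, B - 1)))
  expect_equal(first_order_entropy(one), 0)
  half <- tibble::tibble(mass = c(0.5, 0.5, rep(0, B - 2)))
  expect_equal(first_order_entropy(half), 1)
})

test_that("second-order entropy: single orientation 0 bits, iid uniform near log2 B", {
  em <- gabor_edge_map(to_gray(gen_grating(64, 90, 8)))
  expect_lt(second_order_entropy(em), 1e-9)

  set.seed(12)
  n <- 64
  em_u <- edge_map(matrix(1, n, n), matrix(runif(n * n, 0, 360), n, n))
  e2 <- second_order_entropy(em_u, n_top = 4096)
  expect_gt(e2, 0.98 * log2(24))

  sparse <- edge_map(matrix(0, 64, 64), matrix(0, 64, 64))
  expect_error(second_order_entropy(sparse), "sparse")
})

test_that("second-order entropy equals the all-pairs oracle on small maps", {
  set.seed(77)
  for (rep in 1:3) {
    n <- 22 # 484 elements <= 500
    mag <- matrix(rexp(n * n) + 0.01, n, n)
    ori <- matrix(runif(n * n, 0, 360), n, n)
    em <- edge_map(mag, ori)
    expect_equal(second_order_entropy(em, annuli = c(5, 10, 20)),
                 oracle_second_order(em, annuli = c(5, 10, 20)),
                 tolerance = 1e-10)
  }
})

test_that("entropies always lie in [0, log2 B]", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 32
    em <- edge_map(matrix(rexp(n * n), n, n),
                   matrix(runif(n * n, 0, 360)^1.5 %% 360, n, n))
    e1 <- first_order_entropy(em)
    e2 <- second_order_entropy(em)
    expect_true(e1 >= 0 && e1 <= log2(24) + 1e-9)
    expect_true(e2 >= 0 && e2 <= log2(24) + 1e-9)
  }
})
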