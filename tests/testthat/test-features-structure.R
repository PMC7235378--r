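test_that("tiled textures have sub-histograms matching the ground histogram", {
  img <- gen_tiled_texture(128, tiles = 2, noise = 0, seed = 2)
  p <- hog_pyramid(img)
  for (r in seq_len(nrow(p$levels[[1]]))) {
    expect_equal(p$levels[[1]][r, ], p$ground, tolerance = 1e-6)
  }
  expect_gt(self_similarity(p), 0.8)
})

test_that("split-content images separate orientations across level-1 cells", {
  img <- gen_split_content(128, wavelength = 8)
  p <- hog_pyramid(img)
  doms <- apply(p$levels[[1]], 1, which.max)
  expect_gt(length(unique(doms)), 1)
  expect_lt(self_similarity(img), self_similarity(gen_tiled_texture(128, 4, 1)))
})

test_that("rotating an image 90 degrees permutes HOG bins by 4 positions", {
  img <- gen_oriented_texture(128, "vonmises", mu_deg = 30, kappa = 8,
                              n_segments = 120, seed = 6)
  g <- unclass(to_gray(img))
  rot <- t(g)[ncol(g):1, , drop = FALSE] # 90 deg counter-clockwise
  p1 <- hog_pyramid(raster_image(g, "a"), grayscale = TRUE)
  p2 <- hog_pyramid(raster_image(rot, "b"), grayscale = TRUE)
  shifted <- p1$ground[((seq_len(16) - 1 + 4) %% 16) + 1]
  expect_equal(max(abs(p2$ground - shifted)), 0, tolerance = 0.03)
})

test_that("self-similarity attains its extremes and matches a brute-force oracle", {
  # identical sub-histograms -> 1; disjoint support -> 0
  p <- structure(list(
    ground = c(1, rep(0, 15)),
    levels = list(matrix(rep(c(1, rep(0, 15)), 4), 4, byrow = TRUE)),
    bins = 16
  ), class = "hog_pyramid")
  expect_equal(self_similarity(p), 1)
  p$levels <- list(matrix(rep(c(0, 1, rep(0, 14)), 4), 4, byrow = TRUE))
  expect_equal(self_similarity(p), 0)

  img <- gen_powerlaw_image(128, -2, seed = 31)
  py <- hog_pyramid(img)
  sims <- unlist(lapply(py$levels, function(h) {
    apply(h, 1, function(x) sum(pmin(x, py$ground)))
  }))
  expect_equal(self_similarity(py), median(sims), tolerance = 1e-12)
  expect_equal(length(sims), 84)
})

test_that("filter grid is zero on constants and orientation-selective on gratings", {
  g0 <- filter_response_grid(const_img(0.5, n = 64))
  expect_true(all(g0$responses == 0))

  bank <- filter_bank()
  gr <- filter_response_grid(gen_grating(64, 90, 8), bank)
  lum8 <- which(bank$plane == "lum" & bank$lambda == 8)
  resp_by_theta <- vapply(lum8, function(k) sum(gr$responses[k, , ]), numeric(1))
  expect_equal(bank$theta[lum8][which.max(resp_by_theta)], 90)
})

test_that("mirroring the image mirrors the response grid with partner swap", {
  img <- gen_powerlaw_image(64, -2, seed = 41)
  g <- filter_response_grid(img)
  gm <- filter_response_grid(mirror_image(img, "lr"))
  M <- g$responses[g$mirror, , g$S:1, drop = FALSE]
  expect_equal(gm$responses, M, tolerance = 1e-7)
})

test_that("symmetry scores: exact mirrors give 1, score is mirror-invariant and ordered", {
  base <- gen_powerlaw_image(64, -2, seed = 51)
  sym1 <- symmetry_scores(gen_mirrored_composite(base, "lr", 1))
  expect_equal(sym1$sym_lr, 1, tolerance = 1e-9)
  symud <- symmetry_scores(gen_mirrored_composite(base, "ud", 1))
  expect_equal(symud$sym_ud, 1, tolerance = 1e-9)

  s_base <- symmetry_scores(base)$sym_lr
  s_mirr <- symmetry_scores(mirror_image(base, "lr"))$sym_lr
  expect_equal(s_base, s_mirr, tolerance = 1e-9)

  # half black / half noise is less symmetric than the same noise mirrored
  set.seed(3)
  n <- 64
  noise <- matrix(runif(n * n / 2), n, n / 2)
  asym <- raster_image(cbind(matrix(0, n, n / 2), noise), "asym")
  symm <- raster_image(cbind(noise[, (n / 2):1], noise), "symm")
  expect_lt(symmetry_scores(asym)$sym_lr, symmetry_scores(symm)$sym_lr)

  expect_warning(s0 <- symmetry_scores(const_img(0.5, n = 32)), "featureless")
  expect_equal(s0$sym_lr, 1)
})

test_that("Pa/Pf variances match closed forms and a brute-force oracle", {
  # equal response everywhere -> both variances zero
  S <- 4; F <- 6
  grid <- structure(list(responses = array(1, c(F, S, S)),
                         mirror = seq_len(F), S = S), class = "filter_grid")
  pv <- cnn_variances(grid)
  expect_equal(pv$var_pa, 0)
  expect_equal(pv$var_pf, 0)

  # one-hot filter: var over filters of mean vector (1, 0, ..., 0)
  grid$responses <- array(0, c(F, S, S)); grid$responses[1, , ] <- 2
  pv1 <- cnn_variances(grid)
  expect_equal(pv1$var_pa, var(c(1, rep(0, F - 1))))
  expect_equal(pv1$var_pf, 0)

  # random grids vs explicit double-loop oracle
  set.seed(13)
  for (rep in 1:3) {
    resp <- array(rexp(F * S * S), c(F, S, S))
    grid$responses <- resp
    R <- matrix(resp, nrow = F)
    R <- sweep(R, 2, colSums(R), "/")
    a <- rowMeans(R)
    pa <- sum((a - mean(a))^2) / (F - 1)
    pf <- mean(vapply(seq_len(F), function(f) {
      sum((R[f, ] - mean(R[f, ]))^2) / (S * S - 1)
    }, numeric(1)))
    got <- cnn_variances(grid)
    expect_equal(got$var_pa, pa, tolerance = 1e-12)
    expect_equal(got$var_pf, pf, tolerance = 1e-12)
  }
})

test_that("superimposing textures activates more filters and lowers Pa", {
  g1 <- gen_grating(64, 0, 8)
  g2 <- gen_grating(64, 90, 8)
  mix <- raster_image((g1$pixels + g2$pixels) / 2, "mix")
  pa_single <- cnn_variances(filter_response_grid(g1))$var_pa
  pa_mix <- cnn_variances(filter_response_grid(mix))$var_pa
  expect_lt(pa_mix, pa_single)
})

test_that("symmetry blend weight is monotone for sym scores", {
  ws <- c(0, 0.25, 0.5, 0.75, 1)
  for (s in 1:2) {
    base <- gen_powerlaw_image(64, -2, seed = 60 + s)
    vals <- vapply(ws, function(w) {
      symmetry_scores(gen_mirrored_composite(base, "lr", w))$sym_lr
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-9))
  }
})
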