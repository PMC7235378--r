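# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

const_img <- function(r, g = r, b = r, n = 16, id = "const") {
  px <- array(0, dim = c(n, n, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  raster_image(px, id = id)
}

# vertical step edge: left half dark, right half bright
step_edge_img <- function(n = 64, lo = 0.2, hi = 0.8) {
  m <- matrix(lo, n, n)
  m[, (n %/% 2 + 1):n] <- hi
  raster_image(m, id = "step")
}

checkerboard_img <- function(n = 64, cell = 2) {
  idx <- (outer(seq_len(n) %/% cell, seq_len(n) %/% cell, "+") %% 2)
  raster_image(matrix(as.numeric(idx), n, n), id = "checker")
}

write_tmp_png <- function(img, name = "img.png") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  write_image(img, path)
  path
}

# features table of iid standard normals, for classifier/regression tests
random_feature_table <- function(n, seed, p = 13) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- feature_names()[seq_len(p)]
  dplyr::bind_cols(tibble::tibble(id = sprintf("s%04d", seq_len(n))),
                   tibble::as_tibble(X))
}

# independent all-pairs oracle for the second-order entropy (pure R)
oracle_second_order <- function(edges, B = 24, annuli = c(20, 40, 80, 160)) {
  m <- edges$magnitude
  nz <- which(m > 0)
  nr <- nrow(m)
  rows <- ((nz - 1L) %% nr) + 1L
  cols <- ((nz - 1L) %/% nr) + 1L
  ori <- edges$orientation[nz]
  n <- length(nz)
  d <- sqrt(outer(rows, rows, "-")^2 + outer(cols, cols, "-")^2)
  diffmat <- outer(ori, ori, function(a, b) (b - a) %% 360)
  binw <- 360 / B
  lims <- c(0, annuli)
  ents <- c()
  for (a in seq_along(annuli)) {
    sel <- d > lims[a] & d <= lims[a + 1] & row(d) != col(d)
    if (sum(sel) < 100) next
    bins <- pmin(floor(diffmat[sel] / binw), B - 1)
    p <- tabulate(bins + 1, nbins = B)
    p <- p / sum(p)
    p <- p[p > 0]
    ents <- c(ents, -sum(p * log2(p)))
  }
  mean(ents)
}

# textbook Holm step-down adjustment
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}
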