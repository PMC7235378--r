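#' Pyramid of histograms of oriented gradients (PHOG derivative)
#'
#' The image is reduced to about 100,000 pixels, per-pixel signed gradient
#' orientations (0-360 degrees, from the colour channel with the maximal
#' gradient magnitude at that pixel) are binned into 16 equal orientation
#' bins, magnitude-weighted, for the whole image (ground level) and for the
#' 4, 16 and 64 sub-rectangles of pyramid levels 1-3. Every histogram is
#' normalized to sum 1; sub-rectangles without gradient energy are flagged
#' empty.
#'
#' @param img a [raster_image()].
#' @param bins orientation bins (default 16).
#' @param levels pyramid levels (default 3).
#' @param target_pixels resize target before gradient computation.
#' @param grayscale if `TRUE`, gradients are taken on the luminance image
#'   instead of the maximal-magnitude colour channel.
#' @return A list of class `hog_pyramid` with `ground` (length-`bins`
#'   histogram) and `levels` (list of matrices, one row per sub-rectangle).
#' @export
hog_pyramid <- function(img, bins = 16, levels = 3, target_pixels = 1e5,
                        grayscale = FALSE) {
  stopifnot(is_raster_image(img))
  check_extractable(img)
  img <- resize_to_area(img, target_pixels)
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  grad <- function(m) {
    # central differences with circular wrap (consistent with the FFT-based
    # filtering elsewhere; makes periodic tilings exactly self-similar)
    gx <- (m[, c(2:w, 1)] - m[, c(w, 1:(w - 1))]) / 2
    gy <- (m[c(2:h, 1), ] - m[c(h, 1:(h - 1)), ]) / 2
    list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
  }
  if (grayscale) {
    g <- grad(to_gray(img))
    gx <- g$gx; gy <- g$gy; mag <- g$mag
  } else {
    gs <- lapply(1:3, function(c) grad(px[, , c]))
    mags <- vapply(gs, `[[`, matrix(0, h, w), "mag")
    best <- max.col(matrix(aperm(mags, c(3, 1, 2)), nrow = 3, ncol = h * w) |> t(),
                    ties.method = "first")
    pick <- function(field) {
      m <- matrix(0, h, w)
      for (c in 1:3) {
        sel <- best == c
        m[sel] <- gs[[c]][[field]][sel]
      }
      m
    }
    gx <- pick("gx"); gy <- pick("gy"); mag <- pick("mag")
  }
  if (sum(mag) <= 0) stop("featureless image: no gradient energy at ground level", call. = FALSE)
  ori <- (atan2(gy, gx) * 180 / pi) %% 360
  bin <- floor(ori / (360 / bins)) + 1L
  bin[bin > bins] <- bins
  hist_of <- function(sel) {
    s <- unname(vapply(split(as.vector(mag)[sel],
                             factor(as.vector(bin)[sel], levels = seq_len(bins))),
                       sum, numeric(1)))
    tot <- sum(s)
    if (tot <= 0) return(rep(NA_real_, bins)) # flagged empty
    s / tot
  }
  all_idx <- seq_len(h * w)
  ground <- hist_of(all_idx)
  row_of <- ((all_idx - 1L) %% h) + 1L
  col_of <- ((all_idx - 1L) %/% h) + 1L
  lev <- vector("list", levels)
  for (L in seq_len(levels)) {
    k <- 2L^L
    rcell <- pmin(floor((row_of - 1L) * k / h), k - 1L)
    ccell <- pmin(floor((col_of - 1L) * k / w), k - 1L)
    cell <- rcell * k + ccell + 1L
    hmat <- matrix(NA_real_, k * k, bins)
    for (cl in seq_len(k * k)) hmat[cl, ] <- hist_of(all_idx[cell == cl])
    lev[[L]] <- hmat
  }
  structure(list(ground = ground, levels = lev, bins = bins), class = "hog_pyramid")
}

#' PHOG self-similarity
#'
#' For every sub-rectangle histogram at pyramid levels 1-3, similarity with
#' the ground-level histogram is the histogram intersection
#' `sum(min(h, g))`; self-similarity is the median over all 84
#' sub-histograms. Empty sub-rectangles (no gradient energy) count as
#' similarity 0.
#'
#' @param p a [hog_pyramid()] or a [raster_image()].
#' @param aggregate `"median"` (default, PHOG-derivative convention) or
#'   `"mean"`.
#' @return A scalar in `[0, 1]`.
#' @export
self_similarity <- function(p, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is_raster_image(p)) p <- hog_pyramid(p)
  stopifnot(inherits(p, "hog_pyramid"))
  g <- p$ground
  sims <- unlist(lapply(p$levels, function(hmat) {
    apply(hmat, 1, function(h) {
      if (anyNA(h)) 0 else sum(pmin(h, g))
    })
  }))
  if (aggregate == "median") stats::median(sims) else mean(sims)
}

#' Fixed oriented filter bank for symmetry and response-variance features
#'
#' A deterministic analytic stand-in for the first convolutional layer of a
#' pretrained network: 48 kernels covering colour, edges and texture —
#' odd-symmetric Gabors at 12 orientations and wavelengths {4, 8} pixels on
#' the luminance plane (24 kernels) and at 12 orientations, wavelength 8,
#' on the R-G and B-Y colour-opponent planes (24 kernels). Each kernel has
#' an orientation-mirrored partner inside the bank, which the symmetry
#' score relies on.
#'
#' @param n_orientations orientations over 0-180 degrees (default 12).
#' @param wavelengths luminance wavelengths (default `c(4, 8)`).
#' @return A list of class `filter_bank` with `kernels`, `plane`
#'   (`"lum"`, `"rg"`, `"by"`), `theta`, `mirror` (partner index) and `id`.
#' @export
filter_bank <- function(n_orientations = 12, wavelengths = c(4, 8)) {
  theta <- seq(0, 180, length.out = n_orientations + 1L)[-(n_orientations + 1L)]
  spec <- rbind(
    expand.grid(theta = theta, lambda = wavelengths, plane = "lum",
                stringsAsFactors = FALSE),
    expand.grid(theta = theta, lambda = max(wavelengths), plane = c("rg", "by"),
                stringsAsFactors = FALSE)
  )
  kernels <- Map(function(t, l) gabor_kernel(t, l, phase = "odd"),
                 spec$theta, spec$lambda)
  mirror_theta <- (180 - spec$theta) %% 180
  mirror <- vapply(seq_len(nrow(spec)), function(i) {
    which(abs(spec$theta - mirror_theta[i]) < 1e-9 &
            spec$lambda == spec$lambda[i] & spec$plane == spec$plane[i])[1]
  }, integer(1))
  structure(
    list(kernels = kernels, plane = spec$plane, theta = spec$theta,
         lambda = spec$lambda, mirror = mirror,
         id = paste0("fb", n_orientations, "_", paste(wavelengths, collapse = "-"))),
    class = "filter_bank"
  )
}

.default_filter_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- filter_bank()
    bank
  }
})

#' Pooled filter-response grid
#'
#' Convolves the image with the fixed [filter_bank()], rectifies the
#' responses (absolute value) and max-pools them into an S x S spatial
#' grid, giving an `F x S x S` array of non-negative pooled responses.
#'
#' @param img a [raster_image()].
#' @param bank a [filter_bank()].
#' @param S pooling grid size per side (default 8).
#' @return A list of class `filter_grid` with `responses` (F x S x S
#'   array), `mirror` partner indices and `S`.
#' @export
filter_response_grid <- function(img, bank = .default_filter_bank(), S = 8) {
  stopifnot(is_raster_image(img), inherits(bank, "filter_bank"))
  check_extractable(img)
  h <- img$height; w <- img$width
  planes <- list(
    lum = to_gray(img),
    rg = img$pixels[, , 1] - img$pixels[, , 2],
    by = img$pixels[, , 3] - (img$pixels[, , 1] + img$pixels[, , 2]) / 2
  )
  ffts <- lapply(planes, function(m) stats::fft(unclass(m)))
  otfs <- bank_otfs(bank, c(h, w))
  rcell <- pmin(floor((seq_len(h) - 1L) * S / h), S - 1L) + 1L
  ccell <- pmin(floor((seq_len(w) - 1L) * S / w), S - 1L) + 1L
  # column-major cell id so matrix(vapply(...), S, S) lands at [rcell, ccell]
  cell_id <- rep(rcell, times = w) + (rep(ccell, each = h) - 1L) * S
  cell_split <- split(seq_len(h * w), cell_id)
  nf <- length(otfs)
  resp <- array(0, dim = c(nf, S, S))
  for (k in seq_len(nf)) {
    a <- abs(corr_from_fft(ffts[[bank$plane[k]]], otfs[[k]]))
    resp[k, , ] <- matrix(vapply(cell_split, function(ii) max(a[ii]), numeric(1)),
                          S, S)
  }
  resp[resp < 1e-12] <- 0
  structure(list(responses = resp, mirror = bank$mirror, S = S,
                 bank_id = bank$id),
            class = "filter_grid")
}

#' Left-right and up-down symmetry scores
#'
#' Compares the pooled filter-response grid of the image with the grid of
#' its mirror image, computed by reversing the grid columns (left-right) or
#' rows (up-down) and swapping every filter with its orientation-mirrored
#' partner:
#' `sym = 1 - sum|G - M| / (sum|G| + sum|M|)`.
#' The score is 1 for a perfectly mirror-symmetric image and decreases as
#' the two halves diverge in colour, edge and texture content. A response
#' grid that is zero everywhere (featureless image) scores 1 with a
#' warning.
#'
#' @param img a [raster_image()] or a precomputed [filter_response_grid()].
#' @param bank a [filter_bank()].
#' @param S pooling grid size.
#' @return A one-row tibble with `sym_lr` and `sym_ud`, both in `[0, 1]`.
#' @export
symmetry_scores <- function(img, bank = .default_filter_bank(), S = 8) {
  grid <- if (inherits(img, "filter_grid")) img else filter_response_grid(img, bank, S)
  G <- grid$responses
  tot <- sum(abs(G))
  if (tot <= 0) {
    warning("featureless image: zero filter response, symmetry defined as 1", call. = FALSE)
    return(tibble::tibble(sym_lr = 1, sym_ud = 1))
  }
  S_ <- grid$S
  mir <- grid$mirror
  score <- function(M) 1 - sum(abs(G - M)) / (sum(abs(G)) + sum(abs(M)))
  M_lr <- G[mir, , S_:1, drop = FALSE]
  M_ud <- G[mir, S_:1, , drop = FALSE]
  tibble::tibble(sym_lr = score(M_lr), sym_ud = score(M_ud))
}

#' Response variances Pa and Pf of the pooled filter grid
#'
#' Responses are normalized per grid cell to sum 1 over filters (cells with
#' zero energy are excluded). With `a[f]` the mean normalized response of
#' filter `f` over cells: `var_pa` is the variance of `a` over filters (low
#' when many filters respond — "richness"), and `var_pf` is the mean over
#' filters of the variance of the normalized response across cells
#' (response variability between image sections).
#'
#' @param grid a [filter_response_grid()] (or a [raster_image()]).
#' @return A one-row tibble with `var_pa` and `var_pf` (both >= 0).
#' @export
cnn_variances <- function(grid) {
  if (is_raster_image(grid)) grid <- filter_response_grid(grid)
  stopifnot(inherits(grid, "filter_grid"))
  G <- grid$responses
  nf <- dim(G)[1]
  R <- matrix(G, nrow = nf) # filters x cells
  cell_tot <- colSums(R)
  if (sum(cell_tot) <= 0) stop("zero filter response: Pa/Pf undefined", call. = FALSE)
  R <- R[, cell_tot > 0, drop = FALSE]
  R <- sweep(R, 2, colSums(R), "/")
  a <- rowMeans(R)
  tibble::tibble(
    var_pa = stats::var(a),
    var_pf = mean(apply(R, 1, stats::var))
  )
}

#' Structural features of an image
#'
#' Convenience wrapper computing `self_similarity`, `sym_lr`, `sym_ud`,
#' `var_pa` and `var_pf` (the filter grid is computed once).
#'
#' @param img a [raster_image()].
#' @param bank a [filter_bank()].
#' @param S pooling grid size.
#' @return A one-row tibble.
#' @export
structure_stats <- function(img, bank = .default_filter_bank(), S = 8) {
  grid <- filter_response_grid(img, bank, S)
  sym <- symmetry_scores(grid)
  pv <- cnn_variances(grid)
  ss <- tryCatch(self_similarity(hog_pyramid(img)), error = function(e) NA_real_)
  tibble::tibble(self_similarity = ss, sym_lr = sym$sym_lr, sym_ud = sym$sym_ud,
                 var_pa = pv$var_pa, var_pf = pv$var_pf)
}
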