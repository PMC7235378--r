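# Synthetic images with controlled global properties, and study corpora
# whose ratings have a known linear dependence on the measured features.
# Every generator takes an explicit seed (Mersenne-Twister via set.seed)
# and is byte-deterministic given (parameters, seed).

#' Random-phase image with a power-law Fourier spectrum
#'
#' Builds an n x n grayscale image whose Fourier amplitude is exactly
#' `f^(exponent/2)` (so power follows `f^exponent`) with uniform random
#' phases, then rescales to `[0, 1]` and replicates to RGB. Natural scenes
#' have an exponent around -2.
#'
#' @param n side length, a power of two >= 64.
#' @param exponent generating power-spectrum exponent in `[-4, 0]`.
#' @param seed integer seed.
#' @return A [raster_image()].
#' @export
gen_powerlaw_image <- function(n = 256, exponent = -2, seed = 1) {
  stopifnot(n >= 64, (bitwAnd(n, n - 1L) == 0), exponent >= -4, exponent <= 0)
  set.seed(seed)
  w <- matrix(stats::rnorm(n * n), n)
  W <- stats::fft(w)
  f <- c(0:(n %/% 2), (n %/% 2 - 1):1)[seq_len(n)]
  fr <- sqrt(outer(f^2, f^2, "+"))
  amp <- ifelse(fr > 0, fr^(exponent / 2), 0)
  mw <- Mod(W); mw[mw == 0] <- 1
  Z <- W / mw * amp # unit-modulus phases, exact amplitudes, Hermitian
  img <- Re(stats::fft(Z, inverse = TRUE)) / (n * n)
  rng <- range(img)
  img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0 + 0.5
  raster_image(img, id = sprintf("powerlaw_e%+.2f_s%d", exponent, seed))
}

#' Sinusoidal grating
#'
#' @param n side length.
#' @param orientation_deg stripe (edge) orientation in degrees.
#' @param wavelength spatial wavelength in pixels.
#' @param contrast amplitude in `[0, 1]`.
#' @return A [raster_image()] (grayscale replicated to RGB).
#' @export
gen_grating <- function(n = 128, orientation_deg = 0, wavelength = 8,
                        contrast = 1) {
  phi <- (orientation_deg + 90) * pi / 180 # wave vector normal to stripes
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)
  g <- 0.5 + contrast / 2 * sin(2 * pi * (X * cos(phi) + Y * sin(phi)) / wavelength)
  raster_image(g, id = sprintf("grating_o%g_w%g", orientation_deg, wavelength))
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); mu/kappa on the
# full circle in radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Texture of oriented line segments
#'
#' Superposes anti-aliased line segments whose orientations are drawn from
#' a stated distribution: `"uniform"` over 0-180 degrees, `"vonmises"`
#' around `mu_deg` with concentration `kappa`, or `"single"` (all segments
#' at `mu_deg`). Supports the edge-orientation entropy tests: a uniform
#' distribution drives the first-order entropy towards its maximum, a
#' single orientation towards zero.
#'
#' @param n side length.
#' @param dist orientation distribution.
#' @param mu_deg mean orientation (degrees).
#' @param kappa von Mises concentration.
#' @param n_segments number of segments.
#' @param seg_len,thickness segment geometry in pixels.
#' @param seed integer seed.
#' @return A [raster_image()].
#' @export
gen_oriented_texture <- function(n = 256, dist = c("uniform", "vonmises", "single"),
                                 mu_deg = 90, kappa = 4, n_segments = 200,
                                 seg_len = n / 6, thickness = 1.2, seed = 1) {
  dist <- match.arg(dist)
  set.seed(seed)
  theta <- switch(dist,
    uniform = stats::runif(n_segments, 0, pi),
    vonmises = rvonmises(n_segments, mu = 2 * mu_deg * pi / 180, kappa = kappa) / 2,
    single = rep(mu_deg * pi / 180, n_segments)
  )
  canvas <- matrix(0.5, n, n)
  cx <- stats::runif(n_segments, 1, n)
  cy <- stats::runif(n_segments, 1, n)
  bright <- rep_len(c(0.95, 0.05), n_segments)
  half <- seg_len / 2
  for (s in seq_len(n_segments)) {
    dx <- cos(theta[s]); dy <- sin(theta[s])
    x0 <- cx[s] - half * dx; x1 <- cx[s] + half * dx
    y0 <- cy[s] - half * dy; y1 <- cy[s] + half * dy
    rlo <- max(1L, floor(min(y0, y1) - thickness - 1))
    rhi <- min(n, ceiling(max(y0, y1) + thickness + 1))
    clo <- max(1L, floor(min(x0, x1) - thickness - 1))
    chi <- min(n, ceiling(max(x0, x1) + thickness + 1))
    if (rlo > rhi || clo > chi) next
    X <- matrix(clo:chi, rhi - rlo + 1L, chi - clo + 1L, byrow = TRUE)
    Y <- matrix(rlo:rhi, rhi - rlo + 1L, chi - clo + 1L)
    # distance from pixel to the segment
    vx <- x1 - x0; vy <- y1 - y0
    tt <- pmin(pmax(((X - x0) * vx + (Y - y0) * vy) / (vx^2 + vy^2), 0), 1)
    d <- sqrt((X - (x0 + tt * vx))^2 + (Y - (y0 + tt * vy))^2)
    a <- pmin(pmax(thickness + 0.5 - d, 0), 1) # soft 1-px edge
    block <- canvas[rlo:rhi, clo:chi]
    canvas[rlo:rhi, clo:chi] <- block * (1 - a) + bright[s] * a
  }
  raster_image(canvas, id = sprintf("texture_%s_s%d", dist, seed))
}

#' Mirror an image
#'
#' @param img a [raster_image()].
#' @param axis `"lr"` (reverse columns) or `"ud"` (reverse rows).
#' @return A [raster_image()].
#' @export
mirror_image <- function(img, axis = c("lr", "ud")) {
  axis <- match.arg(axis)
  px <- img$pixels
  px <- if (axis == "lr") px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
        else px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
  raster_image(px, id = paste0(img$id, "_m", axis))
}

#' Blend an image towards its symmetrized self
#'
#' Pixelwise `(1 - w) * base + w * S(base)` with
#' `S(base) = (base + mirror(base)) / 2` the symmetrized image (equivalent
#' to blending a weight `w/2` of the pure mirror into the base). `w = 1`
#' yields an exactly mirror-symmetric image, `w = 0` the base unchanged,
#' and the symmetry score along the chosen axis is non-decreasing in `w`.
#'
#' @param base a [raster_image()].
#' @param axis mirror axis, `"lr"` or `"ud"`.
#' @param w blend weight in `[0, 1]`.
#' @return A [raster_image()].
#' @export
gen_mirrored_composite <- function(base, axis = c("lr", "ud"), w = 1) {
  axis <- match.arg(axis)
  stopifnot(w >= 0, w <= 1)
  m <- mirror_image(base, axis)
  raster_image((1 - w / 2) * base$pixels + (w / 2) * m$pixels,
               id = sprintf("%s_blend%s_w%.2f", base$id, axis, w))
}

#' Uniform colour field with slight noise
#'
#' @param n side length.
#' @param h,s,v target hue, saturation, value in `[0, 1]`.
#' @param noise value-channel noise SD (keeps gradients nonzero).
#' @param seed integer seed.
#' @return A [raster_image()].
#' @export
gen_colored_field <- function(n = 128, h = 0.3, s = 0.5, v = 0.6,
                              noise = 0.02, seed = 1) {
  set.seed(seed)
  col <- grDevices::col2rgb(grDevices::hsv(h, s, v)) / 255
  px <- array(rep(col, each = n * n), dim = c(n, n, 3))
  px <- px + array(stats::rnorm(n * n * 3, 0, noise), dim = dim(px))
  raster_image(pmin(pmax(px, 0), 1), id = sprintf("field_h%.2f_s%d", h, seed))
}

#' Tiled texture image
#'
#' Tiles one random texture patch into a `tiles x tiles` grid; every
#' sub-region of the result has the same gradient statistics as the whole,
#' giving high self-similarity.
#'
#' @param n side length (multiple of `tiles`).
#' @param tiles tiles per side.
#' @param noise SD of aperiodic pixel noise added after tiling (keeps the
#'   Fourier spectrum continuous; set 0 for an exactly periodic image).
#' @param seed integer seed.
#' @return A [raster_image()].
#' @export
gen_tiled_texture <- function(n = 128, tiles = 4, noise = 0.02, seed = 1) {
  stopifnot(n %% tiles == 0)
  set.seed(seed)
  m <- n %/% tiles
  patch <- matrix(stats::runif(m * m), m)
  patch <- (patch + patch[c(2:m, 1), ] + patch[, c(2:m, 1)]) / 3 # mild smoothing
  canvas <- matrix(0, n, n)
  for (i in 0:(tiles - 1)) for (j in 0:(tiles - 1)) {
    canvas[i * m + seq_len(m), j * m + seq_len(m)] <- patch
  }
  if (noise > 0) {
    canvas <- pmin(pmax(canvas + stats::rnorm(n * n, 0, noise), 0), 1)
  }
  raster_image(canvas, id = sprintf("tiled_%dx%d_s%d", tiles, tiles, seed))
}

#' Split-content image
#'
#' Left half and right half carry gratings of different orientation, so
#' sub-region gradient histograms differ from the global histogram (low
#' self-similarity counterpart to [gen_tiled_texture()]).
#'
#' @param n side length.
#' @param wavelength grating wavelength.
#' @return A [raster_image()].
#' @export
gen_split_content <- function(n = 128, wavelength = 8) {
  v <- gen_grating(n, 90, wavelength)$pixels[, , 1]
  h <- gen_grating(n, 0, wavelength)$pixels[, , 1]
  half <- n %/% 2
  canvas <- cbind(v[, seq_len(half)], h[, seq_len(n - half)])
  raster_image(canvas, id = sprintf("split_%d", n))
}

# One image from a recipe row of gen_study's mixed corpus.
.study_image <- function(kind, i, size, seed) {
  switch(kind,
    powerlaw = gen_powerlaw_image(size, exponent = -3.5 + 3 * ((i %% 7) / 6),
                                  seed = seed),
    grating = gen_grating(size, orientation_deg = (i * 37) %% 180,
                          wavelength = c(4, 6, 8, 12, 16)[(i %% 5) + 1]),
    texture = gen_oriented_texture(size, dist = c("uniform", "vonmises")[(i %% 2) + 1],
                                   mu_deg = (i * 53) %% 180,
                                   kappa = 1 + (i %% 4), seed = seed),
    mirrored = gen_mirrored_composite(gen_powerlaw_image(size, -2, seed = seed),
                                      axis = c("lr", "ud")[(i %% 2) + 1],
                                      w = (i %% 5) / 4),
    field = gen_colored_field(size, h = (i %% 10) / 10, s = 0.2 + 0.08 * (i %% 9),
                              v = 0.25 + 0.08 * (i %% 8), seed = seed),
    tiled = gen_tiled_texture(size, tiles = c(2, 4, 8)[(i %% 3) + 1], seed = seed),
    split = gen_mirrored_composite(gen_split_content(size,
                                     wavelength = c(6, 8, 12)[(i %% 3) + 1]),
                                   axis = "lr", w = (i %% 3) / 4)
  )
}

#' Generate a synthetic rating study
#'
#' Builds a mixed corpus of synthetic images (power-law noise, gratings,
#' oriented textures, mirrored composites, colour fields, tiled and
#' split-content images) spanning wide ranges of the thirteen properties,
#' extracts the real features with [extract_features()], and generates a
#' rating as a linear combination of the *measured*, sample-z-scored
#' features plus Gaussian noise, mapped affinely onto the rating scale.
#' Because ratings are built from measured features (not recipe targets),
#' the generating coefficients are recoverable exactly up to noise.
#'
#' @param n_images number of images (>= 100 for realistic studies; smaller
#'   corpora are allowed for quick checks).
#' @param betas named numeric vector of generating coefficients, keyed by
#'   feature names (missing names count as 0).
#' @param noise_sd SD of the Gaussian rating noise on the latent scale;
#'   ignored when `target_r2` is given.
#' @param target_r2 if given, the noise SD is set so the population R2 of
#'   the latent rating equals this value.
#' @param scale rating scale `c(lo, hi)` (default 1-9).
#' @param size image side length (default 128).
#' @param seed integer seed; per-image seeds are derived from it.
#' @param term rating term name.
#' @param keep_images keep the image objects in the result (memory-heavy).
#' @return An object of class `synthetic_study`: list with `features`
#'   (tibble), `ratings` (tibble id + term), `betas` (full 13-vector),
#'   `noise_sd`, `latent_sd`, `scale`, `seed`, and optionally `images`.
#' @export
gen_study <- function(n_images = 300, betas = c(s_mean = 0.5), noise_sd = 1,
                      target_r2 = NULL, scale = c(1, 9), size = 128,
                      seed = 1, term = "valence", keep_images = FALSE) {
  stopifnot(n_images >= 10, all(names(betas) %in% feature_names()))
  kinds <- rep_len(c("powerlaw", "grating", "texture", "mirrored", "field",
                     "tiled", "split"), n_images)
  ids <- sprintf("img%04d", seq_len(n_images))
  imgs <- vector("list", n_images)
  feats <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    img <- .study_image(kinds[i], i, size, seed = seed + 7L * i)
    img$id <- ids[i]
    feats[[i]] <- extract_features(list(img))
    if (keep_images) imgs[[i]] <- img
  }
  features <- dplyr::bind_rows(feats)
  b <- stats::setNames(numeric(13), feature_names())
  b[names(betas)] <- betas
  Z <- scale(as.matrix(features[, feature_names()]))
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  Z[is.na(Z)] <- 0
  signal <- as.numeric(Z %*% b)
  if (!is.null(target_r2)) {
    stopifnot(target_r2 > 0, target_r2 < 1)
    noise_sd <- stats::sd(signal) * sqrt((1 - target_r2) / target_r2)
  }
  set.seed(seed)
  latent <- signal + stats::rnorm(n_images, 0, noise_sd)
  half_range <- max(abs(latent - mean(latent)), 1e-12)
  rating <- mean(scale) + (latent - mean(latent)) * diff(scale) / (2 * half_range)
  ratings <- tibble::tibble(id = ids)
  ratings[[term]] <- rating
  out <- list(
    features = features, ratings = validate_ratings(ratings, scale = scale),
    betas = b, noise_sd = noise_sd, latent_sd = stats::sd(latent),
    signal = signal, z_features = Z, scale = scale, seed = seed, term = term,
    kinds = kinds
  )
  if (keep_images) out$images <- imgs
  structure(out, class = "synthetic_study")
}

#' Re-draw the ratings of a synthetic study with fresh noise
#'
#' Keeps the images, measured features and generating coefficients of a
#' [gen_study()] and re-draws only the Gaussian rating noise — the basis
#' for parameter-recovery replicates that do not re-extract features.
#'
#' @param study a `synthetic_study`.
#' @param seed integer seed for the new noise draw.
#' @return The study with a fresh `ratings` table.
#' @export
draw_ratings <- function(study, seed) {
  stopifnot(inherits(study, "synthetic_study"))
  set.seed(seed)
  latent <- study$signal + stats::rnorm(length(study$signal), 0, study$noise_sd)
  half_range <- max(abs(latent - mean(latent)), 1e-12)
  rating <- mean(study$scale) +
    (latent - mean(latent)) * diff(study$scale) / (2 * half_range)
  ratings <- tibble::tibble(id = study$features$id)
  ratings[[study$term]] <- rating
  study$ratings <- validate_ratings(ratings, scale = study$scale)
  study$latent_sd <- stats::sd(latent)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d images, term '%s', noise_sd %.3g, seed %d\n",
              nrow(x$features), x$term, x$noise_sd, x$seed))
  invisible(x)
}
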