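#' Construct a Gabor filter bank for edge extraction
#'
#' Odd-symmetric (edge-sensitive) Gabor kernels at `n_orientations` equally
#' spaced edge orientations over 0-180 degrees and one kernel per spatial
#' wavelength. Bandwidth is about one octave.
#'
#' @param n_orientations number of orientations (>= 8; default 24, i.e.
#'   7.5 degree steps).
#' @param wavelengths spatial wavelengths in pixels, ascending (default
#'   `c(4, 8, 16)`).
#' @return A list of class `gabor_bank` with `kernels`, `theta` (edge
#'   orientation in degrees), `lambda` and a cache `id`.
#' @export
gabor_bank <- function(n_orientations = 24, wavelengths = c(4, 8, 16)) {
  stopifnot(n_orientations >= 8, all(wavelengths > 0), !is.unsorted(wavelengths))
  theta <- seq(0, 180, length.out = n_orientations + 1L)[-(n_orientations + 1L)]
  grid <- expand.grid(theta = theta, lambda = wavelengths)
  kernels <- Map(function(t, l) gabor_kernel(t, l, phase = "odd"),
                 grid$theta, grid$lambda)
  structure(
    list(kernels = kernels, theta = grid$theta, lambda = grid$lambda,
         n_orientations = n_orientations,
         id = paste0("gb", n_orientations, "_", paste(wavelengths, collapse = "-"))),
    class = "gabor_bank"
  )
}

#' Gabor edge map of a grayscale image
#'
#' Filters the image with every kernel of the bank (FFT-based correlation,
#' circular boundary) and records, per pixel, the maximal absolute response
#' (`magnitude`) and the edge orientation of the winning filter
#' (`orientation`). Orientations are stored as the doubled filter angle,
#' `2 * theta` in `[0, 360)` degrees, so that the 180-degree periodicity of
#' unsigned edge orientation maps onto a full circle; a single grating
#' therefore occupies a single orientation, independent of contrast
#' polarity.
#'
#' @param gray matrix from [to_gray()] (or a [raster_image()]).
#' @param bank a [gabor_bank()].
#' @return A list of class `edge_map` with matrices `magnitude` (>= 0) and
#'   `orientation` (degrees in `[0, 360)`, meaningful where magnitude > 0).
#' @export
gabor_edge_map <- function(gray, bank = gabor_bank()) {
  gray <- as_gray(gray)
  stopifnot(is.matrix(gray), inherits(bank, "gabor_bank"))
  d <- dim(gray)
  otfs <- bank_otfs(bank, d)
  gf <- stats::fft(gray)
  mag <- matrix(0, d[1], d[2])
  ori <- matrix(0, d[1], d[2])
  for (k in seq_along(otfs)) {
    a <- abs(corr_from_fft(gf, otfs[[k]]))
    better <- a > mag
    if (any(better)) {
      mag[better] <- a[better]
      ori[better] <- (2 * bank$theta[k]) %% 360
    }
  }
  mag[mag < 1e-12] <- 0
  structure(list(magnitude = mag, orientation = ori), class = "edge_map")
}

#' Construct an edge map directly (for synthetic inputs)
#'
#' @param magnitude,orientation matrices of equal size; orientation in
#'   degrees `[0, 360)`.
#' @return An `edge_map`.
#' @export
edge_map <- function(magnitude, orientation) {
  stopifnot(is.matrix(magnitude), is.matrix(orientation),
            all(dim(magnitude) == dim(orientation)), all(magnitude >= 0))
  structure(list(magnitude = magnitude, orientation = orientation %% 360),
            class = "edge_map")
}

#' Edge density of an image
#'
#' Sum of all edge-map magnitudes divided by the pixel count, times 1000.
#' The x1000 scale constant makes typical values order-1 to order-100; the
#' absolute scale is implementation-defined (it depends on the filter
#' normalization), so only comparisons within one configuration are
#' meaningful.
#'
#' @param edges an `edge_map` (or a [raster_image()], filtered with the
#'   default bank).
#' @return A non-negative scalar.
#' @export
edge_density <- function(edges) {
  if (is_raster_image(edges)) edges <- gabor_edge_map(to_gray(edges))
  stopifnot(inherits(edges, "edge_map"))
  1000 * sum(edges$magnitude) / length(edges$magnitude)
}

#' Magnitude-weighted histogram of edge orientations
#'
#' @param edges an `edge_map`.
#' @param B number of equal angular bins over 360 degrees (default 24).
#' @return A tibble with columns `bin` (1..B), `angle_lo`, `angle_hi` and
#'   `mass` (non-negative, summing to 1).
#' @export
orientation_histogram <- function(edges, B = 24) {
  stopifnot(inherits(edges, "edge_map"), B >= 8)
  w <- as.vector(edges$magnitude)
  if (sum(w) <= 0) stop("no edges: total edge magnitude is zero", call. = FALSE)
  bin <- floor((as.vector(edges$orientation) %% 360) / (360 / B)) + 1L
  bin[bin > B] <- B
  mass <- vapply(split(w, factor(bin, levels = seq_len(B))), sum, numeric(1))
  mass <- unname(mass) / sum(mass)
  tibble::tibble(
    bin = seq_len(B),
    angle_lo = (seq_len(B) - 1) * 360 / B,
    angle_hi = seq_len(B) * 360 / B,
    mass = mass
  )
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order edge-orientation entropy
#'
#' Shannon entropy (bits) of the magnitude-weighted edge-orientation
#' distribution: maximal (`log2 B`) when all orientations are represented
#' at equal strength, smaller when particular orientations predominate.
#'
#' @param h an orientation histogram from [orientation_histogram()], or an
#'   `edge_map` / [raster_image()] (converted with `B` bins).
#' @param B bins used when `h` is not already a histogram.
#' @return Entropy in bits, in `[0, log2(B)]`.
#' @export
first_order_entropy <- function(h, B = 24) {
  if (is_raster_image(h)) h <- gabor_edge_map(to_gray(h))
  if (inherits(h, "edge_map")) h <- orientation_histogram(h, B = B)
  stopifnot(is.data.frame(h), "mass" %in% names(h))
  shannon_bits(h$mass)
}

#' Second-order edge-orientation entropy
#'
#' Measures how unpredictable edge orientations are across image positions.
#' The `n_top` strongest edge elements are selected (ties broken by row,
#' then column order); for each distance annulus, a `B`-bin histogram of
#' pairwise orientation differences (orientation at position j minus
#' orientation at position i, modulo 360) is accumulated over all ordered
#' pairs whose separation falls in the annulus. The result is the mean
#' Shannon entropy over annuli with at least 100 pairs: close to `log2 B`
#' when orientations at different positions are mutually unpredictable, 0
#' when a single orientation dominates everywhere.
#'
#' @param edges an `edge_map` (or [raster_image()]).
#' @param B orientation-difference bins (default 24).
#' @param n_top number of strongest edge elements to use (default 10000).
#' @param annuli outer radii (pixels) of the distance annuli; annulus i is
#'   `(annuli[i-1], annuli[i]]` with an implicit inner edge at 0.
#' @return Entropy in bits, in `[0, log2(B)]`.
#' @export
second_order_entropy <- function(edges, B = 24, n_top = 10000,
                                 annuli = c(20, 40, 80, 160)) {
  if (is_raster_image(edges)) edges <- gabor_edge_map(to_gray(edges))
  stopifnot(inherits(edges, "edge_map"), B >= 8, length(annuli) >= 1,
            !is.unsorted(annuli), all(annuli > 0))
  m <- edges$magnitude
  nz <- which(m > 0)
  if (length(nz) < 2) stop("image too sparse: fewer than 2 edge elements", call. = FALSE)
  nr <- nrow(m)
  rows <- ((nz - 1L) %% nr) + 1L
  cols <- ((nz - 1L) %/% nr) + 1L
  # strongest first; deterministic tie-break by (row, column)
  ord <- order(-m[nz], rows, cols)
  take <- utils::head(ord, n_top)
  counts <- cpp_pair_orientation_hist(
    as.numeric(rows[take]), as.numeric(cols[take]),
    as.numeric(edges$orientation[nz][take]),
    as.numeric(annuli), as.integer(B)
  )
  n_pairs <- rowSums(counts)
  use <- n_pairs >= 100
  if (!any(use)) stop("image too sparse: fewer than 100 pairs in every annulus", call. = FALSE)
  ent <- vapply(which(use), function(i) shannon_bits(counts[i, ] / n_pairs[i]), numeric(1))
  mean(ent)
}

#' Edge-based features of an image
#'
#' Convenience wrapper computing `edge_density`, `entropy1` and `entropy2`
#' from a single Gabor edge map.
#'
#' @param img a [raster_image()].
#' @param bank a [gabor_bank()].
#' @param B orientation bins for both entropies.
#' @param n_top strongest elements used by the second-order entropy.
#' @return A one-row tibble with `edge_density`, `entropy1`, `entropy2`.
#' @export
edge_stats <- function(img, bank = gabor_bank(), B = 24, n_top = 10000) {
  em <- gabor_edge_map(to_gray(img), bank)
  ed <- edge_density(em)
  if (sum(em$magnitude) <= 0) {
    return(tibble::tibble(edge_density = 0, entropy1 = NA_real_, entropy2 = NA_real_))
  }
  tibble::tibble(
    edge_density = ed,
    entropy1 = first_order_entropy(em, B = B),
    entropy2 = second_order_entropy(em, B = B, n_top = n_top)
  )
}
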