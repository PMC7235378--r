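#' Pad a grayscale image to a square by mirror reflection
#'
#' The shorter dimension is extended to `max(H, W)` by reflecting the image
#' content outward, split evenly between the two sides. Mirror padding is
#' used (rather than zeros) because zero padding injects spurious
#' high-frequency energy at the seams.
#'
#' @param gray H x W numeric matrix in `[0, 1]` (see [to_gray()]).
#' @return An N x N matrix with `N = max(H, W)`.
#' @export
pad_to_square <- function(gray) {
  gray <- as_gray(gray)
  stopifnot(is.matrix(gray))
  h <- nrow(gray); w <- ncol(gray)
  n <- max(h, w)
  reflect_idx <- function(len, total) {
    # centred: `len` source rows/cols extended to `total` by reflection
    pad <- total - len
    lo <- pad %/% 2L
    idx <- seq_len(total) - lo
    # fold indices into 1..len by repeated reflection about the edges
    period <- 2L * len
    idx <- ((idx - 1L) %% period) + 1L
    idx[idx > len] <- period - idx[idx > len] + 1L
    idx
  }
  out <- gray[reflect_idx(h, n), reflect_idx(w, n), drop = FALSE]
  structure(out, class = c("gray_image", "matrix", "array"))
}

# radius (cycles/image) of every FFT bin of an n x n grid; cached.
.radius_cache <- new.env(parent = emptyenv())
fft_radius <- function(n) {
  key <- as.character(n)
  got <- .radius_cache[[key]]
  if (!is.null(got)) return(got)
  f <- c(0:(n %/% 2), if (n %% 2 == 0) (n %/% 2 - 1):1 else ((n - 1) %/% 2):1)
  f <- f[seq_len(n)]
  r <- round(sqrt(outer(f^2, f^2, "+")))
  .radius_cache[[key]] <- r
  r
}

#' Radially averaged Fourier power spectrum
#'
#' Computes the 2-D power spectrum `|FFT|^2` of a square grayscale image
#' and averages it over annuli of integer radius 1 ... N/2
#' cycles/image. The DC term is excluded, so the spectrum is invariant to
#' adding a constant to the image.
#'
#' @param gray square N x N matrix, `N >= 32` (use [pad_to_square()] first
#'   for non-square images).
#' @return A tibble with columns `freq` (cycles/image, ascending) and
#'   `power` (mean spectral power in the annulus); attribute `n` records N.
#' @export
radial_average_power <- function(gray) {
  gray <- as_gray(gray)
  stopifnot(is.matrix(gray))
  n <- nrow(gray)
  if (ncol(gray) != n) stop("radial_average_power() needs a square image; use pad_to_square()", call. = FALSE)
  if (n < 32) stop("image too small for spectral fit (need N >= 32, got ", n, ")", call. = FALSE)
  p <- Mod(stats::fft(gray))^2
  r <- fft_radius(n)
  rmax <- n %/% 2
  keep <- r >= 1 & r <= rmax
  sums <- rowsum(p[keep], r[keep])
  counts <- rowsum(rep(1, sum(keep)), r[keep])
  out <- tibble::tibble(
    freq = as.numeric(rownames(sums)),
    power = as.numeric(sums / counts)
  )
  out <- out[order(out$freq), ]
  attr(out, "n") <- n
  out
}

#' Fit a line to the radially averaged spectrum in log-log space
#'
#' Data points are binned into `n_bins` equal intervals of log10 frequency
#' over the fit range; within each bin the mean log10 power and mean log10
#' frequency are taken, and an ordinary least-squares line is fitted
#' through the bin means. The slope of that line is the Fourier slope
#' (around -2 for natural scenes); the mean squared residual of the binned
#' points about the line is the Fourier sigma.
#'
#' The default fit range is `[5, N/4]` cycles/image: the lowest frequencies
#' are dominated by global layout, and the highest octave by pixel-level
#' aliasing.
#'
#' @param spec tibble from [radial_average_power()].
#' @param n_bins number of equal log-width frequency bins (default 20).
#' @param f_lo,f_hi fit range in cycles/image; `f_hi = NULL` means N/4.
#' @return A list of class `spectral_fit` with `slope`, `sigma`,
#'   `n_bins` (non-empty bins used) and `fit_range`.
#' @export
fit_loglog <- function(spec, n_bins = 20, f_lo = 5, f_hi = NULL) {
  stopifnot(is.data.frame(spec), all(c("freq", "power") %in% names(spec)))
  fr <- spec$freq
  if (log10(max(fr) / min(fr)) < 1.5) {
    stop("image too small for spectral fit (spectrum spans < 1.5 decades)", call. = FALSE)
  }
  if (is.null(f_hi)) {
    n <- attr(spec, "n")
    f_hi <- if (!is.null(n)) n / 4 else max(fr) / 2
  }
  keep <- fr >= f_lo & fr <= f_hi & spec$power > 0
  lf <- log10(fr[keep]); lp <- log10(spec$power[keep])
  edges <- seq(log10(f_lo), log10(f_hi), length.out = n_bins + 1L)
  bin <- findInterval(lf, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
  xb <- as.numeric(tapply(lf, bin, mean))
  yb <- as.numeric(tapply(lp, bin, mean))
  used <- length(xb)
  if (used < 8) stop("spectral fit failed: fewer than 8 non-empty bins", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, xb), yb)
  sigma <- sum(fit$residuals^2) / used
  structure(
    list(slope = unname(fit$coefficients[2]), sigma = sigma,
         n_bins = used, fit_range = c(f_lo, f_hi)),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> slope = %.4f, sigma = %.3g (%d bins over [%g, %g] cyc/img)\n",
              x$slope, x$sigma, x$n_bins, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Fourier slope and sigma of an image
#'
#' Convenience wrapper: grayscale conversion, mirror padding to a square,
#' radial averaging of the power spectrum and the binned log-log line fit.
#'
#' @param img a [raster_image()] or grayscale matrix.
#' @inheritParams fit_loglog
#' @return A one-row tibble with `fourier_slope` and `fourier_sigma`.
#' @export
fourier_stats <- function(img, n_bins = 20, f_lo = 5, f_hi = NULL) {
  g <- pad_to_square(as_gray(img))
  fit <- fit_loglog(radial_average_power(g), n_bins = n_bins, f_lo = f_lo, f_hi = f_hi)
  tibble::tibble(fourier_slope = fit$slope, fourier_sigma = fit$sigma)
}
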