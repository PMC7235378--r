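# FFT-based correlation with circular boundary handling. Kernel transfer
# functions are cached per (image size, bank id) because the extractor is
# called once per image over corpora of hundreds of images.

.otf_cache <- new.env(parent = emptyenv())

# Embed a centred odd-sized kernel at the origin of a d[1] x d[2] grid
# (wrapping negative offsets) and return its FFT.
kernel_otf <- function(kernel, d) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh > d[1] || kw > d[2]) {
    # crop the kernel centrally for images smaller than its support
    keep_r <- min(kh, d[1]); keep_c <- min(kw, d[2])
    r0 <- (kh - keep_r) %/% 2L; c0 <- (kw - keep_c) %/% 2L
    kernel <- kernel[r0 + seq_len(keep_r), c0 + seq_len(keep_c), drop = FALSE]
    kernel <- kernel - mean(kernel) # keep the kernel DC-free after cropping
    kh <- keep_r; kw <- keep_c
  }
  big <- matrix(0, d[1], d[2])
  rc <- (kh + 1L) %/% 2L; cc <- (kw + 1L) %/% 2L
  ri <- ((seq_len(kh) - rc) %% d[1]) + 1L
  ci <- ((seq_len(kw) - cc) %% d[2]) + 1L
  big[ri, ci] <- kernel
  stats::fft(big)
}

bank_otfs <- function(bank, d) {
  key <- paste0(bank$id, "_", d[1], "x", d[2])
  got <- .otf_cache[[key]]
  if (!is.null(got)) return(got)
  otfs <- lapply(bank$kernels, kernel_otf, d = d)
  # keep the cache small: drop older entries beyond a handful of sizes
  if (length(ls(.otf_cache)) > 6L) rm(list = ls(.otf_cache)[1L], envir = .otf_cache)
  .otf_cache[[key]] <- otfs
  otfs
}

# Cross-correlation of a real matrix with one kernel, given the image FFT
# and the kernel OTF: resp(x) = sum_u img(x + u) k(u).
corr_from_fft <- function(img_fft, otf) {
  Re(stats::fft(img_fft * Conj(otf), inverse = TRUE)) / length(img_fft)
}

# Odd- or even-symmetric Gabor kernel. `theta_deg` is the EDGE orientation
# (stripe direction); the carrier wave vector is perpendicular to it.
# Bandwidth ~1 octave gives sigma ~= 0.56 * wavelength.
gabor_kernel <- function(theta_deg, wavelength, phase = c("odd", "even"),
                         sigma = 0.56 * wavelength, gamma = 0.5) {
  phase <- match.arg(phase)
  phi <- (theta_deg + 90) * pi / 180 # wave-vector direction
  half <- max(3L, ceiling(2.5 * sigma))
  xs <- -half:half
  X <- matrix(xs, length(xs), length(xs), byrow = TRUE)  # column offset
  Y <- matrix(xs, length(xs), length(xs))                # row offset
  xr <- X * cos(phi) + Y * sin(phi)
  yr <- -X * sin(phi) + Y * cos(phi)
  env <- exp(-(xr^2 + (gamma * yr)^2) / (2 * sigma^2))
  k <- if (phase == "odd") env * sin(2 * pi * xr / wavelength)
       else env * cos(2 * pi * xr / wavelength)
  k <- k - mean(k) # DC-free
  k / sqrt(sum(k^2))
}
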