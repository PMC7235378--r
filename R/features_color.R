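#' Mean HSV channel values of an image
#'
#' Converts every pixel from RGB to HSV (standard hexcone model, hue scaled
#' to `[0, 1]`) and takes the arithmetic mean of each channel over all
#' pixels. Hue is averaged arithmetically on `[0, 1]` — not circularly — to
#' mirror the conventional rgb2hsv-then-mean procedure; achromatic pixels
#' (saturation 0) contribute hue 0. A circular hue mean is available via
#' `circular_hue = TRUE` for sensitivity checks.
#'
#' @param img a [raster_image()].
#' @param circular_hue if `TRUE`, the hue mean is the direction of the
#'   resultant vector of hues on the colour circle (still in `[0, 1]`).
#' @return A one-row tibble with columns `h_mean`, `s_mean`, `v_mean`,
#'   each in `[0, 1]`.
#' @export
hsv_means <- function(img, circular_hue = FALSE) {
  stopifnot(is_raster_image(img))
  check_extractable(img)
  rgb <- rbind(
    as.vector(img$pixels[, , 1]),
    as.vector(img$pixels[, , 2]),
    as.vector(img$pixels[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- if (circular_hue) {
    ang <- hsv[1, ] * 2 * pi
    m <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)
    if (m < 0) m <- m + 1
    m
  } else {
    mean(hsv[1, ])
  }
  tibble::tibble(h_mean = h, s_mean = mean(hsv[2, ]), v_mean = mean(hsv[3, ]))
}
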