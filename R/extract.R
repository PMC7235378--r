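#' Extract the thirteen global image properties
#'
#' Runs the whole feature battery on a set of images: mean HSV channels,
#' left-right/up-down symmetry, Gabor edge density, PHOG self-similarity,
#' Fourier slope and sigma, first- and second-order edge-orientation
#' entropies, and the filter-response variances Pa and Pf. All features
#' except self-similarity (which resizes to ~100,000 pixels by definition)
#' are computed at native resolution; image size is recorded in the output.
#'
#' @param images one of: a character vector of image paths, a directory
#'   containing images, or a list of [raster_image()] objects.
#' @param gabor a [gabor_bank()] for the edge features.
#' @param bank a [filter_bank()] for symmetry and Pa/Pf.
#' @param B orientation bins for the entropies (default 24).
#' @param n_top strongest edge elements for the second-order entropy.
#' @param n_bins log-frequency bins for the spectral fit.
#' @param progress print a message per image.
#' @return A tibble with columns `id`, the 13 features (see
#'   [feature_names()]), `width` and `height`. Images that fail to process
#'   yield a row of NAs and are listed in the `failures` attribute; the run
#'   continues.
#' @export
extract_features <- function(images, gabor = gabor_bank(),
                             bank = .default_filter_bank(),
                             B = 24, n_top = 10000, n_bins = 20,
                             progress = FALSE) {
  if (is.character(images)) {
    if (length(images) == 1L && dir.exists(images)) {
      images <- list.files(images, pattern = "\\.(png|jpe?g|tiff?)$",
                           ignore.case = TRUE, full.names = TRUE)
    }
    ids <- sub("\\.[^.]+$", "", basename(images))
    loader <- function(i) load_image(images[[i]], id = ids[[i]])
    n <- length(images)
  } else if (is_raster_image(images)) {
    images <- list(images)
    loader <- function(i) images[[i]]
    ids <- images[[1]]$id
    n <- 1L
  } else {
    stopifnot(is.list(images), all(vapply(images, is_raster_image, logical(1))))
    loader <- function(i) images[[i]]
    ids <- vapply(images, `[[`, character(1), "id")
    n <- length(images)
  }
  failures <- character(0)
  one <- function(i) {
    img <- loader(i)
    em <- gabor_edge_map(to_gray(img), gabor)
    grid <- filter_response_grid(img, bank)
    sym <- symmetry_scores(grid)
    pv <- cnn_variances(grid)
    dplyr::bind_cols(
      hsv_means(img),
      sym,
      tibble::tibble(
        edge_density = edge_density(em),
        self_similarity = self_similarity(hog_pyramid(img))
      ),
      fourier_stats(img, n_bins = n_bins),
      tibble::tibble(
        entropy1 = first_order_entropy(em, B = B),
        entropy2 = second_order_entropy(em, B = B, n_top = n_top)
      ),
      pv,
      tibble::tibble(width = img$width, height = img$height)
    )
  }
  na_row <- tibble::as_tibble(stats::setNames(
    as.list(rep(NA_real_, 15L)), c(feature_names(), "width", "height")
  ))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (progress) message("extracting features: ", ids[[i]], " (", i, "/", n, ")")
    rows[[i]] <- tryCatch(one(i), error = function(e) {
      warning("feature extraction failed for '", ids[[i]], "': ",
              conditionMessage(e), call. = FALSE)
      failures <<- c(failures, ids[[i]])
      na_row
    })
  }
  out <- dplyr::bind_cols(tibble::tibble(id = as.character(ids)),
                          dplyr::bind_rows(rows))
  out <- out[, c("id", feature_names(), "width", "height")]
  attr(out, "failures") <- failures
  out
}
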