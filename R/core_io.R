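#' Construct a raster image
#'
#' The unit every feature extractor consumes: an H x W x 3 array of RGB
#' values in `[0, 1]` plus an id label. Extractors reject images smaller
#' than 8 x 8 pixels.
#'
#' @param pixels numeric H x W x 3 array (RGB) or H x W matrix (grayscale,
#'   replicated to three identical channels), all values in `[0, 1]`.
#' @param id character label for the image.
#' @return An object of class `raster_image` with elements `pixels`,
#'   `width`, `height`, `id`.
#' @export
raster_image <- function(pixels, id = "image") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("pixel values of '", id, "' must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(pixels = pmin(pmax(pixels, 0), 1), width = w, height = h, id = id),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat("<raster_image> '", x$id, "' ", x$height, "x", x$width, " RGB\n", sep = "")
  invisible(x)
}

is_raster_image <- function(x) inherits(x, "raster_image")

# Extractors reject degenerate images below 8x8 pixels.
check_extractable <- function(img) {
  if (img$width < 8L || img$height < 8L) {
    stop("degenerate image '", img$id, "': extractors need at least 8x8 ",
         "pixels, got ", img$height, "x", img$width, call. = FALSE)
  }
  invisible(img)
}

#' Load a raster image from disk
#'
#' Reads PNG, JPEG or TIFF files (RGB, RGBA or grayscale). Values are
#' rescaled to `[0, 1]`; an alpha channel is discarded; grayscale sources
#' are replicated to three identical channels. BMP is not supported.
#'
#' @param path path to the image file.
#' @param id id to assign; default is the file name without extension.
#' @return A [raster_image()].
#' @export
load_image <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read image: no such file '", path, "'", call. = FALSE)
  if (grepl("\\.bmp$", path, ignore.case = TRUE)) {
    stop("unsupported image format for '", path, "': BMP is not supported, ",
         "use PNG, JPEG or TIFF", call. = FALSE)
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) stop("failed to decode image '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  px <- EBImage::imageData(img) # EBImage stores width x height (x channels)
  if (length(dim(px)) == 2L) {
    px <- aperm(px, c(2L, 1L)) # -> H x W
  } else {
    nc <- dim(px)[3]
    if (nc >= 4L) px <- px[, , 1:3, drop = FALSE] # drop alpha
    if (dim(px)[3] == 1L) px <- px[, , 1L]
    if (length(dim(px)) == 3L) px <- aperm(px, c(2L, 1L, 3L)) else px <- aperm(px, c(2L, 1L))
  }
  px <- pmin(pmax(px, 0), 1)
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  raster_image(px, id = id)
}

#' Write a raster image to disk
#'
#' @param img a [raster_image()].
#' @param path output path; format from extension (png, jpeg, tiff).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is_raster_image(img))
  arr <- aperm(img$pixels, c(2L, 1L, 3L)) # EBImage expects width x height
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  invisible(path)
}

#' Convert an image to grayscale luminance
#'
#' ITU-R BT.601 luma weights: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img a [raster_image()].
#' @return An H x W numeric matrix in `[0, 1]` (class `gray_image`).
#' @export
to_gray <- function(img) {
  stopifnot(is_raster_image(img))
  g <- 0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] + 0.114 * img$pixels[, , 3]
  structure(g, class = c("gray_image", class(g)))
}

as_gray <- function(x) {
  if (is_raster_image(x)) to_gray(x) else x
}

#' Downscale an image to a target pixel count
#'
#' Preserves the aspect ratio and resizes by bilinear interpolation so the
#' output area is within 2% of `target_pixels`. Images already at or below
#' the target are returned unchanged (no upsampling).
#'
#' @param img a [raster_image()].
#' @param target_pixels target number of pixels (width x height), >= 64.
#' @return A [raster_image()].
#' @export
resize_to_area <- function(img, target_pixels = 1e5) {
  stopifnot(is_raster_image(img), target_pixels >= 64)
  n <- img$width * img$height
  if (n <= target_pixels) return(img)
  s <- sqrt(target_pixels / n)
  new_h <- max(8L, round(img$height * s))
  new_w <- max(8L, round(img$width * s))
  arr <- aperm(img$pixels, c(2L, 1L, 3L))
  out <- EBImage::resize(EBImage::Image(arr, colormode = "Color"),
                         w = new_w, h = new_h, filter = "bilinear")
  raster_image(aperm(EBImage::imageData(out), c(2L, 1L, 3L)), id = img$id)
}

#' Read a table of affective ratings
#'
#' Expects delimited text (comma or tab) with a header row containing an
#' `id` column; every other numeric column is treated as a rating term
#' (e.g. valence, arousal). Duplicate ids and ratings outside the declared
#' scale are validation errors; missing cells are kept and flagged.
#'
#' @param path path to the delimited file.
#' @param scale optional length-2 numeric `c(min, max)` applied to all
#'   rating terms (e.g. `c(1, 9)`).
#' @return A tibble with column `id` and one column per rating term;
#'   attributes `scale_min` / `scale_max` record the scale.
#' @export
read_ratings <- function(path, scale = NULL) {
  if (!file.exists(path)) stop("cannot read ratings: no such file '", path, "'", call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_ratings(tbl, scale = scale)
}

#' Validate a ratings table
#'
#' @param tbl data frame with an `id` column and numeric rating columns.
#' @inheritParams read_ratings
#' @return The validated tibble (see [read_ratings()]).
#' @export
validate_ratings <- function(tbl, scale = NULL) {
  tbl <- tibble::as_tibble(tbl)
  if (!"id" %in% names(tbl)) stop("ratings table must contain an 'id' column", call. = FALSE)
  tbl$id <- as.character(tbl$id)
  dup <- tbl$id[duplicated(tbl$id)]
  if (length(dup)) {
    stop("duplicate image ids in ratings table: ",
         paste(utils::head(unique(dup), 5), collapse = ", "), call. = FALSE)
  }
  terms <- setdiff(names(tbl), "id")
  terms <- terms[vapply(tbl[terms], is.numeric, logical(1))]
  if (!length(terms)) stop("ratings table has no numeric rating columns", call. = FALSE)
  n_missing <- sum(is.na(tbl[terms]))
  if (n_missing > 0) {
    warning(n_missing, " missing rating value(s) kept as NA", call. = FALSE)
  }
  if (!is.null(scale)) {
    stopifnot(length(scale) == 2, scale[1] < scale[2])
    for (tm in terms) {
      bad <- which(!is.na(tbl[[tm]]) & (tbl[[tm]] < scale[1] | tbl[[tm]] > scale[2]))
      if (length(bad)) {
        stop("rating '", tm, "' outside declared scale [", scale[1], ", ",
             scale[2], "] for id(s): ",
             paste(utils::head(tbl$id[bad], 5), collapse = ", "), call. = FALSE)
      }
    }
    attr(tbl, "scale_min") <- scale[1]
    attr(tbl, "scale_max") <- scale[2]
  }
  attr(tbl, "rating_terms") <- terms
  tbl
}

#' Names of the thirteen global image properties
#'
#' @return Character vector of the 13 feature column names.
#' @export
feature_names <- function() {
  c("h_mean", "s_mean", "v_mean", "sym_lr", "sym_ud", "edge_density",
    "self_similarity", "fourier_slope", "fourier_sigma", "entropy1",
    "entropy2", "var_pa", "var_pf")
}

#' Write / read a feature table
#'
#' Feature tables are written as CSV with an `id` column plus exactly the
#' thirteen feature columns (and any extra metadata columns such as image
#' size). Values round-trip through text to at least 12 significant digits.
#'
#' @param features tibble with `id` and the 13 feature columns.
#' @param path output path.
#' @return `path` invisibly for `write_features`; a tibble for
#'   `read_features`.
#' @export
write_features <- function(features, path) {
  stopifnot(is.data.frame(features), "id" %in% names(features))
  missing <- setdiff(feature_names(), names(features))
  if (length(missing)) {
    stop("feature table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tbl$id <- as.character(tbl$id)
  missing <- setdiff(feature_names(), names(tbl))
  if (length(missing)) {
    stop("feature file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl
}
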