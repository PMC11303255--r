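#' Calibrated multi-channel image
#'
#' A lightweight container for a 2D multi-channel fluorescence micrograph with
#' a physical pixel size. Channels are stored as numeric matrices indexed
#' `[row = y, col = x]`; the centre of pixel `(i, j)` sits at physical
#' coordinates `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)` in µm, so
#' sub-pixel sampling is unambiguous.
#'
#' @param channels Named list of numeric matrices, all the same dimension.
#' @param pixel_size Physical pixel size in µm/px (default 0.031, the
#'   acquisition scale of a 100x/1.5 NA confocal at high zoom).
#' @param bit_depth Acquisition bit depth; the saturation level is
#'   `2^bit_depth - 1` (4095 for 12-bit data).
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(channels, pixel_size = 0.031, bit_depth = 12) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of matrices", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1)))) {
    stop("every channel must be a matrix", call. = FALSE)
  }
  if (length(unique(lapply(dims, identity))) != 1) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be > 0", call. = FALSE)
  }
  structure(
    list(
      channels = channels,
      pixel_size = pixel_size,
      bit_depth = bit_depth,
      saturation_level = 2^bit_depth - 1
    ),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<calibrated_image> %d x %d px, %.4g um/px, %d-bit, channels: %s\n",
    d[1], d[2], x$pixel_size, x$bit_depth,
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname calibrated_image
#' @param x An object.
#' @export
is_calibrated_image <- function(x) inherits(x, "calibrated_image")

#' Extract a channel matrix
#'
#' @param image A [calibrated_image()].
#' @param channel Channel name.
#' @return The channel matrix.
#' @export
img_channel <- function(image, channel) {
  stopifnot(is_calibrated_image(image))
  if (!channel %in% names(image$channels)) {
    stop(sprintf("channel '%s' not found (have: %s)", channel,
                 paste(names(image$channels), collapse = ", ")), call. = FALSE)
  }
  image$channels[[channel]]
}

# Bilinear interpolation of `mat` at physical coordinates (x, y) in um.
# Pixel centres at ((j - 0.5) px, (i - 0.5) px). Coordinates are clamped to
# the centre grid so samples half a pixel from the border stay defined.
bilinear_sample <- function(mat, x_um, y_um, pixel_size) {
  nr <- nrow(mat); nc <- ncol(mat)
  cx <- x_um / pixel_size - 0.5   # 0-based column coordinate of sample
  cy <- y_um / pixel_size - 0.5
  cx <- pmin(pmax(cx, 0), nc - 1)
  cy <- pmin(pmax(cy, 0), nr - 1)
  j0 <- pmin(floor(cx), nc - 2); i0 <- pmin(floor(cy), nr - 2)
  fx <- cx - j0; fy <- cy - i0
  # 1-based matrix indices
  i1 <- i0 + 1; j1 <- j0 + 1
  v00 <- mat[cbind(i1, j1)]
  v01 <- mat[cbind(i1, j1 + 1)]
  v10 <- mat[cbind(i1 + 1, j1)]
  v11 <- mat[cbind(i1 + 1, j1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Pixelwise Pearson overlap between two channels
#'
#' Standard Pearson correlation of two channels over a pixel mask, the
#' colocalization statistic used to show that astrocytic markers correlate
#' with each other but not with the WFA-labelled net.
#'
#' @param image A [calibrated_image()].
#' @param chA,chB Channel names.
#' @param mask Optional logical matrix selecting pixels; `NULL` uses all.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_overlap <- function(image, chA, chB, mask = NULL) {
  a <- img_channel(image, chA)
  b <- img_channel(image, chB)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  stopifnot(identical(dim(mask), dim(a)))
  va <- a[mask]; vb <- b[mask]
  if (length(va) < 2) stop("mask selects fewer than 2 pixels", call. = FALSE)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero-variance channel in mask: correlation undefined", call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Read / write a calibrated image as multi-page TIFF
#'
#' Channels are written as pages of one TIFF, intensities scaled to `[0, 1]`
#' by the saturation level as the TIFF format expects; the calibration
#' (pixel size, bit depth, channel names) travels in a JSON sidecar
#' `<path>.json` because baseline TIFF tags cannot carry it portably.
#'
#' @param image A [calibrated_image()].
#' @param path File path (`.tif`).
#' @return `write_image_tiff()` returns `path` invisibly; `read_image_tiff()`
#'   returns a [calibrated_image()].
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(is_calibrated_image(image))
  sat <- image$saturation_level
  pages <- lapply(image$channels, function(m) pmin(pmax(m / sat, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(
    pixel_size = image$pixel_size,
    bit_depth = image$bit_depth,
    channel_names = names(image$channels)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @param pixel_size,bit_depth,channel_names Overrides used when no JSON
#'   sidecar is present.
#' @export
read_image_tiff <- function(path, pixel_size = NULL, bit_depth = 12,
                            channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size
    bit_depth <- meta$bit_depth
    if (is.null(channel_names)) channel_names <- meta$channel_names
  }
  if (is.null(pixel_size)) {
    stop("pixel_size not supplied and no sidecar metadata found", call. = FALSE)
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_along(pages))
  sat <- 2^bit_depth - 1
  channels <- stats::setNames(lapply(pages, function(m) m * sat), channel_names)
  calibrated_image(channels, pixel_size = pixel_size, bit_depth = bit_depth)
}
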