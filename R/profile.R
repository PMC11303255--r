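#' Line-intensity profiles along a closed contour
#'
#' A line profile holds multi-channel intensities sampled at uniform
#' arc-length positions `s` (µm) along a closed contour of perimeter `L`.
#' The domain is circular: the sample at `s = 0` is adjacent to the sample at
#' `s = L - ds`. Stored as a tibble with an `s` column plus one column per
#' channel; `ds` and `L` ride along as attributes.
#'
#' @param s Arc-length positions (µm), uniformly spaced from 0.
#' @param intensities Named list of numeric vectors, one per channel.
#' @param L Perimeter (µm).
#' @return A tibble of class `line_profile`.
#' @export
line_profile <- function(s, intensities, L) {
  stopifnot(is.numeric(s), length(s) >= 8, is.list(intensities))
  lens <- vapply(intensities, length, integer(1))
  if (any(lens != length(s))) {
    stop("all channels must have one value per sample", call. = FALSE)
  }
  ds <- s[2] - s[1]
  if (max(abs(diff(s) - ds)) > 1e-9 * max(ds, 1)) {
    stop("samples must be equally spaced", call. = FALSE)
  }
  out <- tibble::tibble(s = s, !!!intensities)
  attr(out, "ds") <- ds
  attr(out, "L") <- L
  class(out) <- c("line_profile", class(out))
  out
}

#' @rdname line_profile
#' @param profile A line profile.
#' @export
profile_channels <- function(profile) setdiff(names(profile), "s")

#' @rdname line_profile
#' @export
profile_perimeter <- function(profile) attr(profile, "L")

#' @rdname line_profile
#' @export
profile_ds <- function(profile) attr(profile, "ds")

# Circular linear interpolation of one channel at arbitrary positions s0.
profile_value_at <- function(profile, channel, s0) {
  L <- profile_perimeter(profile)
  s <- profile$s
  v <- profile[[channel]]
  n <- length(s)
  ds <- profile_ds(profile)
  s0 <- s0 %% L
  i0 <- floor(s0 / ds)                  # 0-based lower sample
  f <- (s0 - i0 * ds) / ds
  i0 <- i0 %% n
  i1 <- (i0 + 1) %% n
  (1 - f) * v[i0 + 1] + f * v[i1 + 1]
}

#' Extract a line-intensity profile along a closed contour
#'
#' Reproduces in software the manual workflow of tracing a polyline along the
#' entire periphery of a net and reading off an intensity profile: the
#' contour is resampled at spacing `ds` (default: one pixel), and at each
#' sample the intensity of every channel is the mean of `band_px` bilinear
#' samples taken along the local normal, one pixel apart and centred on the
#' contour. The small normal band mimics the finite width of a hand-traced
#' polyline and suppresses single-pixel noise.
#'
#' @param image A [calibrated_image()].
#' @param contour A contour tibble (µm coordinates).
#' @param band_px Odd number of samples across the band (default 3).
#' @param ds Sample spacing in µm; defaults to the pixel size.
#' @return A [line_profile()] with one column per channel.
#' @export
extract_profile <- function(image, contour, band_px = 3, ds = NULL) {
  stopifnot(is_calibrated_image(image))
  if (band_px < 1 || band_px %% 2 != 1) {
    stop("`band_px` must be odd and >= 1", call. = FALSE)
  }
  px <- image$pixel_size
  if (is.null(ds)) ds <- px
  L <- contour_perimeter(contour)
  rc <- resample_contour(contour, ds)
  n <- nrow(rc)
  ds_eff <- L / n
  nrm <- contour_normals(rc)
  offsets <- (seq_len(band_px) - (band_px + 1) / 2) * px
  d <- dim(image$channels[[1]])
  xmax <- d[2] * px; ymax <- d[1] * px
  # all band sample coordinates: n samples x band_px offsets
  xs <- outer(rc$x, rep(1, band_px)) + outer(nrm[, 1], offsets)
  ys <- outer(rc$y, rep(1, band_px)) + outer(nrm[, 2], offsets)
  if (any(xs < 0 | xs > xmax | ys < 0 | ys > ymax)) {
    stop("contour (plus band) extends outside the image", call. = FALSE)
  }
  intensities <- lapply(image$channels, function(m) {
    v <- bilinear_sample(m, as.vector(xs), as.vector(ys), px)
    rowMeans(matrix(v, nrow = n))
  })
  line_profile(s = (seq_len(n) - 1) * ds_eff, intensities = intensities, L = L)
}

#' Read / write line profiles as CSV
#'
#' The CSV has the `s` column plus one column per channel; the perimeter is
#' recovered from the uniform spacing (`L = n * ds`) on read.
#'
#' @param profile A [line_profile()].
#' @param path CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(tibble::as_tibble(profile), path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  ds <- tb$s[2] - tb$s[1]
  line_profile(tb$s, as.list(tb[setdiff(names(tb), "s")]), L = nrow(tb) * ds)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a line profile
#'
#' One trace per channel against arc length, the standard presentation of a
#' net-periphery intensity profile (WFA peaks and hole troughs, with marker
#' peaks inside the troughs).
#'
#' @param object A [line_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.line_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"s",
                              names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc length s (µm)", y = "intensity (a.u.)")
}
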