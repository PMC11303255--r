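#' Otsu threshold of an intensity channel
#'
#' Automated between-class-variance-maximizing threshold over the (masked)
#' intensity histogram, the standard binarization step for soma, WFA and
#' astrocytic-marker channels. Delegates to the classic Otsu scan over a
#' `levels`-bin histogram on the 12-bit range.
#'
#' @param channel Numeric intensity matrix.
#' @param mask Optional logical matrix restricting the histogram.
#' @param range Intensity range spanned by the histogram.
#' @param levels Number of histogram bins.
#' @return The threshold intensity; pixels with value > threshold are
#'   foreground.
#' @export
otsu_threshold <- function(channel, mask = NULL, range = c(0, 4095),
                           levels = 4096) {
  v <- if (is.null(mask)) as.vector(channel) else channel[mask]
  if (length(unique(v)) < 2) {
    stop("degenerate histogram: fewer than 2 distinct values", call. = FALSE)
  }
  # EBImage's otsu operates on an Image; a 1 x n raster carries the masked
  # histogram without reimplementing the scan.
  img <- EBImage::Image(matrix((v - range[1]) / diff(range), nrow = 1))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  thr * diff(range) + range[1]
}

#' Binary soma mask from a soma channel
#'
#' Otsu-binarizes the soma (or PV) channel, keeps the largest connected
#' component and fills internal holes — the "binary representation of the
#' cell soma" that the pericellular band is grown from.
#'
#' @param image A [calibrated_image()].
#' @param channel Soma channel name.
#' @return A logical matrix of class `soma_mask` with attributes
#'   `pixel_size` and `threshold`.
#' @export
soma_mask <- function(image, channel) {
  m <- img_channel(image, channel)
  thr <- otsu_threshold(m, range = c(0, image$saturation_level),
                        levels = image$saturation_level + 1)
  bin <- m > thr
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labs <- as.vector(EBImage::imageData(lab))
  labs_pos <- labs[labs > 0]
  if (!length(labs_pos)) stop("empty soma mask after thresholding", call. = FALSE)
  biggest <- as.integer(names(which.max(table(labs_pos))))
  keep <- matrix(labs == biggest, nrow(m), ncol(m))
  filled <- EBImage::fillHull(EBImage::Image(keep * 1))
  out <- matrix(as.vector(EBImage::imageData(filled)) > 0, nrow(m), ncol(m))
  attr(out, "pixel_size") <- image$pixel_size
  attr(out, "threshold") <- thr
  class(out) <- c("soma_mask", class(out))
  out
}

#' Pericellular band around a soma mask
#'
#' All pixels outside the soma whose Euclidean distance to the soma is at
#' most `width` (default 0.8 µm, the width of the pericellular area covered
#' by a net), computed with a Euclidean distance transform. Bands narrower
#' than one pixel fall back to the one-pixel dilation shell (the
#' quantization floor). If the soma touches the image border the band is
#' clipped and the `clipped` attribute is set.
#'
#' @param soma Logical soma mask (e.g. from [soma_mask()]).
#' @param width Band width, µm.
#' @param pixel_size µm/px; defaults to the mask's `pixel_size` attribute.
#' @return A logical matrix of class `band_mask` with attributes `width`,
#'   `pixel_size`, `clipped`, `area_um2`.
#' @export
pericellular_band <- function(soma, width = 0.8, pixel_size = NULL) {
  stopifnot(width > 0)
  if (is.null(pixel_size)) pixel_size <- attr(soma, "pixel_size")
  if (is.null(pixel_size)) stop("`pixel_size` required", call. = FALSE)
  if (!any(soma)) stop("empty soma mask", call. = FALSE)
  # distance of every non-soma pixel to the soma
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image((!soma) * 1)))
  w_px <- max(width / pixel_size, 1)  # quantization floor: 1-px shell
  band <- !soma & d <= w_px
  clipped <- any(soma[c(1, nrow(soma)), ]) || any(soma[, c(1, ncol(soma))])
  if (clipped) {
    warning("soma touches the image border; band is clipped", call. = FALSE)
  }
  attr(band, "width") <- width
  attr(band, "pixel_size") <- pixel_size
  attr(band, "clipped") <- clipped
  attr(band, "area_um2") <- sum(band) * pixel_size^2
  class(band) <- c("band_mask", class(band))
  band
}

#' Pericellular coverage of marker masks
#'
#' Area of each binary marker mask inside the pericellular band, in µm² and
#' normalized by the cell perimeter (µm² per µm), plus a `combined` row for
#' the union of the markers listed in `combine` — the combined astrocytic
#' coverage of e.g. S100B + GLT1 + GFAP.
#'
#' @param band A `band_mask` from [pericellular_band()].
#' @param marker_masks Named list of logical matrices.
#' @param perimeter Cell perimeter, µm.
#' @param combine Marker names forming the combined union (default: all).
#' @return A tibble with columns `marker`, `band_area_um2`, `normalized_um`.
#' @export
coverage <- function(band, marker_masks, perimeter, combine = NULL) {
  stopifnot(perimeter > 0, length(marker_masks) >= 1)
  px <- attr(band, "pixel_size")
  stopifnot(all(vapply(marker_masks, function(m)
    identical(dim(m), dim(band)), logical(1))))
  if (is.null(combine)) combine <- names(marker_masks)
  one <- function(m) sum(m & band) * px^2
  areas <- unname(vapply(marker_masks, one, numeric(1)))
  union <- Reduce(`|`, marker_masks[combine])
  tibble::tibble(
    marker = c(names(marker_masks), "combined"),
    band_area_um2 = c(areas, one(union)),
    normalized_um = c(areas, one(union)) / perimeter
  )
}

#' Count puncta inside the pericellular band
#'
#' @param puncta A `puncta_set` from [find_maxima()] (µm coordinates).
#' @param band A `band_mask`.
#' @param perimeter Cell perimeter, µm.
#' @return A one-row tibble: `n`, `per_um` (count normalized to perimeter).
#' @export
pericellular_puncta <- function(puncta, band, perimeter) {
  stopifnot(perimeter > 0)
  px <- attr(band, "pixel_size")
  inside <- logical(nrow(puncta))
  if (nrow(puncta) > 0) {
    i <- pmin(pmax(round(puncta$y / px + 0.5), 1), nrow(band))
    j <- pmin(pmax(round(puncta$x / px + 0.5), 1), ncol(band))
    inside <- band[cbind(i, j)]
  }
  tibble::tibble(n = sum(inside), per_um = sum(inside) / perimeter)
}

#' Flag puncta in contact with an astrocytic mask
#'
#' A punctum is in contact when any astrocytic-mask pixel lies within
#' `contact_radius` of its coordinate; radius 0 means the punctum's own
#' pixel. The default one-pixel radius implements a Boolean overlap call.
#'
#' @param puncta A `puncta_set` (µm coordinates).
#' @param astro_mask Logical astrocytic marker mask.
#' @param contact_radius Contact radius, µm.
#' @param pixel_size µm/px; defaults to the puncta set's attribute.
#' @return The puncta tibble with a logical `contact` column.
#' @export
puncta_with_astro_contact <- function(puncta, astro_mask, contact_radius = NULL,
                                      pixel_size = NULL) {
  if (is.null(pixel_size)) pixel_size <- attr(puncta, "pixel_size") %||% 1
  if (is.null(contact_radius)) contact_radius <- pixel_size
  stopifnot(contact_radius >= 0)
  out <- tibble::as_tibble(puncta)
  if (nrow(out) == 0) {
    out$contact <- logical()
    return(out)
  }
  if (!any(astro_mask)) {
    out$contact <- FALSE
    return(out)
  }
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image((!astro_mask) * 1)))
  i <- pmin(pmax(round(out$y / pixel_size + 0.5), 1), nrow(astro_mask))
  j <- pmin(pmax(round(out$x / pixel_size + 0.5), 1), ncol(astro_mask))
  out$contact <- d[cbind(i, j)] * pixel_size <= contact_radius
  out
}

#' Spatial disruption profile from an injection site
#'
#' Mean (and sd) channel intensity in uniform square ROIs (edge `roi_edge`,
#' default 400 µm = 0.4 mm) laid adjacent to each other from the injection
#' site along the +x (lateral) direction, quantifying how far an enzymatic
#' net disruption spreads.
#'
#' @param image A [calibrated_image()].
#' @param channel Channel name.
#' @param injection_site `c(x, y)` in µm; must lie inside the image.
#' @param roi_edge ROI edge length, µm.
#' @return A tibble: `bin`, `distance_um` (bin centre distance from the
#'   site), `mean`, `sd`, `n_px`.
#' @export
disruption_profile <- function(image, channel, injection_site, roi_edge = 400) {
  m <- img_channel(image, channel)
  px <- image$pixel_size
  xmax <- ncol(m) * px; ymax <- nrow(m) * px
  sx <- injection_site[1]; sy <- injection_site[2]
  if (sx < 0 || sx > xmax || sy < 0 || sy > ymax) {
    stop("injection site lies outside the image", call. = FALSE)
  }
  xs <- (seq_len(ncol(m)) - 0.5) * px
  ys <- (seq_len(nrow(m)) - 0.5) * px
  rows <- which(ys >= sy - roi_edge / 2 & ys < sy + roi_edge / 2)
  k <- 0L
  out <- list()
  repeat {
    x0 <- sx + k * roi_edge
    cols <- which(xs >= x0 & xs < x0 + roi_edge)
    if (!length(cols)) break
    vals <- m[rows, cols]
    out[[k + 1L]] <- tibble::tibble(
      bin = k + 1L, distance_um = x0 + roi_edge / 2 - sx,
      mean = mean(vals), sd = stats::sd(vals), n_px = length(vals))
    k <- k + 1L
  }
  dplyr::bind_rows(out)
}

#' Pericellular WFA intensity and area
#'
#' Mean raw WFA intensity over the 0.8-µm pericellular band plus the
#' Otsu-binarized WFA-positive area within the band, the readouts used to
#' score net disruption on individual cells. A band whose WFA values are
#' constant has no Otsu threshold; its WFA-positive area is the full band
#' when the constant is positive and zero otherwise.
#'
#' @param soma Logical soma mask.
#' @param wfa WFA intensity matrix.
#' @param width Band width, µm.
#' @param pixel_size µm/px; defaults to the mask's attribute.
#' @return A one-row tibble: `mean_intensity`, `wfa_area_um2`,
#'   `band_area_um2`.
#' @export
pericellular_wfa <- function(soma, wfa, width = 0.8, pixel_size = NULL) {
  if (is.null(pixel_size)) pixel_size <- attr(soma, "pixel_size")
  band <- pericellular_band(soma, width, pixel_size)
  vals <- wfa[band]
  if (length(unique(vals)) < 2) {
    area <- if (vals[1] > 0) attr(band, "area_um2") else 0
  } else {
    thr <- otsu_threshold(wfa, mask = band)
    area <- sum(vals > thr) * pixel_size^2
  }
  tibble::tibble(mean_intensity = mean(vals), wfa_area_um2 = area,
                 band_area_um2 = attr(band, "area_um2"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
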