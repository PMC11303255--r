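#' Unsaturated peak intensity of a profile channel
#'
#' The maximum sample value strictly below the saturation level. Hole
#' thresholds are expressed as a fraction of this quantity so that clipped
#' (saturated) samples cannot inflate the reference peak.
#'
#' @param profile A [line_profile()].
#' @param channel Channel name (default `"WFA"`).
#' @param saturation_level Saturation intensity (4095 for 12-bit data).
#' @return The unsaturated peak intensity.
#' @export
unsaturated_peak <- function(profile, channel = "WFA",
                             saturation_level = 4095) {
  v <- profile[[channel]]
  if (is.null(v) || length(v) == 0) stop("empty profile", call. = FALSE)
  v <- v[v < saturation_level]
  if (length(v) == 0) {
    stop("all samples are saturated; cannot define an unsaturated peak",
         call. = FALSE)
  }
  max(v)
}

#' Detect PNN holes on a line profile
#'
#' Holes are maximal circular runs of samples strictly below `threshold`
#' whose width is at least `w_min` (default 0.5 µm, the resolution-limit
#' cutoff). Runs wrapping the profile origin are merged into one hole; hole
#' boundaries are the linearly interpolated threshold crossings between
#' samples, so widths are sub-sample accurate and independent of the sample
#' spacing. Any single supra-threshold sample splits a run.
#'
#' @param profile A [line_profile()].
#' @param channel Channel name (default `"WFA"`).
#' @param threshold Intensity threshold (> 0).
#' @param w_min Minimum hole width, µm.
#' @return A tibble of class `hole_set` with columns `hole`, `start`, `end`,
#'   `width` (µm; `start`/`end` circular, half-open) and attributes
#'   `perimeter`, `threshold`.
#' @export
detect_holes <- function(profile, channel = "WFA", threshold, w_min = 0.5) {
  stopifnot(threshold > 0)
  v <- profile[[channel]]
  s <- profile$s
  n <- length(v)
  L <- profile_perimeter(profile)
  ds <- profile_ds(profile)
  below <- v < threshold

  empty <- tibble::tibble(hole = integer(), start = numeric(),
                          end = numeric(), width = numeric())
  out <- if (!any(below)) {
    empty
  } else if (all(below)) {
    # degenerate: the whole contour is below threshold -> one full-circle run
    tibble::tibble(hole = 1L, start = 0, end = 0, width = L)
  } else {
    # rotate so the run containing the wrap point is contiguous
    first_above <- which(!below)[1]
    rot <- function(i) ((i - 1 + first_above - 1) %% n) + 1  # rotated -> original
    b <- below[c(first_above:n, seq_len(first_above - 1))]
    r <- rle(b)
    ends_r <- cumsum(r$lengths)
    starts_r <- ends_r - r$lengths + 1
    runs <- which(r$values)
    rows <- lapply(runs, function(k) {
      i0 <- rot(starts_r[k])        # first below-threshold sample (original idx)
      i1 <- rot(ends_r[k])          # last below-threshold sample
      ip <- ((i0 - 2) %% n) + 1     # sample above threshold before the run
      iq <- (i1 %% n) + 1           # sample above threshold after the run
      f0 <- (v[ip] - threshold) / (v[ip] - v[i0])
      f1 <- (threshold - v[i1]) / (v[iq] - v[i1])
      start <- (s[ip] + f0 * ds) %% L
      end <- (s[i1] + f1 * ds) %% L
      width <- (end - start) %% L
      c(start = start, end = end, width = width)
    })
    m <- do.call(rbind, rows)
    keep <- m[, "width"] >= w_min
    m <- m[keep, , drop = FALSE]
    o <- order(m[, "start"])
    tibble::tibble(hole = seq_len(sum(keep)),
                   start = unname(m[o, "start"]),
                   end = unname(m[o, "end"]),
                   width = unname(m[o, "width"]))
  }
  attr(out, "perimeter") <- L
  attr(out, "threshold") <- threshold
  class(out) <- c("hole_set", class(out))
  out
}

#' Select the hole-count-maximizing threshold fraction
#'
#' Sweeps the threshold fraction over `[f_min, f_max]` in steps of `f_step`
#' (fractions of the unsaturated peak) and returns the fraction at which the
#' number of qualifying holes (width >= `w_min`) is maximal, ties broken
#' toward the smallest fraction (the most conservative hole boundaries).
#' This operationalizes choosing the threshold "that covers the maximum
#' number of drops".
#'
#' @inheritParams detect_holes
#' @param f_min,f_max,f_step Fraction sweep bounds and step.
#' @param saturation_level Saturation intensity for the peak reference.
#' @return A list of class `threshold_result`: `threshold`,
#'   `fraction_of_peak`, `unsaturated_peak`, `n_holes`, and the full sweep
#'   (`sweep`, a tibble of fraction vs. hole count).
#' @export
select_threshold <- function(profile, channel = "WFA", f_min = 0.40,
                             f_max = 0.66, f_step = 0.01, w_min = 0.5,
                             saturation_level = 4095) {
  stopifnot(f_min < f_max, f_min > 0, f_max < 1, f_step > 0)
  pk <- unsaturated_peak(profile, channel, saturation_level)
  fs <- seq(f_min, f_max, by = f_step)
  counts <- vapply(fs, function(f) {
    nrow(detect_holes(profile, channel, threshold = f * pk, w_min = w_min))
  }, integer(1))
  best <- which.max(counts)  # first maximum = smallest fraction
  structure(
    list(threshold = fs[best] * pk, fraction_of_peak = fs[best],
         unsaturated_peak = pk, n_holes = counts[best],
         sweep = tibble::tibble(fraction = fs, n_holes = counts)),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> fraction %.2f of unsaturated peak %.4g -> threshold %.4g (%d holes)\n",
    x$fraction_of_peak, x$unsaturated_peak, x$threshold, x$n_holes))
  invisible(x)
}

#' Hole count normalized to the cell perimeter
#'
#' @param holes A `hole_set` from [detect_holes()].
#' @return Holes per µm of perimeter.
#' @export
holes_per_perimeter <- function(holes) {
  L <- attr(holes, "perimeter")
  if (is.null(L) || L <= 0) stop("hole set has no positive perimeter", call. = FALSE)
  nrow(holes) / L
}
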