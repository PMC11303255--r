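#' Specification of a synthetic perineuronal net
#'
#' Describes the geometry and signal model of one synthetic net: a circular
#' soma contour of radius `contour_radius` whose WFA coat sits at
#' `wfa_peak_level` and is interrupted by `n_holes` troughs ("holes") whose
#' floors drop to `wfa_floor_frac` of the peak. Hole edges follow a
#' raised-cosine ramp one PSF FWHM wide (the Gaussian edge-spread of a
#' confocal point-spread function with `psf_sigma`); the flat floor spans the
#' full true hole interval so every ground-truth hole lies strictly below the
#' 40%-of-peak detection floor in the noise-free signal.
#'
#' Noise is additive Gaussian with sd `wfa_peak_level * (1 - wfa_floor_frac)
#' / snr` (so `snr` is the trough-depth-to-noise ratio), optionally preceded
#' by Poisson shot noise; intensities are clipped to `[0, 2^bit_depth - 1]`
#' as a 12-bit detector would. Marker bumps placed in occupied holes have
#' amplitude `marker_snr` times the noise sd (at least 5x, so occupancy
#' remains decidable), or 20% of the WFA peak when noise is off.
#'
#' @param contour_radius Soma contour radius, µm.
#' @param pixel_size Sampling interval along the contour, µm (also the image
#'   pixel size for 2D synthesis).
#' @param n_holes Number of holes per net.
#' @param hole_width Range `c(min, max)` of true hole widths, µm. Reported
#'   hole widths run from 0.5 µm to several µm with no published
#'   distribution; the default 0.6--1.2 µm keeps ~25 holes plus >= 0.5 µm
#'   inter-hole WFA ridges feasible on a typical 50 µm perimeter.
#' @param min_gap Minimum inter-hole WFA ridge width, µm.
#' @param wfa_peak_level WFA coat intensity (12-bit scale).
#' @param wfa_floor_frac Hole floor as a fraction of the peak; must be in
#'   (0, 0.40) so holes are detectable below the lowest threshold.
#' @param psf_sigma Gaussian PSF sigma, µm.
#' @param snr Trough-depth-to-noise-sd ratio; `Inf` disables noise.
#' @param marker_snr Marker bump amplitude in units of the noise sd.
#' @param poisson Add Poisson shot noise before the Gaussian read noise.
#' @param bit_depth Detector bit depth (saturation at `2^bit_depth - 1`).
#' @return A list of class `net_spec`.
#' @export
net_spec <- function(contour_radius = 8, pixel_size = 0.031, n_holes = 25,
                     hole_width = c(0.6, 1.2), min_gap = 0.5,
                     wfa_peak_level = 3000, wfa_floor_frac = 0.15,
                     psf_sigma = 0.1, snr = Inf, marker_snr = 10,
                     poisson = FALSE, bit_depth = 12) {
  stopifnot(contour_radius > 0, pixel_size > 0, n_holes >= 0,
            length(hole_width) == 2, hole_width[1] <= hole_width[2],
            hole_width[1] > 0, min_gap > 0, wfa_peak_level > 0,
            psf_sigma > 0, snr > 0, marker_snr >= 5)
  if (wfa_floor_frac <= 0 || wfa_floor_frac >= 0.40) {
    stop("`wfa_floor_frac` must lie in (0, 0.40) so holes sit below the ",
         "40%-of-peak threshold floor", call. = FALSE)
  }
  noise_sd <- if (is.finite(snr)) wfa_peak_level * (1 - wfa_floor_frac) / snr else 0
  marker_amp <- if (noise_sd > 0) marker_snr * noise_sd else 0.2 * wfa_peak_level
  # diffuse marker background: keeps Gaussian noise clear of the detector
  # floor at 0, as real fluorescence backgrounds sit above zero offset
  marker_bg <- 4 * noise_sd
  structure(
    list(
      contour_radius = contour_radius, pixel_size = pixel_size,
      n_holes = n_holes, hole_width = hole_width, min_gap = min_gap,
      wfa_peak_level = wfa_peak_level, wfa_floor_frac = wfa_floor_frac,
      psf_sigma = psf_sigma, snr = snr, noise_sd = noise_sd,
      marker_amp = marker_amp, marker_bg = marker_bg,
      poisson = poisson, bit_depth = bit_depth,
      saturation_level = 2^bit_depth - 1
    ),
    class = "net_spec"
  )
}

#' Per-hole occupancy profile
#'
#' The mutually exclusive partition of channel combinations from which each
#' hole's content is drawn. Combination labels are channel names joined by
#' `"+"` (order-free) with `"none"` for the empty combination; probabilities
#' must sum to 1. Missing combinations get probability 0.
#'
#' @param channels Character vector of marker channel names.
#' @param probabilities Named numeric vector, names being combination labels.
#' @return A list of class `occupancy_profile` with the full `2^k` partition.
#' @export
occupancy_profile <- function(channels, probabilities) {
  stopifnot(length(channels) >= 1, !anyDuplicated(channels))
  labs <- combination_labels(channels)
  canon <- function(nm) {
    if (identical(nm, "none")) return("none")
    parts <- strsplit(nm, "+", fixed = TRUE)[[1]]
    bad <- setdiff(parts, channels)
    if (length(bad)) {
      stop("unknown channel(s) in combination '", nm, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    paste(channels[channels %in% parts], collapse = "+")
  }
  names(probabilities) <- vapply(names(probabilities), canon, character(1))
  if (anyDuplicated(names(probabilities))) {
    stop("duplicate combinations in `probabilities`", call. = FALSE)
  }
  p <- stats::setNames(numeric(length(labs)), labs)
  p[names(probabilities)] <- probabilities
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
    stop("probabilities must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  structure(list(channels = channels, probabilities = p),
            class = "occupancy_profile")
}

# All 2^k exclusive combination labels for a channel set, "none" last.
combination_labels <- function(channels) {
  k <- length(channels)
  labs <- character(2^k)
  for (m in 0:(2^k - 1)) {
    sel <- channels[bitwAnd(m, bitwShiftL(1, seq_len(k) - 1)) > 0]
    labs[m + 1] <- if (length(sel)) paste(sel, collapse = "+") else "none"
  }
  c(setdiff(labs, "none"), "none")
}

#' Bundled occupancy presets transcribed from published panels
#'
#' Exclusive-partition probabilities for the marker pairs (and the
#' three-channel panel) with published cohort occupancy percentages:
#' astrocytic reporter (AldheGFP) with Kir4.1, GLT1,
#' vGlut1, vGAT; vGlut1 with GLT1; vGAT with GAT3; and the three-channel
#' AldheGFP/vGlut1/vGAT panel whose union occupancy is approximately 95%.
#'
#' @param name Preset name; with no argument, all presets are returned.
#' @return An [occupancy_profile()] (or a named list of them).
#' @export
occupancy_presets <- function(name = NULL) {
  presets <- list(
    fig1gh = occupancy_profile(
      c("AldheGFP", "Kir4.1"),
      c("AldheGFP+Kir4.1" = 0.62, "AldheGFP" = 0.01, "Kir4.1" = 0.09,
        "none" = 0.28)),
    fig1kl = occupancy_profile(
      c("AldheGFP", "GLT1"),
      c("AldheGFP+GLT1" = 0.56, "AldheGFP" = 0.03, "GLT1" = 0.14,
        "none" = 0.27)),
    fig2cd = occupancy_profile(
      c("AldheGFP", "vGlut1"),
      c("AldheGFP+vGlut1" = 0.44, "AldheGFP" = 0.09, "vGlut1" = 0.27,
        "none" = 0.20)),
    fig2gh = occupancy_profile(
      c("AldheGFP", "vGAT"),
      c("AldheGFP+vGAT" = 0.33, "AldheGFP" = 0.25, "vGAT" = 0.24,
        "none" = 0.18)),
    fig2kl = occupancy_profile(
      c("vGlut1", "GLT1"),
      c("vGlut1+GLT1" = 0.47, "vGlut1" = 0.16, "GLT1" = 0.17,
        "none" = 0.20)),
    fig2op = occupancy_profile(
      c("vGAT", "GAT3"),
      c("vGAT+GAT3" = 0.35, "vGAT" = 0.17, "GAT3" = 0.28, "none" = 0.20)),
    fig2st = occupancy_profile(
      c("AldheGFP", "vGlut1", "vGAT"),
      c("AldheGFP+vGlut1+vGAT" = 0.241, "AldheGFP+vGlut1" = 0.215,
        "AldheGFP+vGAT" = 0.124, "AldheGFP" = 0.060,
        "vGlut1+vGAT" = 0.129, "vGlut1" = 0.115, "vGAT" = 0.066,
        "none" = 0.050))
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "' (have: ",
         paste(names(presets), collapse = ", "), ")", call. = FALSE)
  }
  presets[[name]]
}

# Run code with a private RNG stream: seeds, runs, restores global state.
with_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Place n disjoint holes with widths in `width_range` on a circle of
# circumference L, keeping every inter-hole ridge >= min_gap.
place_holes <- function(n, width_range, min_gap, L) {
  if (n == 0) {
    return(tibble::tibble(hole = integer(), start = numeric(),
                          end = numeric(), width = numeric()))
  }
  w <- stats::runif(n, width_range[1], width_range[2])
  slack <- L - sum(w) - n * min_gap
  if (slack < 0) {
    stop("infeasible geometry: total hole width plus minimum ridges exceeds ",
         "the circumference", call. = FALSE)
  }
  e <- stats::rexp(n)
  gaps <- min_gap + slack * e / sum(e)
  offset <- stats::runif(1, 0, L)
  starts <- (offset + cumsum(c(0, (w + gaps)[-n]))) %% L
  tibble::tibble(hole = seq_len(n), start = starts,
                 end = (starts + w) %% L, width = w)
}

# Trough depth factor in [0, 1] at positions s: 1 on the hole floor, raised
# cosine over an edge of width `edge` outside each interval, 0 elsewhere.
trough_factor <- function(s, holes, L, edge) {
  g <- numeric(length(s))
  for (k in seq_len(nrow(holes))) {
    a <- holes$start[k]; w <- holes$width[k]
    # circular offset of s from hole start, in [0, L)
    d <- (s - a) %% L
    inside <- d < w
    # distance outside the interval (shortest way round)
    dist_out <- pmin((d - w) %% L, (a - s) %% L)
    ramp <- !inside & dist_out < edge
    gk <- numeric(length(s))
    gk[inside] <- 1
    gk[ramp] <- 0.5 * (1 + cos(pi * dist_out[ramp] / edge))
    g <- pmax(g, gk)
  }
  g
}

# Circular distance between positions on [0, L)
circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

apply_noise <- function(clean, spec) {
  v <- clean
  if (isTRUE(spec$poisson)) v <- stats::rpois(length(v), pmax(v, 0))
  if (spec$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, spec$noise_sd)
  pmin(pmax(v, 0), spec$saturation_level)
}

# Draw hole geometry, per-hole occupancy and marker bump centres for one net.
# Assumes an active RNG stream (call inside with_rng()).
draw_net_truth <- function(spec, occ) {
  L <- 2 * pi * spec$contour_radius
  holes <- place_holes(spec$n_holes, spec$hole_width, spec$min_gap, L)
  n_h <- nrow(holes)
  combos <- if (n_h > 0) {
    sample(names(occ$probabilities), size = n_h, replace = TRUE,
           prob = occ$probabilities)
  } else character()
  present <- matrix(FALSE, nrow = n_h, ncol = length(occ$channels),
                    dimnames = list(NULL, occ$channels))
  for (k in seq_len(n_h)) {
    parts <- strsplit(combos[k], "+", fixed = TRUE)[[1]]
    present[k, ] <- occ$channels %in% parts
  }
  occupancy <- tidyr::expand_grid(hole = holes$hole, channel = occ$channels)
  occupancy$present <- as.vector(t(present))
  occupancy$center <- NA_real_
  for (k in seq_len(n_h)) {
    w <- holes$width[k]
    for (ch in occ$channels) {
      if (!present[k, ch]) next
      centre <- (holes$start[k] + stats::runif(1, 0.2 * w, 0.8 * w)) %% L
      occupancy$center[occupancy$hole == k & occupancy$channel == ch] <- centre
    }
  }
  list(holes = holes, occupancy = occupancy, combos = combos,
       channels = occ$channels, L = L, spec = spec)
}

#' Simulate a net-periphery line profile with ground truth
#'
#' Generates the WFA channel of one synthetic net (peak coat interrupted by
#' hole troughs, see [net_spec()]) plus one channel per marker in the
#' occupancy profile. Each hole draws its content from the occupancy
#' partition; every occupied channel receives a Gaussian bump (sd = PSF
#' sigma) centred uniformly within the central 60% of the hole so the peak
#' cannot sit ambiguously on a hole edge. All randomness flows from `seed`.
#'
#' @param spec A [net_spec()].
#' @param occ An [occupancy_profile()].
#' @param seed Integer seed.
#' @return A list with elements `profile` (a [line_profile()] with channels
#'   `WFA` plus the markers) and `truth` (hole intervals, per-hole occupancy
#'   and marker bump centres, the generating net_spec, and the seed).
#' @export
simulate_profile <- function(spec, occ, seed) {
  stopifnot(inherits(spec, "net_spec"), inherits(occ, "occupancy_profile"))
  with_rng(seed, {
    truth <- draw_net_truth(spec, occ)
    L <- truth$L
    n <- as.integer(round(L / spec$pixel_size))
    s <- (seq_len(n) - 1) * (L / n)
    edge <- 2.355 * spec$psf_sigma  # one PSF FWHM
    peak <- spec$wfa_peak_level
    floor_lv <- spec$wfa_floor_frac * peak
    wfa_clean <- peak - (peak - floor_lv) * trough_factor(s, truth$holes, L, edge)

    marker_clean <- stats::setNames(
      lapply(occ$channels, function(ch) rep(spec$marker_bg, n)), occ$channels)
    bumps <- truth$occupancy[truth$occupancy$present, ]
    for (k in seq_len(nrow(bumps))) {
      ch <- bumps$channel[k]
      d <- circ_dist(s, bumps$center[k], L)
      marker_clean[[ch]] <- marker_clean[[ch]] +
        spec$marker_amp * exp(-d^2 / (2 * spec$psf_sigma^2))
    }

    intensities <- c(list(WFA = apply_noise(wfa_clean, spec)),
                     lapply(marker_clean, apply_noise, spec = spec))
    truth$wfa_clean <- wfa_clean
    truth$seed <- seed
    list(profile = line_profile(s, intensities, L), truth = truth)
  })
}

#' Simulate a cohort of synthetic nets
#'
#' Draws `n_cells` independent nets from the same spec and occupancy profile;
#' per-cell seeds are derived from `seed` so the whole cohort is reproducible
#' from one integer.
#'
#' @inheritParams simulate_profile
#' @param n_cells Number of nets.
#' @return A list of `simulate_profile()` results, one per cell.
#' @export
simulate_cohort <- function(spec, occ, n_cells, seed) {
  cell_seeds <- with_rng(seed, sample.int(.Machine$integer.max - 1L, n_cells))
  lapply(seq_len(n_cells), function(i) simulate_profile(spec, occ, cell_seeds[i]))
}
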