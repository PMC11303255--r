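#' Simulate a 2D net image with ground truth
#'
#' Renders one synthetic net as a multi-channel 2D micrograph: the WFA coat
#' is an annular ring at the contour radius whose azimuthal intensity follows
#' the same hole model as [simulate_profile()] (flat floor over each hole,
#' raised-cosine PSF edges), with a Gaussian radial cross-section of sigma
#' `ring_sigma`; marker bumps in occupied holes become 2D Gaussian spots on
#' the ring. Extracting a profile along the true circular contour and
#' running hole detection recovers the ground truth.
#'
#' @inheritParams simulate_profile
#' @param ring_sigma Radial sigma of the WFA coat cross-section, µm.
#' @param margin Clear margin between the ring and the image border, µm.
#' @return A list with `image` (a [calibrated_image()]), `contour` (the true
#'   circular contour, µm) and `truth` (as in [simulate_profile()]).
#' @export
simulate_net_image <- function(spec, occ, seed, ring_sigma = 0.25,
                               margin = NULL) {
  stopifnot(inherits(spec, "net_spec"), inherits(occ, "occupancy_profile"))
  if (is.null(margin)) margin <- 4 * ring_sigma + 4 * spec$psf_sigma + 0.25
  with_rng(seed, {
    truth <- draw_net_truth(spec, occ)
    L <- truth$L
    R <- spec$contour_radius
    px <- spec$pixel_size
    half <- R + margin
    npx <- as.integer(ceiling(2 * half / px))
    cx <- cy <- npx * px / 2
    xs <- (seq_len(npx) - 0.5) * px
    X <- matrix(xs, npx, npx, byrow = TRUE)   # x along columns
    Y <- matrix(xs, npx, npx)                 # y along rows
    r <- sqrt((X - cx)^2 + (Y - cy)^2)
    theta <- atan2(Y - cy, X - cx) %% (2 * pi)
    s_pix <- theta * R

    edge <- 2.355 * spec$psf_sigma
    peak <- spec$wfa_peak_level
    floor_lv <- spec$wfa_floor_frac * peak
    radial <- exp(-(r - R)^2 / (2 * ring_sigma^2))
    # only pixels near the ring carry signal; skip the trough model elsewhere
    near <- abs(r - R) < 5 * ring_sigma
    azim <- rep(peak, sum(near))
    if (nrow(truth$holes) > 0) {
      azim <- peak - (peak - floor_lv) *
        trough_factor(s_pix[near], truth$holes, L, edge)
    }
    wfa_clean <- matrix(0, npx, npx)
    wfa_clean[near] <- azim * radial[near]

    marker_clean <- stats::setNames(
      lapply(occ$channels, function(ch) matrix(spec$marker_bg, npx, npx)),
      occ$channels)
    bumps <- truth$occupancy[truth$occupancy$present, ]
    sp <- spec$psf_sigma
    for (k in seq_len(nrow(bumps))) {
      ch <- bumps$channel[k]
      th_c <- bumps$center[k] / R
      x0 <- cx + R * cos(th_c); y0 <- cy + R * sin(th_c)
      # render inside a 5-sigma box only
      jj <- which(abs(xs - x0) < 5 * sp)
      ii <- which(abs(xs - y0) < 5 * sp)
      if (!length(ii) || !length(jj)) next
      gx <- exp(-(xs[jj] - x0)^2 / (2 * sp^2))
      gy <- exp(-(xs[ii] - y0)^2 / (2 * sp^2))
      marker_clean[[ch]][ii, jj] <- marker_clean[[ch]][ii, jj] +
        spec$marker_amp * outer(gy, gx)
    }

    noisy <- function(m) {
      v <- apply_noise(as.vector(m), spec)
      matrix(v, nrow(m), ncol(m))
    }
    channels <- c(list(WFA = noisy(wfa_clean)),
                  lapply(marker_clean, noisy))
    truth$seed <- seed
    truth$center <- c(cx, cy)
    list(
      image = calibrated_image(channels, pixel_size = px,
                               bit_depth = spec$bit_depth),
      contour = contour_circle(c(cx, cy), R, n = as.integer(round(L / px))),
      truth = truth
    )
  })
}

# Sample n angles uniformly from a union of angular arcs
# (tibble with start/width columns, radians).
sample_in_arcs <- function(n, arcs) {
  if (n == 0) return(numeric())
  total <- sum(arcs$width)
  if (total <= 0) stop("no arc mass to sample puncta from", call. = FALSE)
  u <- stats::runif(n, 0, total)
  upper <- cumsum(arcs$width)
  idx <- findInterval(u, c(0, upper), rightmost.closed = TRUE)
  (arcs$start[idx] + (u - c(0, upper)[idx])) %% (2 * pi)
}

#' Simulate a soma with pericellular markers and puncta
#'
#' Renders a soma disk channel, an astrocytic marker channel occupying a
#' prescribed fraction of the pericellular band (as random angular sectors
#' spanning the band radially), and a synaptic-puncta channel of Gaussian
#' spots at recorded coordinates inside the band. When `contact_frac` is
#' given, that fraction of puncta is placed inside astrocyte-covered sectors
#' (the rest well inside uncovered sectors), providing ground truth for
#' puncta--astrocyte contact calls.
#'
#' @param soma_radius Soma radius, µm.
#' @param band_coverage Fraction of the pericellular band covered by the
#'   astrocytic marker, in `[0, 1]`.
#' @param n_puncta Number of synaptic puncta in the band.
#' @param puncta_amp Punctum peak amplitude (12-bit scale).
#' @param contact_frac Fraction of puncta in contact with the astrocytic
#'   marker; `NULL` places puncta uniformly and records realized contact.
#' @param band_width Pericellular band width, µm (default 0.8).
#' @param pixel_size µm per pixel.
#' @param noise_sd Additive Gaussian noise sd (0 disables).
#' @param n_arcs Number of astrocyte sectors the coverage is split across.
#' @param seed Integer seed.
#' @return A list with `image` (channels `soma`, `astro`, `puncta`) and
#'   `truth` (soma radius and centre, coverage arcs, puncta coordinates with
#'   contact flags, perimeter).
#' @export
simulate_pericellular_image <- function(soma_radius = 5, band_coverage = 0.4,
                                        n_puncta = 30, puncta_amp = 2000,
                                        contact_frac = NULL, band_width = 0.8,
                                        pixel_size = 0.031, noise_sd = 0,
                                        n_arcs = 6, seed = 1) {
  stopifnot(band_coverage >= 0, band_coverage <= 1, soma_radius > 0)
  with_rng(seed, {
    R <- soma_radius
    half <- R + band_width + 1
    npx <- as.integer(ceiling(2 * half / pixel_size))
    cx <- cy <- npx * pixel_size / 2
    xs <- (seq_len(npx) - 0.5) * pixel_size
    X <- matrix(xs, npx, npx, byrow = TRUE)
    Y <- matrix(xs, npx, npx)
    r <- sqrt((X - cx)^2 + (Y - cy)^2)
    theta <- atan2(Y - cy, X - cx) %% (2 * pi)

    lvl <- 3000
    edge <- 2 * pixel_size
    soma <- lvl * pmin(pmax((R - r) / edge + 0.5, 0), 1)

    # astrocyte coverage: n_arcs random sectors totalling band_coverage * 2pi
    if (band_coverage <= 0) {
      arcs <- tibble::tibble(start = numeric(), width = numeric())
    } else if (band_coverage >= 1) {
      arcs <- tibble::tibble(start = 0, width = 2 * pi)
    } else {
      wts <- stats::rexp(n_arcs); wts <- wts / sum(wts)
      widths <- band_coverage * 2 * pi * wts
      gw <- stats::rexp(n_arcs); gw <- gw / sum(gw)
      gaps <- (1 - band_coverage) * 2 * pi * gw
      start0 <- stats::runif(1, 0, 2 * pi)
      starts <- (start0 + cumsum(c(0, (widths + gaps)[-n_arcs]))) %% (2 * pi)
      arcs <- tibble::tibble(start = starts, width = widths)
    }
    in_arc <- matrix(FALSE, npx, npx)
    for (k in seq_len(nrow(arcs))) {
      in_arc <- in_arc |
        (((theta - arcs$start[k]) %% (2 * pi)) < arcs$width[k])
    }
    in_band_wide <- r > R - 2 * pixel_size & r <= R + band_width + 3 * pixel_size
    astro <- ifelse(in_arc & in_band_wide, lvl, 0)

    # puncta inside the band
    gap_arcs <- if (nrow(arcs) == 0) {
      tibble::tibble(start = 0, width = 2 * pi)
    } else if (band_coverage >= 1) {
      tibble::tibble(start = numeric(), width = numeric())
    } else {
      tibble::tibble(start = (arcs$start + arcs$width) %% (2 * pi),
                     width = (c(arcs$start[-1], arcs$start[1]) -
                                (arcs$start + arcs$width)) %% (2 * pi))
    }
    clearance <- 0.35 / R  # radians kept clear of sector edges
    shrink <- function(a, by) {
      keep <- a$width > 2 * by
      tibble::tibble(start = (a$start[keep] + by) %% (2 * pi),
                     width = a$width[keep] - 2 * by)
    }
    # rejection-sample puncta angles so no two puncta sit closer than
    # min_sep um (discrete presynaptic boutons do not coincide)
    min_sep <- 0.30
    draw_sep <- function(n, draw_one) {
      th <- numeric(0)
      tries <- 0
      while (length(th) < n && tries < 5000) {
        cand <- draw_one()
        if (!length(th) ||
            all(circ_dist(cand, th, 2 * pi) * R > min_sep)) {
          th <- c(th, cand)
        }
        tries <- tries + 1
      }
      if (length(th) < n) {
        stop("could not place puncta with the required separation",
             call. = FALSE)
      }
      th
    }
    if (is.null(contact_frac)) {
      th_p <- draw_sep(n_puncta, function() stats::runif(1, 0, 2 * pi))
    } else {
      n_con <- round(contact_frac * n_puncta)
      arcs_in <- shrink(arcs, clearance)
      arcs_out <- shrink(gap_arcs, clearance)
      th_con <- draw_sep(n_con, function() sample_in_arcs(1, arcs_in))
      th_non <- draw_sep(n_puncta - n_con,
                         function() sample_in_arcs(1, arcs_out))
      th_p <- c(th_con, th_non)
    }
    n_p <- length(th_p)
    rp <- stats::runif(n_p, R + 0.15, R + band_width - 0.1)
    px_ <- cx + rp * cos(th_p); py_ <- cy + rp * sin(th_p)
    sigma_p <- 0.08
    puncta_img <- matrix(0, npx, npx)
    for (k in seq_len(n_p)) {
      jj <- which(abs(xs - px_[k]) < 5 * sigma_p)
      ii <- which(abs(xs - py_[k]) < 5 * sigma_p)
      gx <- exp(-(xs[jj] - px_[k])^2 / (2 * sigma_p^2))
      gy <- exp(-(xs[ii] - py_[k])^2 / (2 * sigma_p^2))
      puncta_img[ii, jj] <- puncta_img[ii, jj] + puncta_amp * outer(gy, gx)
    }
    in_covered <- if (nrow(arcs) == 0) rep(FALSE, n_p) else {
      vapply(th_p, function(t0) {
        any(((t0 - arcs$start) %% (2 * pi)) < arcs$width)
      }, logical(1))
    }

    add_noise <- function(m) {
      if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
      matrix(pmin(pmax(m, 0), 4095), npx, npx)
    }
    image <- calibrated_image(
      list(soma = add_noise(soma), astro = add_noise(astro),
           puncta = add_noise(puncta_img)),
      pixel_size = pixel_size, bit_depth = 12
    )
    list(
      image = image,
      truth = list(
        center = c(cx, cy), soma_radius = R, band_width = band_width,
        coverage = band_coverage, arcs = arcs,
        perimeter = 2 * pi * R,
        puncta = tibble::tibble(x = px_, y = py_, amplitude = puncta_amp,
                                channel = "puncta",
                                astro_contact = in_covered),
        seed = seed
      )
    )
  })
}
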