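disk_mask <- function(r_um, px, pad_um = 1.5) {
  half <- r_um + pad_um
  n <- ceiling(2 * half / px)
  ctr <- n * px / 2
  xs <- (seq_len(n) - 0.5) * px
  X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
  out <- sqrt((X - ctr)^2 + (Y - ctr)^2) <= r_um
  attr(out, "pixel_size") <- px
  out
}

test_that("otsu threshold splits a bimodal histogram and matches a brute scan", {
  set.seed(3)
  m <- matrix(c(rep(10, 600), rep(200, 400)), 40, 25)
  thr <- otsu_threshold(m, range = c(0, 255), levels = 256)
  expect_gt(thr, 10); expect_lt(thr, 200)
  # brute-force between-class variance scan on an 8-bit toy image
  img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  counts <- tabulate(img + 1, 256)
  w <- cumsum(counts); mu <- cumsum(counts * (0:255))
  tot <- w[256]; mu_t <- mu[256]
  bc <- (mu_t * w - mu * tot)^2 / (w * (tot - w))
  bc[!is.finite(bc)] <- 0
  best <- which.max(bc) - 1
  got <- otsu_threshold(img, range = c(0, 255), levels = 256)
  expect_equal(round(got), best, tolerance = 1)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate")
})

test_that("pericellular band area matches the annulus closed form", {
  px <- 0.031
  soma <- disk_mask(5, px)
  band <- pericellular_band(soma, width = 0.8, pixel_size = px)
  analytic <- pi * (5.8^2 - 5^2)   # ~27.14 um^2
  expect_equal(attr(band, "area_um2"), analytic, tolerance = 0.02)
  # every band pixel sits outside the soma
  expect_false(any(band & soma))
})

test_that("sub-pixel band widths fall back to the one-pixel shell", {
  px <- 0.2
  soma <- disk_mask(2, px)
  band <- pericellular_band(soma, width = 0.05, pixel_size = px)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image((!soma) * 1)))
  expect_true(all(d[band] <= 1))
  expect_gt(sum(band), 0)
})

test_that("a soma touching the border flags a clipped band", {
  px <- 0.1
  soma <- disk_mask(2, px, pad_um = 0)
  expect_warning(pericellular_band(soma, 0.5, pixel_size = px), "clipped")
})

test_that("coverage handles full, disjoint and union markers", {
  px <- 0.05
  soma <- disk_mask(3, px)
  band <- pericellular_band(soma, 0.8, pixel_size = px)
  perim <- 2 * pi * 3
  full <- matrix(TRUE, nrow(soma), ncol(soma))
  cov <- coverage(band, list(m = full), perim)
  expect_equal(cov$band_area_um2[cov$marker == "m"], attr(band, "area_um2"))
  expect_equal(cov$normalized_um[cov$marker == "m"],
               attr(band, "area_um2") / perim)
  # two disjoint half-planes: combined equals the sum
  left <- col(soma) <= ncol(soma) / 2
  right <- !left
  cov2 <- coverage(band, list(a = left, b = right), perim)
  expect_equal(cov2$band_area_um2[cov2$marker == "combined"],
               sum(cov2$band_area_um2[cov2$marker %in% c("a", "b")]))
  # union coverage never exceeds the sum of parts
  overlap <- left | (col(soma) <= 0.6 * ncol(soma))
  cov3 <- coverage(band, list(a = left, b = overlap), perim)
  expect_lte(cov3$band_area_um2[cov3$marker == "combined"],
             sum(cov3$band_area_um2[cov3$marker %in% c("a", "b")]))
})

test_that("synthetic band coverage is recovered within tolerance", {
  syn <- simulate_pericellular_image(band_coverage = 0.4, n_puncta = 0,
                                     seed = 11)
  img <- syn$image
  soma <- soma_mask(img, "soma")
  band <- pericellular_band(soma, 0.8)
  astro <- img_channel(img, "astro") > 1500
  cov <- coverage(band, list(astro = astro), syn$truth$perimeter)
  frac <- cov$band_area_um2[cov$marker == "astro"] / attr(band, "area_um2")
  expect_equal(frac, 0.40, tolerance = 0.075)
})

test_that("area outputs scale as pixel_size^2 under resolution changes", {
  for (px in c(0.05, 0.1)) {
    soma <- disk_mask(4, px)
    band <- pericellular_band(soma, 0.8, pixel_size = px)
    expect_equal(attr(band, "area_um2"), pi * (4.8^2 - 16), tolerance = 0.05)
  }
})

test_that("puncta counting and contact flags follow the ground truth", {
  syn <- simulate_pericellular_image(band_coverage = 0.5, n_puncta = 40,
                                     puncta_amp = 2000, contact_frac = 0.6,
                                     seed = 19)
  img <- syn$image
  pts <- find_maxima(img_channel(img, "puncta"), prominence = 500,
                     pixel_size = img$pixel_size)
  expect_equal(nrow(pts), 40)
  soma <- soma_mask(img, "soma")
  band <- pericellular_band(soma, 0.8)
  pb <- pericellular_puncta(pts, band, syn$truth$perimeter)
  expect_gt(pb$n, 35)   # all truth puncta lie in the band
  astro <- img_channel(img, "astro") > 1500
  flagged <- puncta_with_astro_contact(pts, astro,
                                       contact_radius = 2 * img$pixel_size,
                                       pixel_size = img$pixel_size)
  expect_equal(mean(flagged$contact), 0.6, tolerance = 0.05)
  # empty and full astro masks
  none <- puncta_with_astro_contact(pts, astro & FALSE, 0.1, img$pixel_size)
  expect_equal(sum(none$contact), 0)
  all_m <- puncta_with_astro_contact(pts, astro | TRUE, 0.1, img$pixel_size)
  expect_true(all(all_m$contact))
})

test_that("puncta in the soma do not count as pericellular", {
  px <- 0.05
  soma <- disk_mask(3, px)
  band <- pericellular_band(soma, 0.8, pixel_size = px)
  ctr <- nrow(soma) * px / 2
  inside <- tibble::tibble(x = ctr + c(-0.5, 0, 0.5), y = ctr,
                           row = 0, col = 0, value = 1000)
  pb <- pericellular_puncta(inside, band, 2 * pi * 3)
  expect_equal(pb$n, 0)
})

test_that("disruption profile orders ROI means along the gradient", {
  px <- 2   # coarse pixels, image in um
  n <- 600  # 1.2 mm
  ramp <- matrix(rep(seq(1000, 100, length.out = n), each = n), n, n)
  img <- calibrated_image(list(WFA = ramp), pixel_size = px)
  dp <- disruption_profile(img, "WFA", injection_site = c(10, 600),
                           roi_edge = 400)
  expect_gte(nrow(dp), 2)
  expect_true(all(diff(dp$mean) < 0))
  # uniform image: all bins equal
  img2 <- calibrated_image(list(WFA = matrix(500, 200, 200)), pixel_size = px)
  dp2 <- disruption_profile(img2, "WFA", c(5, 200), roi_edge = 100)
  expect_true(all(dp2$mean == 500))
  expect_error(disruption_profile(img, "WFA", c(-5, 0)), "outside")
  # synthetic step at 1.2 mm in a wider field: drop between bins 3 and 4
  n2 <- 800
  step <- matrix(800, n2, n2)
  step[, ((1200 / px) + 1):n2] <- 200
  img3 <- calibrated_image(list(WFA = step), pixel_size = px)
  dp3 <- disruption_profile(img3, "WFA", c(0.1, 800), roi_edge = 400)
  expect_equal(dp3$mean[1:3], rep(800, 3), tolerance = 0.01)
  expect_lt(dp3$mean[4], 300)
})

test_that("pericellular WFA readouts match constructed bands", {
  px <- 0.05
  soma <- disk_mask(3, px)
  zero <- matrix(0, nrow(soma), ncol(soma))
  res0 <- pericellular_wfa(soma, zero, pixel_size = px)
  expect_equal(res0$mean_intensity, 0)
  expect_equal(res0$wfa_area_um2, 0)
  # full-intensity band: WFA-positive area equals the band area
  full <- matrix(3000, nrow(soma), ncol(soma))
  res1 <- pericellular_wfa(soma, full, pixel_size = px)
  expect_equal(res1$wfa_area_um2, res1$band_area_um2)
  # half-covered band: area ~ 50%
  half <- matrix(0, nrow(soma), ncol(soma))
  half[, seq_len(ncol(soma) / 2)] <- 3000
  res2 <- pericellular_wfa(soma, half, pixel_size = px)
  expect_equal(res2$wfa_area_um2 / res2$band_area_um2, 0.5, tolerance = 0.05)
})
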