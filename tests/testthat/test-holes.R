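test_that("unsaturated peak ignores saturated samples", {
  n <- 100
  v <- rep(100, n); v[5] <- 4095; v[10] <- 3800
  p <- line_profile((0:(n - 1)) * 0.1, list(WFA = v), n * 0.1)
  expect_equal(unsaturated_peak(p, "WFA", 4095), 3800)
  v2 <- rep(50, n); v2[3] <- 900
  p2 <- line_profile((0:(n - 1)) * 0.1, list(WFA = v2), n * 0.1)
  expect_equal(unsaturated_peak(p2), 900)   # plain maximum when unsaturated
  p3 <- line_profile((0:(n - 1)) * 0.1, list(WFA = rep(4095, n)), n * 0.1)
  expect_error(unsaturated_peak(p3), "saturated")
})

test_that("width cutoff keeps only holes of at least 0.5 um", {
  tro <- data.frame(start = c(5, 15, 30), width = c(0.3, 0.6, 1.2),
                    floor = 0.1)
  p <- make_trough_profile(tro)
  h <- detect_holes(p, "WFA", threshold = 0.5 * 3000)
  expect_equal(nrow(h), 2)
  expect_equal(h$width, c(0.6, 1.2), tolerance = 0.05)
})

test_that("a trough spanning the wrap point is one hole", {
  tro <- data.frame(start = 49.6, width = 0.8, floor = 0.1)  # wraps L = 50
  p <- make_trough_profile(tro)
  h <- detect_holes(p, "WFA", threshold = 1500)
  expect_equal(nrow(h), 1)
  expect_equal(h$width, 0.8, tolerance = 0.05)
  expect_gt(h$start, h$end %% 50)  # circular interval crossing the origin
})

test_that("profiles entirely above threshold give an empty hole set", {
  p <- make_trough_profile(data.frame(start = numeric(), width = numeric(),
                                      floor = numeric()))
  h <- detect_holes(p, "WFA", threshold = 1000)
  expect_equal(nrow(h), 0)
  expect_equal(holes_per_perimeter(h), 0)
})

test_that("detect_holes agrees exactly with the run-length oracle", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(c(200, 500, 2000), 1)
    L <- runif(1, 20, 80)
    # smooth random profile with plenty of threshold crossings
    v <- 1500 + cumsum(rnorm(n)) * 50
    v <- v - mean(v) + 1500 + 400 * sin(seq(0, 8 * pi, length.out = n))
    p <- line_profile((0:(n - 1)) * (L / n), list(WFA = v), L)
    thr <- runif(1, 1200, 1800)
    got <- detect_holes(p, "WFA", thr, w_min = 0.5)
    ref <- oracle_holes(v, L, thr, w_min = 0.5)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$start, ref$start, tolerance = 1e-10)
    expect_equal(got$width, ref$width, tolerance = 1e-10)
  }
})

test_that("threshold sweep reproduces the exhaustive two-trough analysis", {
  tro <- data.frame(start = c(10, 30), width = c(1, 1), floor = c(0.30, 0.55))
  p <- make_trough_profile(tro)
  # manual exhaustive scan over the sweep grid
  pk <- unsaturated_peak(p)
  fs <- seq(0.40, 0.66, by = 0.01)
  counts <- vapply(fs, function(f)
    nrow(detect_holes(p, "WFA", f * pk)), integer(1))
  expect_true(all(counts[fs < 0.55] == 1))
  expect_true(all(counts[fs >= 0.56] == 2))
  res <- select_threshold(p)
  expect_equal(res$n_holes, 2)
  expect_gte(res$fraction_of_peak, 0.56)
  expect_lte(res$fraction_of_peak, 0.66)
  expect_equal(res$fraction_of_peak, fs[which.max(counts)])  # smallest max
})

test_that("ties over all-zero counts resolve to the smallest fraction", {
  # never below 0.66 x peak: zero holes at every fraction, f_min returned
  tro <- data.frame(start = 10, width = 2, floor = 0.70)
  p <- make_trough_profile(tro)
  res <- select_threshold(p)
  expect_equal(res$n_holes, 0)
  expect_equal(res$fraction_of_peak, 0.40)
})

test_that("noise-free synthetic cohorts are recovered perfectly", {
  spec <- net_spec(n_holes = 20, wfa_floor_frac = 0.10, snr = Inf)
  syn <- simulate_profile(spec, occupancy_presets("fig1gh"), seed = 23)
  res <- select_threshold(syn$profile)
  h <- detect_holes(syn$profile, "WFA", res$threshold)
  expect_equal(nrow(h), 20)
  expect_equal(holes_per_perimeter(h), 20 / syn$truth$L)
  # detected intervals contain the true centres
  ctr <- (syn$truth$holes$start + syn$truth$holes$width / 2) %% syn$truth$L
  hits <- vapply(ctr, function(cc) {
    any(((cc - h$start) %% syn$truth$L) < h$width)
  }, logical(1))
  expect_true(all(hits))
})

test_that("below-threshold arc length is monotone in the threshold", {
  spec <- net_spec(n_holes = 15, snr = 10)
  syn <- simulate_profile(spec, occupancy_presets("fig1gh"), seed = 29)
  pk <- unsaturated_peak(syn$profile)
  arc <- vapply(seq(0.40, 0.66, by = 0.02), function(f) {
    h <- detect_holes(syn$profile, "WFA", f * pk, w_min = 0)
    sum(h$width)
  }, numeric(1))
  expect_true(all(diff(arc) >= -1e-9))
})

test_that("circular rotation shifts holes without changing widths or calls", {
  spec <- net_spec(n_holes = 12, snr = 20)
  syn <- simulate_profile(spec, occupancy_presets("fig2cd"), seed = 37)
  p <- syn$profile
  n <- nrow(p)
  k <- 500
  L <- profile_perimeter(p)
  ds <- profile_ds(p)
  rot_idx <- ((seq_len(n) - 1 + k) %% n) + 1
  pr <- line_profile(p$s, lapply(
    as.list(tibble::as_tibble(p)[profile_channels(p)]),
    function(v) v[rot_idx]), L)
  thr <- 0.5 * unsaturated_peak(p)
  h0 <- detect_holes(p, "WFA", thr)
  h1 <- detect_holes(pr, "WFA", thr)
  expect_equal(nrow(h0), nrow(h1))
  shift_back <- sort((h1$start + k * ds) %% L)
  expect_equal(sort(h0$start), shift_back, tolerance = 1e-8)
  expect_equal(sort(h0$width), sort(h1$width), tolerance = 1e-8)
  c0 <- classify_occupancy(h0, p)
  c1 <- classify_occupancy(h1, pr)
  expect_equal(sum(c0$present), sum(c1$present))
})
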