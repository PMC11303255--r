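test_that("identical seed and config give bit-identical outputs", {
  spec <- net_spec(snr = 10)
  occ <- occupancy_presets("fig2cd")
  a <- simulate_profile(spec, occ, seed = 11)
  b <- simulate_profile(spec, occ, seed = 11)
  expect_identical(a$profile$WFA, b$profile$WFA)
  expect_identical(a$truth$holes, b$truth$holes)

  ia <- simulate_net_image(net_spec(n_holes = 4, contour_radius = 3), occ, 5)
  ib <- simulate_net_image(net_spec(n_holes = 4, contour_radius = 3), occ, 5)
  expect_identical(ia$image$channels$WFA, ib$image$channels$WFA)

  sa <- simulate_uptake_sweeps(80, 0.04, n_sweeps = 3, noise_sd = 5, seed = 2)
  sb <- simulate_uptake_sweeps(80, 0.04, n_sweeps = 3, noise_sd = 5, seed = 2)
  expect_identical(sa$sweeps$i, sb$sweeps$i)

  ea <- simulate_eeg(30, seed = 4)
  eb <- simulate_eeg(30, seed = 4)
  expect_identical(ea$eeg$v, eb$eeg$v)
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_profile(net_spec(), occupancy_presets("fig1gh"), 9))
  expect_identical(.Random.seed, before)
})

test_that("noise-free profiles dip below 40% of peak exactly on the true holes", {
  spec <- net_spec(n_holes = 3, hole_width = c(1, 1), snr = Inf)
  syn <- simulate_profile(spec, occupancy_presets("fig1gh"), seed = 31)
  v <- syn$profile$WFA
  s <- syn$profile$s
  L <- profile_perimeter(syn$profile)
  thr <- 0.40 * spec$wfa_peak_level
  below <- v < thr
  # geometric soundness: every truth interval strictly below 0.40 x peak
  for (k in seq_len(3)) {
    rel <- (s - syn$truth$holes$start[k]) %% L
    inside <- rel < syn$truth$holes$width[k]
    expect_true(all(v[inside] < thr))
  }
  # and the below-threshold set forms exactly 3 disjoint circular arcs
  det <- detect_holes(syn$profile, "WFA", thr, w_min = 0.5)
  expect_equal(nrow(det), 3)
})

test_that("degenerate occupancy gives no marker peaks in any hole", {
  occ <- occupancy_profile(c("AldheGFP"), c(none = 1))
  syn <- simulate_profile(net_spec(n_holes = 10), occ, seed = 17)
  expect_false(any(syn$truth$occupancy$present))
  expect_true(all(is.na(syn$truth$occupancy$center)))
  # the marker channel is flat background
  expect_equal(stats::sd(syn$profile$AldheGFP), 0)
})

test_that("occupancy sampling converges to the profile probabilities", {
  # 10,000 holes drawn with P(both) = 0.44: empirical fraction within
  # 3 binomial sd (binomial sampling oracle)
  occ <- occupancy_presets("fig2cd")
  spec <- net_spec(n_holes = 25)
  n_cells <- 400  # 10,000 holes
  combos <- unlist(lapply(simulate_cohort(spec, occ, n_cells, seed = 77),
                          function(x) x$truth$combos))
  n <- length(combos)
  expect_equal(n, 10000)
  p <- 0.44
  frac <- mean(combos == "AldheGFP+vGlut1")
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  # conservation: exclusive categories sum to the number of holes
  expect_equal(sum(table(combos)), n)
})

test_that("marker bumps are centred inside their holes with contract amplitude", {
  spec <- net_spec(n_holes = 20, snr = 10)
  syn <- simulate_profile(spec, occupancy_presets("fig1gh"), seed = 13)
  occ_tab <- syn$truth$occupancy
  hol <- syn$truth$holes
  L <- syn$truth$L
  for (r in which(occ_tab$present)) {
    h <- hol[hol$hole == occ_tab$hole[r], ]
    rel <- (occ_tab$center[r] - h$start) %% L
    expect_gte(rel, 0.2 * h$width - 1e-9)
    expect_lte(rel, 0.8 * h$width + 1e-9)
  }
  expect_gte(spec$marker_amp, 5 * spec$noise_sd)
})

test_that("infeasible hole geometry raises a geometry error", {
  spec <- net_spec(contour_radius = 2, n_holes = 20, hole_width = c(1, 1))
  expect_error(simulate_profile(spec, occupancy_presets("fig1gh"), 1),
               "infeasible geometry")
})

test_that("net image geometry matches the requested calibration", {
  # ring of radius 8 um at 0.031 um/px spans about 516 px across
  spec <- net_spec(contour_radius = 8, pixel_size = 0.031, n_holes = 0)
  syn <- simulate_net_image(spec, occupancy_presets("fig1gh"), seed = 1)
  wfa <- syn$image$channels$WFA
  mid <- round(nrow(wfa) / 2)
  lit <- which(wfa[mid, ] > 0.5 * spec$wfa_peak_level)
  left <- lit[lit < ncol(wfa) / 2]; right <- lit[lit > ncol(wfa) / 2]
  # distance between the ring's left and right centre lines = diameter
  expect_equal(mean(range(right)) - mean(range(left)), 2 * 8 / 0.031,
               tolerance = 0.005)
  # no holes: profile along the circle is constant within PSF tolerance
  prof <- extract_profile(syn$image, syn$contour)
  expect_lt(stats::sd(prof$WFA) / mean(prof$WFA), 0.02)
})

test_that("pericellular image honours coverage and puncta ground truth", {
  syn0 <- simulate_pericellular_image(band_coverage = 0, n_puncta = 0, seed = 2)
  expect_equal(sum(syn0$image$channels$astro), 0)

  syn <- simulate_pericellular_image(band_coverage = 1, n_puncta = 50,
                                     puncta_amp = 1500, seed = 3)
  expect_equal(nrow(syn$truth$puncta), 50)
  expect_true(all(syn$truth$puncta$astro_contact))
  # closed-form annulus: normalized coverage = band area / perimeter
  r <- syn$truth$soma_radius; w <- syn$truth$band_width
  expect_equal(pi * ((r + w)^2 - r^2) / (2 * pi * r), 0.864, tolerance = 1e-3)
})

test_that("uptake sweep generator matches its analytic kinetics", {
  g <- simulate_uptake_sweeps(peak = 120, tau_decay = 0.04, n_sweeps = 3,
                              noise_sd = 0, seed = 1)
  avg <- qc_and_average(g$sweeps, g$truth$baseline_window)
  expect_equal(min(avg$i), -120)           # averaged peak exact at zero noise
  met <- trace_metrics(avg, c(g$truth$t_stim - 0.01, 1))
  expect_equal(met$peak_pa, 120)
  # 100% -> 37% decay time approximates tau within one sample interval
  expect_equal(met$decay_time_ms, 40, tolerance = 1000 / g$truth$fs / 40 + 0.01)
})

test_that("eeg generator embeds epochs and validates overlap", {
  g0 <- simulate_eeg(20, seed = 5)
  expect_equal(nrow(g0$truth$seizure_epochs), 0)
  sz <- tibble::tibble(t_start = c(5, 8), duration = c(5, 5),
                       spike_hz = 3, amp_ratio = 2.5)
  expect_error(simulate_eeg(30, seizures = sz, seed = 5), "overlap")
  g1 <- simulate_eeg(40, seizures = tibble::tibble(
    t_start = 10, duration = 10, spike_hz = 3, amp_ratio = 2.5), seed = 5)
  expect_equal(length(g1$truth$spike_times), 30)
  expect_true(all(g1$truth$spike_times >= 10 & g1$truth$spike_times <= 20))
})
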