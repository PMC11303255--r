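rect_sweep <- function(amp = 50, t_on = 0.2, dur = 0.1, fs = 10000,
                       total = 1) {
  t <- seq(0, total - 1 / fs, by = 1 / fs)
  on <- seq(round(t_on * fs) + 1, round((t_on + dur) * fs))  # [t_on, t_on+dur)
  i <- numeric(length(t)); i[on] <- amp
  tibble::tibble(t = t, i = i)
}

test_that("identical sweeps average to themselves and noisy ones are excluded", {
  g <- simulate_uptake_sweeps(60, 0.05, n_sweeps = 4, noise_sd = 0, seed = 1)
  avg <- qc_and_average(g$sweeps, g$truth$baseline_window)
  one <- dplyr::filter(g$sweeps, sweep == 1)
  expect_equal(avg$i, one$i)
  expect_equal(attr(avg, "n_sweeps_used"), 4)

  # one sweep with 10 x baseline noise among five clean: excluded
  set.seed(2)
  clean <- simulate_uptake_sweeps(60, 0.05, n_sweeps = 5, noise_sd = 2,
                                  seed = 3)$sweeps
  bad <- dplyr::filter(clean, sweep == 5)
  bad$i <- bad$i + rnorm(nrow(bad), 0, 20)
  sweeps <- dplyr::bind_rows(dplyr::filter(clean, sweep != 5), bad)
  avg2 <- qc_and_average(sweeps, c(0, 0.18))
  expect_equal(attr(avg2, "n_sweeps_used"), 4)
  expect_equal(attr(avg2, "excluded"), 5)

  # QC failure when survivors drop below the minimum
  expect_error(
    qc_and_average(dplyr::filter(clean, sweep %in% 1:3), c(0, 0.18),
                   min_used = 4),
    "QC failure")
})

test_that("baseline correction recovers flat and ramped baselines", {
  t <- seq(0, 1, by = 1e-4)
  flat <- tibble::tibble(t = t, i = rep(-12, length(t)))
  bc <- baseline_correct(flat, c(0, 0.2))
  expect_true(all(abs(bc$i) < 1e-12))
  ramp <- tibble::tibble(t = t, i = 3 + 5 * t)
  bc2 <- baseline_correct(ramp, c(0, 0.2), detrend = TRUE)
  expect_lt(abs(mean(bc2$i)), 1e-9)
  expect_error(baseline_correct(flat, c(0, 1e-5)), "fewer than 10")
})

test_that("rectangular pulse charge equals amplitude times duration", {
  sw <- rect_sweep(amp = 50, dur = 0.1)      # 50 pA x 100 ms = 5 pC
  met <- trace_metrics(sw, c(0.1, 0.9))
  expect_equal(met$charge_pc, 5, tolerance = 1e-3)
  expect_equal(met$peak_pa, 50)
})

test_that("exponential decay time equals tau within one sample interval", {
  fs <- 10000
  g <- simulate_uptake_sweeps(100, 0.04, n_sweeps = 2, noise_sd = 0,
                              seed = 1, fs = fs)
  avg <- qc_and_average(g$sweeps, g$truth$baseline_window)
  met <- trace_metrics(avg, c(0.19, 1))
  # the 37% crossing of a pure exponential sits at tau * ln(1/0.37)
  expect_equal(met$decay_time_ms, -0.04 * log(0.37) * 1000,
               tolerance = (1000 / fs) / 40)
  expect_equal(met$decay_time_ms, 40, tolerance = 0.01)
  expect_equal(met$polarity, -1)
  expect_equal(met$decay_slope_pa_ms, (100 - 37) / met$decay_time_ms)
  # charge of a one-sided exponential: peak x tau
  expect_equal(met$charge_pc, 100 * 0.04, tolerance = 0.01)
})

test_that("zero traces censor the decay", {
  t <- seq(0, 1, by = 1e-4)
  met <- trace_metrics(tibble::tibble(t = t, i = 0 * t), c(0, 1))
  expect_equal(met$peak_pa, 0)
  expect_true(met$decay_censored)
  expect_true(is.na(met$decay_time_ms))
})

test_that("charge is linear in trace scale and additive over windows", {
  sw <- rect_sweep(amp = 40, dur = 0.2)
  m1 <- trace_metrics(sw, c(0.1, 0.9))
  sw3 <- sw; sw3$i <- -3 * sw$i
  m3 <- trace_metrics(sw3, c(0.1, 0.9))
  expect_equal(m3$charge_pc, 3 * m1$charge_pc)
  a <- trace_metrics(sw, c(0.1, 0.25))$charge_pc
  b <- trace_metrics(sw, c(0.25, 0.9))$charge_pc
  expect_equal(a + b, m1$charge_pc, tolerance = 1e-6)
})

test_that("decay metrics survive baseline offset and resampling", {
  fs1 <- 5000; fs2 <- 10000
  g1 <- simulate_uptake_sweeps(80, 0.03, 2, 0, seed = 1, fs = fs1)
  g2 <- simulate_uptake_sweeps(80, 0.03, 2, 0, seed = 1, fs = fs2)
  m1 <- trace_metrics(qc_and_average(g1$sweeps, c(0, 0.18)), c(0.19, 1))
  m2 <- trace_metrics(qc_and_average(g2$sweeps, c(0, 0.18)), c(0.19, 1))
  expect_equal(m1$decay_time_ms, m2$decay_time_ms,
               tolerance = 1000 / fs1 / 30)
  off <- qc_and_average(g1$sweeps, c(0, 0.18))
  off$i <- off$i - 15
  m3 <- trace_metrics(baseline_correct(off, c(0, 0.18)), c(0.19, 1))
  expect_equal(m3$peak_pa, m1$peak_pa, tolerance = 1e-9)
})

test_that("averaging n clean sweeps shrinks baseline noise like 1/sqrt(n)", {
  g <- simulate_uptake_sweeps(0, 0.05, n_sweeps = 5, noise_sd = 10, seed = 21,
                              duration = 2, t_stim = 1.9)
  avg <- qc_and_average(g$sweeps, c(0, 1.8))
  sd_avg <- stats::sd(avg$i[avg$t <= 1.8])
  expect_equal(sd_avg, 10 / sqrt(5), tolerance = 0.2)
})

test_that("io_curve assembles the ladder and recovers a linear response", {
  stim <- glu_protocol()
  gs <- simulate_uptake_sweepset(stim, peaks = 1.5 * stim, tau_decay = 0.04,
                                 n_sweeps = 3, noise_sd = 1, seed = 31)
  cur <- io_curve(gs$sweeps, gs$truth$baseline_window, c(0.19, 1))
  expect_equal(nrow(cur), length(stim))
  fit <- stats::lm(peak_pa ~ stimulus, data = cur)
  expect_equal(unname(stats::coef(fit)["stimulus"]), 1.5, tolerance = 0.05)
  # single level works; empty set errors
  one <- io_curve(dplyr::filter(gs$sweeps, stimulus == 10),
                  gs$truth$baseline_window, c(0.19, 1))
  expect_equal(nrow(one), 1)
  expect_error(io_curve(gs$sweeps[0, ], c(0, 0.1), c(0.2, 1)), "empty")
})

test_that("iGluSnFR net change is the ACSF-normalized percentage", {
  expect_equal(iglusnfr_net_change(10, 10), 0)
  expect_equal(iglusnfr_net_change(10, 14), 40)
  expect_error(iglusnfr_net_change(0, 5), "positive")
  # generator algebra: blocking uptake fraction u raises the peak to
  # 1 / (1 - u), so the net change is 100 u / (1 - u)
  u <- 0.3
  acsf <- 12
  blocked <- acsf / (1 - u)
  expect_equal(iglusnfr_net_change(acsf, blocked), 100 * u / (1 - u))
})
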