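#' Quality-control and average repeated sweeps
#'
#' Excludes sweeps whose baseline-window standard deviation exceeds
#' `baseline_sd_factor` times the group median (the formalization of
#' discarding sweeps with baseline fluctuation or noise) and returns the
#' pointwise mean of the survivors. At least `min_used` sweeps must survive.
#'
#' @param sweeps Tidy sweep table with columns `sweep`, `t`, `i` (pA).
#' @param baseline_window `c(t0, t1)` seconds; must precede the response.
#' @param min_used Minimum number of surviving sweeps (default 2).
#' @param baseline_sd_factor Exclusion factor on the median baseline sd.
#' @return A tibble `t`, `i` (the averaged sweep) with attributes
#'   `n_sweeps_used` and `excluded` (sweep ids).
#' @export
qc_and_average <- function(sweeps, baseline_window, min_used = 2,
                           baseline_sd_factor = 3.0) {
  stopifnot(all(c("sweep", "t", "i") %in% names(sweeps)))
  base <- dplyr::filter(sweeps, .data$t >= baseline_window[1],
                        .data$t <= baseline_window[2])
  sds <- dplyr::summarise(dplyr::group_by(base, .data$sweep),
                          sd = stats::sd(.data$i), .groups = "drop")
  med <- stats::median(sds$sd)
  # a zero-noise group accepts everything
  ok <- if (med == 0) sds$sweep else sds$sweep[sds$sd <= baseline_sd_factor * med]
  if (length(ok) < min_used) {
    stop(sprintf("QC failure: only %d of %d sweeps pass (need >= %d)",
                 length(ok), nrow(sds), min_used), call. = FALSE)
  }
  avg <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(sweeps, .data$sweep %in% ok), .data$t),
    i = mean(.data$i), .groups = "drop")
  avg <- dplyr::arrange(avg, .data$t)
  attr(avg, "n_sweeps_used") <- length(ok)
  attr(avg, "excluded") <- setdiff(sds$sweep, ok)
  avg
}

#' Baseline-correct a sweep
#'
#' Subtracts the baseline-window mean; with `detrend = TRUE` a line fitted
#' over the baseline window is extrapolated and subtracted instead (flagged
#' in the `detrended` attribute).
#'
#' @param sweep Tibble with `t`, `i`.
#' @param baseline_window `c(t0, t1)` seconds spanning >= 10 samples.
#' @param detrend Remove a linear baseline trend.
#' @return The corrected sweep tibble.
#' @export
baseline_correct <- function(sweep, baseline_window, detrend = FALSE) {
  in_base <- sweep$t >= baseline_window[1] & sweep$t <= baseline_window[2]
  if (sum(in_base) < 10) {
    stop("baseline window spans fewer than 10 samples", call. = FALSE)
  }
  out <- sweep
  if (detrend) {
    fit <- stats::lm(i ~ t, data = sweep[in_base, ])
    out$i <- sweep$i - stats::predict(fit, newdata = sweep["t"])
  } else {
    out$i <- sweep$i - mean(sweep$i[in_base])
  }
  attr(out, "detrended") <- detrend
  out
}

#' Peak, charge transfer and decay metrics of a response
#'
#' On a baseline-corrected sweep: the peak is the extremum magnitude inside
#' the response window; charge transfer is the absolute trapezoidal area
#' under the curve over the window (pA x s = pC); decay time is the time
#' from the peak sample to the first crossing of 37% of the peak
#' (approximately 1/e) afterwards, linearly interpolated between samples;
#' decay slope is `(peak - 0.37 peak) / decay_time`. If the trace never
#' falls to 37% inside the window the decay is censored (`NA`, flag set).
#'
#' @param sweep Tibble with `t` (s), `i` (pA), baseline-corrected.
#' @param response_window `c(t0, t1)` seconds.
#' @return A one-row tibble: `peak_pa`, `polarity` (+1/-1), `charge_pc`,
#'   `decay_time_ms`, `decay_slope_pa_ms`, `decay_censored`, `t_peak`.
#' @export
trace_metrics <- function(sweep, response_window) {
  w <- sweep$t >= response_window[1] & sweep$t <= response_window[2]
  if (!any(w)) stop("empty response window", call. = FALSE)
  t <- sweep$t[w]; i <- sweep$i[w]
  k <- which.max(abs(i))
  peak <- abs(i[k])
  polarity <- if (peak == 0) 1 else sign(i[k])
  charge <- abs(pracma::trapz(t, i))
  decay_time <- NA_real_
  censored <- TRUE
  if (peak > 0) {
    target <- 0.37 * peak
    after <- abs(i[k:length(i)])
    cross <- which(after <= target)[1]
    if (!is.na(cross) && cross > 1) {
      j <- k + cross - 1
      # interpolate between samples j-1 (above) and j (at/below)
      f <- (abs(i[j - 1]) - target) / (abs(i[j - 1]) - abs(i[j]))
      decay_time <- (t[j - 1] + f * (t[j] - t[j - 1]) - t[k]) * 1000
      censored <- FALSE
    }
  }
  tibble::tibble(
    peak_pa = peak, polarity = polarity, charge_pc = charge,
    decay_time_ms = decay_time,
    decay_slope_pa_ms = if (!censored) (peak - 0.37 * peak) / decay_time
                        else NA_real_,
    decay_censored = censored, t_peak = t[k]
  )
}

#' Input--output curve over a stimulus ladder
#'
#' Per stimulus level: QC-and-average the repeated sweeps, baseline-correct,
#' and compute [trace_metrics()]. Levels whose sweeps fail QC are reported
#' as missing rows rather than aborting the curve.
#'
#' @param sweeps Tidy sweep table: `stimulus`, `sweep`, `t`, `i`.
#' @param baseline_window,response_window Seconds.
#' @param ladder Stimulus levels expected in the protocol (default: the
#'   levels present in the data); missing levels appear as `NA` rows.
#' @inheritParams qc_and_average
#' @return A tibble keyed by `stimulus` with the metric columns plus
#'   `n_sweeps_used` (`NA` where QC failed or no data).
#' @export
io_curve <- function(sweeps, baseline_window, response_window,
                     ladder = NULL, min_used = 2, baseline_sd_factor = 3.0) {
  stopifnot(all(c("stimulus", "sweep", "t", "i") %in% names(sweeps)))
  if (nrow(sweeps) == 0) stop("empty sweep set", call. = FALSE)
  if (is.null(ladder)) ladder <- sort(unique(sweeps$stimulus))
  purrr::map_dfr(ladder, function(lv) {
    sub <- dplyr::filter(sweeps, .data$stimulus == lv)
    miss <- tibble::tibble(stimulus = lv, peak_pa = NA_real_,
                           polarity = NA_real_, charge_pc = NA_real_,
                           decay_time_ms = NA_real_,
                           decay_slope_pa_ms = NA_real_,
                           decay_censored = NA, t_peak = NA_real_,
                           n_sweeps_used = NA_integer_)
    if (nrow(sub) == 0) return(miss)
    avg <- tryCatch(
      qc_and_average(sub, baseline_window, min_used, baseline_sd_factor),
      error = function(e) NULL)
    if (is.null(avg)) return(miss)
    n_used <- attr(avg, "n_sweeps_used")
    met <- trace_metrics(baseline_correct(avg, baseline_window),
                         response_window)
    dplyr::bind_cols(tibble::tibble(stimulus = lv), met,
                     tibble::tibble(n_sweeps_used = n_used))
  })
}

#' iGluSnFR percent net change after transporter blockade
#'
#' The peak fluorescence transient recorded in ACSF is taken as 100%; the
#' net change is the blocked-condition peak relative to it:
#' `100 * (peak_blocked - peak_acsf) / peak_acsf`. A positive value is the
#' extra glutamate signal unmasked by blocking uptake.
#'
#' @param peak_acsf Peak transient before blockade (a.u.), must be > 0.
#' @param peak_blocked Peak transient under TBOA + DHK (a.u.).
#' @return Percent net change.
#' @export
iglusnfr_net_change <- function(peak_acsf, peak_blocked) {
  if (any(peak_acsf <= 0)) {
    stop("ACSF peak must be positive to serve as the 100% reference",
         call. = FALSE)
  }
  100 * (peak_blocked - peak_acsf) / peak_acsf
}

#' Read sweeps from CSV
#'
#' Expects columns `t` and `i` (plus optional `sweep`, `stimulus`); one file
#' per recording or a tidy multi-sweep table.
#'
#' @param path CSV path.
#' @return A tidy sweep tibble.
#' @export
read_sweeps_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t", "i") %in% names(tb))) {
    stop("sweep CSV needs `t` and `i` columns", call. = FALSE)
  }
  if (!"sweep" %in% names(tb)) tb$sweep <- 1L
  tb
}
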