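#' Detect electrographic seizures on an EEG trace
#'
#' Implements the three-part scoring rule for electrographic seizures:
#' discharges with amplitude at least `amp_factor` times the average
#' baseline amplitude, at a rate of at least `min_rate`, sustained for at
#' least `min_dur`. Spikes are supra-threshold excursions of the rectified
#' trace (threshold = `amp_factor` x baseline amplitude, where baseline
#' amplitude is the mean windowed peak deflection of the seizure-free
#' baseline window; see [simulate_eeg()] for the statistic); excursions
#' closer than 1 ms merge. Candidate events are maximal spike spans with
#' inter-spike intervals <= `1 / min_rate`, padded by one interval of slack
#' at each end; events are kept when their duration reaches `min_dur` and
#' their mean spike rate reaches `min_rate`.
#'
#' @param eeg Tibble with columns `t` (s) and `v` (µV); sampling rate from
#'   the `fs` attribute or inferred from `t`.
#' @param baseline_window `c(t0, t1)` seconds, assumed seizure-free.
#' @param min_rate Minimum spike rate, Hz (default 2).
#' @param min_dur Minimum event duration, s (default 5).
#' @param amp_factor Amplitude criterion relative to baseline (default 2).
#' @param refractory Merge window for threshold crossings, s.
#' @return A tibble of class `seizure_events`: `t_start`, `t_end`,
#'   `duration`, `n_spikes`, `spike_rate`, `mean_amplitude_ratio`.
#'   Seizure latency is the `t_start` of the first event.
#' @export
detect_seizures <- function(eeg, baseline_window, min_rate = 2, min_dur = 5,
                            amp_factor = 2.0, refractory = 0.001) {
  stopifnot(all(c("t", "v") %in% names(eeg)))
  v <- eeg$v; t <- eeg$t
  if (length(v) < 2 || stats::sd(v) == 0) {
    stop("empty or constant EEG record", call. = FALSE)
  }
  fs <- attr(eeg, "fs") %||% (1 / stats::median(diff(t)))
  base <- v[t >= baseline_window[1] & t <= baseline_window[2]]
  if (length(base) < fs) {
    stop("baseline window too short", call. = FALSE)
  }
  a_base <- eeg_amplitude_stat(base, fs)
  thr <- amp_factor * a_base

  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          duration = numeric(), n_spikes = integer(),
                          spike_rate = numeric(),
                          mean_amplitude_ratio = numeric())
  class(empty) <- c("seizure_events", class(empty))
  attr(empty, "baseline_amp") <- a_base

  above <- abs(v) >= thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  exc <- which(r$values)
  spike_t <- numeric(length(exc))
  spike_a <- numeric(length(exc))
  for (m in seq_along(exc)) {
    idx <- starts[exc[m]]:ends[exc[m]]
    k <- idx[which.max(abs(v[idx]))]
    spike_t[m] <- t[k]
    spike_a[m] <- abs(v[k])
  }
  # merge excursions within the refractory window
  if (length(spike_t) > 1) {
    grp <- cumsum(c(TRUE, diff(spike_t) > refractory))
    spike_a <- tapply(spike_a, grp, max)
    spike_t <- tapply(spike_t, grp, function(x) x[1])
  }

  gap <- 1 / min_rate
  ev_grp <- cumsum(c(TRUE, diff(spike_t) > gap))
  events <- purrr::map_dfr(split(seq_along(spike_t), ev_grp), function(idx) {
    t0 <- spike_t[idx[1]] - gap
    t1 <- spike_t[idx[length(idx)]] + gap
    t0 <- max(t0, t[1]); t1 <- min(t1, t[length(t)])
    dur <- t1 - t0
    tibble::tibble(t_start = t0, t_end = t1, duration = dur,
                   n_spikes = length(idx),
                   spike_rate = length(idx) / dur,
                   mean_amplitude_ratio = mean(spike_a[idx]) / a_base)
  })
  events <- events[events$duration >= min_dur &
                     events$spike_rate >= min_rate, ]
  class(events) <- c("seizure_events", class(events))
  attr(events, "baseline_amp") <- a_base
  events
}

#' Read an EEG trace from CSV
#'
#' Expects `t` (s) and `v` (µV) columns; the sampling rate is inferred from
#' the time column and stored as the `fs` attribute.
#'
#' @param path CSV path.
#' @return An EEG tibble.
#' @export
read_eeg_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t", "v") %in% names(tb))) {
    stop("EEG CSV needs `t` and `v` columns", call. = FALSE)
  }
  attr(tb, "fs") <- 1 / stats::median(diff(tb$t))
  tb
}
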