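#' Simulate astrocytic uptake-current sweeps
#'
#' Each sweep is a flat (zero) baseline followed by an inward (negative)
#' current deflection at `t_stim` with instantaneous rise and exponential
#' decay (or alpha-function kinetics), plus additive Gaussian noise. The
#' stimulus pulse is repeated `n_sweeps` times, as in an evoked-uptake
#' recording where each stimulus level is delivered as several sweeps.
#'
#' @param peak Peak current magnitude, pA (deflection is inward/negative).
#' @param tau_decay Decay time constant, s.
#' @param n_sweeps Number of repeated sweeps.
#' @param noise_sd Gaussian noise sd, pA.
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz.
#' @param duration Sweep length, s.
#' @param t_stim Stimulus time, s.
#' @param stimulus Stimulus amplitude label (µA or mA), carried through.
#' @param kinetics `"exp"` (instantaneous rise) or `"alpha"`.
#' @return A list with `sweeps` (tibble: `sweep`, `stimulus`, `t`, `i`) and
#'   `truth` (`peak`, `tau_decay`, `t_stim`, `baseline_window`).
#' @export
simulate_uptake_sweeps <- function(peak, tau_decay, n_sweeps = 5,
                                   noise_sd = 0, seed = 1, fs = 10000,
                                   duration = 1, t_stim = 0.2,
                                   stimulus = NA_real_, kinetics = c("exp", "alpha")) {
  stopifnot(n_sweeps >= 1, peak >= 0, tau_decay > 0, t_stim < duration)
  kinetics <- match.arg(kinetics)
  with_rng(seed, {
    t <- seq(0, duration - 1 / fs, by = 1 / fs)
    dt <- t - t_stim
    shape <- numeric(length(t))
    on <- dt >= 0
    if (kinetics == "exp") {
      shape[on] <- exp(-dt[on] / tau_decay)
    } else {
      shape[on] <- (dt[on] / tau_decay) * exp(1 - dt[on] / tau_decay)
    }
    clean <- -peak * shape
    sweeps <- purrr::map_dfr(seq_len(n_sweeps), function(k) {
      i <- clean
      if (noise_sd > 0) i <- i + stats::rnorm(length(t), 0, noise_sd)
      tibble::tibble(sweep = k, stimulus = stimulus, t = t, i = i)
    })
    list(
      sweeps = sweeps,
      truth = list(peak = peak, tau_decay = tau_decay, t_stim = t_stim,
                   kinetics = kinetics, fs = fs,
                   baseline_window = c(0, t_stim * 0.9))
    )
  })
}

#' Simulate a stimulus-ladder sweep set
#'
#' One [simulate_uptake_sweeps()] call per stimulus level, with per-level
#' peaks, bound into a single tidy sweep table for [io_curve()].
#'
#' @param stimuli Stimulus ladder (µA or mA), e.g. [glu_protocol()].
#' @param peaks Peak magnitudes per level, pA (recycled if scalar slope use
#'   `peaks = slope * stimuli`).
#' @inheritParams simulate_uptake_sweeps
#' @return A list with `sweeps` (tibble) and `truth` (per-level peaks, tau).
#' @export
simulate_uptake_sweepset <- function(stimuli, peaks, tau_decay,
                                     n_sweeps = 5, noise_sd = 0, seed = 1,
                                     fs = 10000, duration = 1, t_stim = 0.2) {
  stopifnot(length(stimuli) >= 1, length(peaks) %in% c(1, length(stimuli)))
  peaks <- rep_len(peaks, length(stimuli))
  seeds <- with_rng(seed, sample.int(.Machine$integer.max - 1L, length(stimuli)))
  parts <- purrr::map(seq_along(stimuli), function(j) {
    simulate_uptake_sweeps(peaks[j], tau_decay, n_sweeps, noise_sd,
                           seed = seeds[j], fs = fs, duration = duration,
                           t_stim = t_stim, stimulus = stimuli[j])$sweeps
  })
  list(
    sweeps = dplyr::bind_rows(parts),
    truth = list(stimuli = stimuli, peaks = peaks, tau_decay = tau_decay,
                 t_stim = t_stim, fs = fs,
                 baseline_window = c(0, t_stim * 0.9))
  )
}

#' Stimulus ladder presets
#'
#' The synaptically evoked glutamate-uptake protocol steps 10 and 20 µA then
#' 20-µA increments to 200 µA; the depolarization-evoked potassium protocol
#' steps 0.1 and 0.2 mA then 0.5 mA and 0.5-mA increments to 3 mA (200 µs
#' pulses in both).
#'
#' @return Numeric stimulus ladder (µA for glutamate, mA for potassium).
#' @export
glu_protocol <- function() c(10, 20, seq(40, 200, by = 20))

#' @rdname glu_protocol
#' @export
k_protocol <- function() c(0.1, 0.2, seq(0.5, 3, by = 0.5))

# Mean per-window maximum absolute deflection: the "amplitude" a scorer
# reads off an EEG trace. Used by both the generator and the detector.
eeg_amplitude_stat <- function(v, fs, win = 0.1) {
  nwin <- max(1L, floor(length(v) / (win * fs)))
  size <- floor(length(v) / nwin)
  idx <- rep(seq_len(nwin), each = size)
  mean(tapply(abs(v[seq_len(nwin * size)]), idx, max))
}

#' Simulate an EEG record with embedded electrographic seizures
#'
#' Background is white Gaussian noise scaled so the mean windowed amplitude
#' (see Details) equals `baseline_amp`. Each seizure epoch adds a rhythmic
#' train of raised-cosine sharp waves at `spike_hz` whose peak amplitude is
#' `amp_ratio` times the realized baseline amplitude, emulating discharges
#' scored against an amplitude-times-two, at-least-2-Hz, at-least-5-s rule.
#'
#' @details "Baseline amplitude" is the mean over non-overlapping 100-ms
#' windows of the maximum absolute deflection: the height of the background
#' waves a reader sees, rather than the mean absolute sample value (which
#' for Gaussian noise sits far below the visible wave height).
#'
#' @param duration Record length, s.
#' @param fs Sampling rate, Hz (default 500, a typical video-EEG setting).
#' @param baseline_amp Target baseline amplitude, µV.
#' @param seizures Tibble/data.frame with columns `t_start`, `duration`,
#'   `spike_hz`, `amp_ratio`; may be empty or `NULL` for a seizure-free record.
#' @param seed Integer seed.
#' @param spike_width Sharp-wave width, s.
#' @return A list with `eeg` (tibble: `t`, `v`; attr `fs`) and `truth`
#'   (epochs, realized baseline amplitude, spike times).
#' @export
simulate_eeg <- function(duration, fs = 500, baseline_amp = 50,
                         seizures = NULL, seed = 1, spike_width = 0.03) {
  if (is.null(seizures)) {
    seizures <- tibble::tibble(t_start = numeric(), duration = numeric(),
                               spike_hz = numeric(), amp_ratio = numeric())
  }
  seizures <- tibble::as_tibble(seizures)
  if (nrow(seizures) > 0) {
    stopifnot(all(seizures$spike_hz >= 0),
              all(seizures$t_start >= 0),
              all(seizures$t_start + seizures$duration <= duration))
    o <- order(seizures$t_start)
    seizures <- seizures[o, ]
    if (nrow(seizures) > 1) {
      ends <- seizures$t_start + seizures$duration
      if (any(seizures$t_start[-1] < ends[-nrow(seizures)])) {
        stop("seizure epochs overlap", call. = FALSE)
      }
    }
  }
  with_rng(seed, {
    n <- as.integer(round(duration * fs))
    t <- (seq_len(n) - 1) / fs
    # E[max |N(0,1)| over 0.1 s at fs] calibrates sd to the target amplitude
    calib <- mean(matrixStats_colmax(abs(matrix(
      stats::rnorm(50 * max(10, round(0.1 * fs))), ncol = 50))))
    sd0 <- baseline_amp / calib
    v <- stats::rnorm(n, 0, sd0)
    a_base <- eeg_amplitude_stat(v, fs)
    spike_times <- numeric()
    half <- spike_width / 2
    for (k in seq_len(nrow(seizures))) {
      hz <- seizures$spike_hz[k]
      if (hz <= 0) next
      t0 <- seizures$t_start[k] + half
      t1 <- seizures$t_start[k] + seizures$duration[k] - half
      st <- seq(t0, t1, by = 1 / hz)
      amp <- seizures$amp_ratio[k] * a_base
      for (tc in st) {
        idx <- which(t > tc - half & t < tc + half)
        v[idx] <- v[idx] + amp * 0.5 * (1 + cos(pi * (t[idx] - tc) / half))
      }
      spike_times <- c(spike_times, st)
    }
    eeg <- tibble::tibble(t = t, v = v)
    attr(eeg, "fs") <- fs
    list(eeg = eeg,
         truth = list(seizure_epochs = seizures, baseline_amp = a_base,
                      spike_times = spike_times, fs = fs, seed = seed))
  })
}

# column maxima without a matrixStats dependency
matrixStats_colmax <- function(m) apply(m, 2, max)
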