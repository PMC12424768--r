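# Spike-train analysis: detection, theta-phase histograms, interspike
# frequency histograms, per-cycle firing statistics.

#' Detect action-potential peaks in a voltage trace
#'
#' Local maxima above a threshold, separated by at least the refractory
#' interval; the registered time is the peak sample.
#'
#' @param v Voltage trace (mV).
#' @param fs Sampling rate (Hz).
#' @param threshold Detection threshold (mV; default 0).
#' @param refractory_ms Minimum separation between detections (ms).
#' @return Spike times (ms), possibly empty.
#' @export
detect_spikes <- function(v, fs, threshold = 0, refractory_ms = 2) {
  n <- length(v)
  if (n < 3) return(numeric(0))
  is_peak <- v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n] &
    v[2:(n - 1)] > threshold
  idx <- which(is_peak) + 1L
  if (length(idx) == 0) return(numeric(0))
  t <- (idx - 1) / fs * 1000
  keep <- logical(length(t))
  last <- -Inf
  for (k in seq_along(t)) {
    if (t[k] - last >= refractory_ms) {
      keep[k] <- TRUE
      last <- t[k]
    }
  }
  t[keep]
}

analysis_window <- function(f_theta, n_cycles, drop_first) {
  period <- 1000 / f_theta
  start <- if (drop_first) period else 0
  c(start, start + n_cycles * period)
}

#' Theta-phase histogram of spike times
#'
#' Registers each spike to the phase of the drive cycle
#' (`phase = 2 pi frac(t f_theta)`, phase 0 at the drive trough), bins
#' into `n_bins` equal bins over `[0, 2 pi)` and normalizes the counts by
#' the number of analyzed theta cycles.
#'
#' @param spike_times Spike times (ms).
#' @param f_theta Theta frequency (Hz).
#' @param n_cycles Analyzed cycles (default 40).
#' @param drop_first Discard spikes in the first cycle (default `TRUE`),
#'   matching the scalogram convention.
#' @param n_bins Number of phase bins (default 30, width pi/15).
#' @return A tibble (`bin_left_rad`, `bin_right_rad`, `count`,
#'   `per_cycle`), with attribute `n_cycles`.
#' @export
phase_histogram <- function(spike_times, f_theta = 8, n_cycles = 40,
                            drop_first = TRUE, n_bins = 30) {
  win <- analysis_window(f_theta, n_cycles, drop_first)
  st <- spike_times[spike_times >= win[1] & spike_times < win[2]]
  phase <- 2 * pi * ((st * f_theta / 1000) %% 1)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  counts <- as.numeric(table(cut(phase, edges, right = FALSE,
                                 include.lowest = TRUE)))
  structure(
    tibble::tibble(bin_left_rad = edges[-(n_bins + 1)],
                   bin_right_rad = edges[-1],
                   count = counts,
                   per_cycle = counts / n_cycles),
    n_cycles = n_cycles, class = c("mec_phase_hist", class(tibble::tibble())))
}

#' Interspike-frequency histogram
#'
#' Each consecutive interspike interval contributes its instantaneous
#' rate `1 / ISI` to a 10 Hz-wide bin (left-closed bins starting at 0);
#' counts are normalized by the number of analyzed theta cycles.
#'
#' @param spike_times Spike times (ms).
#' @param n_cycles Analyzed theta cycles used for normalization.
#' @param bin_width_Hz Bin width (Hz; default 10).
#' @param f_theta,drop_first Analysis window (as [phase_histogram()]).
#'   `f_theta = NULL` uses all spikes.
#' @return A tibble (`bin_left_Hz`, `bin_right_Hz`, `count`,
#'   `per_cycle`); zero rows if fewer than 2 spikes.
#' @export
isi_rate_histogram <- function(spike_times, n_cycles = 40,
                               bin_width_Hz = 10, f_theta = NULL,
                               drop_first = TRUE) {
  st <- sort(spike_times)
  if (!is.null(f_theta)) {
    win <- analysis_window(f_theta, n_cycles, drop_first)
    st <- st[st >= win[1] & st < win[2]]
  }
  if (length(st) < 2) {
    return(tibble::tibble(bin_left_Hz = numeric(0),
                          bin_right_Hz = numeric(0),
                          count = numeric(0), per_cycle = numeric(0)))
  }
  rate <- 1000 / diff(st)
  bin <- floor(rate / bin_width_Hz)
  tab <- table(bin)
  bins <- as.integer(names(tab))
  tibble::tibble(bin_left_Hz = bins * bin_width_Hz,
                 bin_right_Hz = (bins + 1) * bin_width_Hz,
                 count = as.numeric(tab),
                 per_cycle = as.numeric(tab) / n_cycles)
}

#' Mean spikes per theta cycle
#'
#' @param spike_times Spike times (ms).
#' @param f_theta Theta frequency (Hz).
#' @param n_cycles Analyzed cycles.
#' @param drop_first Discard the first cycle (default `TRUE`).
#' @return A one-row tibble: `mean` spikes per cycle and `sem` across
#'   cycles.
#' @export
spikes_per_cycle <- function(spike_times, f_theta = 8, n_cycles = 40,
                             drop_first = TRUE) {
  win <- analysis_window(f_theta, n_cycles, drop_first)
  period <- 1000 / f_theta
  st <- spike_times[spike_times >= win[1] & spike_times < win[2]]
  cyc <- floor((st - win[1]) / period)
  counts <- tabulate(cyc + 1L, nbins = n_cycles)
  tibble::tibble(mean = mean(counts),
                 sem = stats::sd(counts) / sqrt(n_cycles))
}
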