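# Current-trace analysis: zero-phase band-pass filtering, analytic Morlet
# scalograms per theta cycle, peak-gamma extraction, quality exclusions.

#' Band-pass filter specification
#'
#' @param low,high Band edges (Hz); defaults 50 and 200.
#' @param order Butterworth order (applied forward and reverse, so the
#'   effective attenuation is squared and the net phase shift is zero).
#' @return An object of class `mec_filter_spec`.
#' @export
filter_spec <- function(low = 50, high = 200, order = 4) {
  stopifnot(low > 0, high > low, order >= 1)
  structure(list(low = low, high = high, order = order),
            class = "mec_filter_spec")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-and-reverse application of a Butterworth band-pass, preserving
#' passband sinusoids with zero net phase shift.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz); must exceed twice the upper band edge.
#' @param spec An [filter_spec()].
#' @return The filtered trace (same length as `x`).
#' @export
zero_phase_bandpass <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "mec_filter_spec"))
  if (fs <= 2 * spec$high) {
    stop("sampling rate must exceed twice the upper band edge (",
         2 * spec$high, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(spec$order, c(spec$low, spec$high) / (fs / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Scalogram frequency grid
#'
#' Geometric grid at a fixed number of scales (voices) per octave,
#' covering the analysis band with margin.
#'
#' @param f_min,f_max Grid range (Hz).
#' @param scales_per_octave Voices per octave (default 32).
#' @return Increasing numeric vector of center frequencies (Hz).
#' @export
cwt_freq_grid <- function(f_min = 40, f_max = 250, scales_per_octave = 32) {
  stopifnot(f_min > 0, f_max > f_min, scales_per_octave >= 1)
  n <- ceiling(log2(f_max / f_min) * scales_per_octave)
  f_min * 2^(seq(0, n) / scales_per_octave)
}

#' Analytic Morlet continuous wavelet transform
#'
#' FFT-based CWT with the analytic Morlet wavelet
#' `psi(t) = pi^(-1/4) exp(i omega0 t) exp(-t^2 / 2)` (dimensionless
#' center parameter `omega0`, default 6). Scales are mapped to center
#' frequencies by `f = omega0 / (2 pi a)`. Coefficients are normalized so
#' that a unit-amplitude sinusoid at a scale's center frequency yields
#' `|W| = 1` there (hence power `|W|^2` carries the squared units of the
#' input, e.g. pA^2).
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param freqs Center frequencies (Hz), e.g. from [cwt_freq_grid()].
#' @param omega0 Morlet center parameter (dimensionless).
#' @return Complex matrix, `length(freqs)` rows by `length(x)` columns.
#' @export
morlet_cwt <- function(x, fs, freqs = cwt_freq_grid(), omega0 = 6) {
  n <- length(x)
  stopifnot(n > 1, all(freqs > 0), all(freqs < fs / 2))
  # zero-pad to soften circular wrap-around of the FFT convolution
  pad <- 2^ceiling(log2(2 * n))
  xf <- fft(c(x, rep(0, pad - n)))
  w <- 2 * pi * c(seq(0, floor(pad / 2)), seq(-ceiling(pad / 2) + 1, -1)) *
    fs / pad                              # angular frequency (rad/s)
  out <- matrix(0i, length(freqs), n)
  for (k in seq_along(freqs)) {
    a <- omega0 / (2 * pi * freqs[k])     # scale (s)
    # analytic wavelet: support on positive frequencies only; normalized
    # so a unit sinusoid at the center frequency gives |W| = 1
    h <- ifelse(w > 0, 2 * exp(-(a * w - omega0)^2 / 2), 0)
    wt <- fft(xf * h, inverse = TRUE) / pad
    out[k, ] <- wt[seq_len(n)]
  }
  out
}

#' Exclusion criteria for gamma-peak summaries
#'
#' Thresholds used to drop low-quality recordings before frequency
#' comparisons, in the two experimental modes: `thy1` (network-wide
#' drive) and `pv` (interneuron-restricted drive).
#'
#' @param mode `"thy1"` or `"pv"`.
#' @param min_power Minimum cycle-averaged peak gamma power (pA^2;
#'   20 for thy1, 10 for pv).
#' @param max_bandwidth Maximum full width at half maximum of the peak
#'   (Hz; 100 for thy1, 110 for pv).
#' @param min_snr Minimum ratio of peak power to the scalogram average.
#' @param artifact_amplitude Per-cycle absolute current threshold (pA)
#'   above which a theta cycle is discarded as artifactual.
#' @return An object of class `mec_exclusion_criteria`.
#' @export
exclusion_criteria <- function(mode = c("thy1", "pv"),
                               min_power = NULL, max_bandwidth = NULL,
                               min_snr = 5, artifact_amplitude = 3000) {
  mode <- match.arg(mode)
  if (is.null(min_power)) min_power <- if (mode == "thy1") 20 else 10
  if (is.null(max_bandwidth)) max_bandwidth <- if (mode == "thy1") 100 else 110
  stopifnot(min_power > 0, max_bandwidth > 0, min_snr > 0,
            artifact_amplitude > 0)
  structure(list(mode = mode, min_power = min_power,
                 max_bandwidth = max_bandwidth, min_snr = min_snr,
                 artifact_amplitude = artifact_amplitude),
            class = "mec_exclusion_criteria")
}

#' Per-theta-cycle Morlet scalograms and their average
#'
#' Computes the analytic Morlet scalogram of the (typically band-passed)
#' current trace, segments it into theta cycles, discards the first cycle
#' (network activity during the first drive period differs from the steady
#' rhythm) and any cycle containing an artifact (absolute current above
#' `criteria$artifact_amplitude`), and averages the power over the
#' retained cycles.
#'
#' @param trace Current trace (pA), starting at drive phase 0 (cycle
#'   trough); must span at least `n_cycles + 1` theta periods.
#' @param fs Sampling rate (Hz).
#' @param f_theta Theta frequency (Hz).
#' @param freqs Scalogram frequency grid (Hz).
#' @param omega0 Morlet center parameter.
#' @param criteria An [exclusion_criteria()] (used for artifact
#'   rejection here; power/bandwidth/SNR rules apply to summaries via
#'   [apply_exclusions()]).
#' @param n_cycles Number of analyzed cycles after discarding the first;
#'   `NULL` uses all complete cycles present.
#' @param drop_first Discard the first theta cycle (default `TRUE`).
#' @param raw_trace Optional unfiltered trace used for artifact detection
#'   (artifacts are large in the raw recording but attenuated by the
#'   band-pass); defaults to `trace`.
#' @return An object of class `mec_scalogram`: list with `freqs`,
#'   `times_ms` (within-cycle time), `power` (averaged matrix,
#'   frequencies by within-cycle time), `cycle_power` (3-d array:
#'   frequency, time, cycle) for the retained cycles, `cycles_used`,
#'   `n_cycles_used`, `f_theta`.
#' @export
cycle_scalograms <- function(trace, fs, f_theta = 8,
                             freqs = cwt_freq_grid(), omega0 = 6,
                             criteria = exclusion_criteria("thy1"),
                             n_cycles = NULL, drop_first = TRUE,
                             raw_trace = trace) {
  stopifnot(length(raw_trace) == length(trace))
  samples_per_cycle <- fs / f_theta
  spc <- as.integer(floor(samples_per_cycle))
  if (abs(samples_per_cycle - spc) > 1e-6) {
    stop("fs must be an integer multiple of f_theta", call. = FALSE)
  }
  total_cycles <- floor(length(trace) / spc)
  first <- if (drop_first) 2L else 1L
  if (is.null(n_cycles)) n_cycles <- total_cycles - first + 1L
  if (total_cycles < first + n_cycles - 1L) {
    stop("trace too short: need at least ", first + n_cycles - 1L,
         " complete theta cycles, found ", total_cycles, call. = FALSE)
  }
  cycles <- seq(first, first + n_cycles - 1L)

  w <- morlet_cwt(trace, fs, freqs, omega0)
  pw <- Mod(w)^2

  has_artifact <- vapply(cycles, function(k) {
    idx <- ((k - 1L) * spc + 1L):(k * spc)
    any(abs(raw_trace[idx]) > criteria$artifact_amplitude)
  }, logical(1))
  kept <- cycles[!has_artifact]
  if (length(kept) == 0) {
    stop("all theta cycles excluded by the artifact criterion",
         call. = FALSE)
  }

  cyc_arr <- array(NA_real_, c(length(freqs), spc, length(kept)))
  for (j in seq_along(kept)) {
    idx <- ((kept[j] - 1L) * spc + 1L):(kept[j] * spc)
    cyc_arr[, , j] <- pw[, idx]
  }
  avg <- apply(cyc_arr, c(1, 2), mean)

  structure(list(freqs = freqs,
                 times_ms = (seq_len(spc) - 1) / fs * 1000,
                 power = avg, cycle_power = cyc_arr,
                 cycles_used = kept, n_cycles_used = length(kept),
                 f_theta = f_theta, fs = fs),
            class = "mec_scalogram")
}

#' @export
print.mec_scalogram <- function(x, ...) {
  cat("<mec_scalogram> ", length(x$freqs), " frequencies (",
      round(min(x$freqs)), "-", round(max(x$freqs)), " Hz) x ",
      ncol(x$power), " samples/cycle, averaged over ", x$n_cycles_used,
      " theta cycles\n", sep = "")
  invisible(x)
}

#' Long-format scalogram power
#'
#' @param x An `mec_scalogram`.
#' @param ... Unused.
#' @return A tibble (`frequency_Hz`, `time_ms`, `power`).
#' @export
tidy.mec_scalogram <- function(x, ...) {
  tibble::tibble(
    frequency_Hz = rep(x$freqs, times = ncol(x$power)),
    time_ms = rep(x$times_ms, each = nrow(x$power)),
    power = as.numeric(x$power))
}

#' Peak-gamma summary of a cycle-averaged scalogram
#'
#' Locates the global maximum of the cycle-averaged power within the
#' analysis band and summarizes it: peak frequency and power, full width
#' at half maximum in frequency through the peak's time bin, and
#' signal-to-noise ratio defined as peak power divided by the mean power
#' over the whole scalogram.
#'
#' @param scal An `mec_scalogram`.
#' @param band Frequency band searched for the peak (Hz); defaults to the
#'   50-200 Hz filter band.
#' @return A one-row tibble: `peak_frequency_Hz`, `peak_power`,
#'   `bandwidth_Hz`, `snr`, `n_cycles_used`.
#' @export
peak_gamma <- function(scal, band = c(50, 200)) {
  stopifnot(inherits(scal, "mec_scalogram"))
  sel <- which(scal$freqs >= band[1] & scal$freqs <= band[2])
  if (length(sel) == 0) stop("no scalogram frequencies in band",
                             call. = FALSE)
  sub <- scal$power[sel, , drop = FALSE]
  if (max(sub) <= 0 || !any(is.finite(sub))) {
    stop("flat scalogram: gamma peak undefined", call. = FALSE)
  }
  ij <- arrayInd(which.max(sub), dim(sub))
  fi <- sel[ij[1]]; ti <- ij[2]
  pk <- scal$power[fi, ti]
  snr <- pk / mean(scal$power)

  # FWHM along frequency through the peak's time bin, interpolated on the
  # log-spaced grid; unresolved edges extend to the grid limit
  prof <- scal$power[, ti]
  half <- pk / 2
  lo <- fi
  while (lo > 1 && prof[lo - 1] >= half) lo <- lo - 1
  f_lo <- if (lo == 1) scal$freqs[1] else {
    approx(prof[c(lo - 1, lo)], scal$freqs[c(lo - 1, lo)], xout = half)$y
  }
  hi <- fi
  nf <- length(prof)
  while (hi < nf && prof[hi + 1] >= half) hi <- hi + 1
  f_hi <- if (hi == nf) scal$freqs[nf] else {
    approx(prof[c(hi, hi + 1)], scal$freqs[c(hi, hi + 1)], xout = half)$y
  }

  tibble::tibble(peak_frequency_Hz = scal$freqs[fi],
                 peak_power = pk,
                 bandwidth_Hz = f_hi - f_lo,
                 snr = snr,
                 n_cycles_used = scal$n_cycles_used)
}

#' Apply recording-quality exclusions to a gamma-peak summary
#'
#' Drops a summary when the cycle-averaged peak power is below the mode's
#' minimum, the peak bandwidth exceeds the mode's maximum, or the SNR is
#' below 5.
#'
#' @param summary A one-or-more-row tibble from [peak_gamma()].
#' @param criteria An [exclusion_criteria()]; or supply `mode` to use the
#'   mode's defaults.
#' @param mode Convenience shortcut, `"thy1"` or `"pv"`.
#' @return `summary` with columns `kept` (logical) and `reason`
#'   (`NA`, `"power"`, `"bandwidth"` or `"snr"`; the first failing rule).
#' @export
apply_exclusions <- function(summary, criteria = NULL,
                             mode = c("thy1", "pv")) {
  if (is.null(criteria)) criteria <- exclusion_criteria(match.arg(mode))
  stopifnot(inherits(criteria, "mec_exclusion_criteria"))
  reason <- rep(NA_character_, nrow(summary))
  reason[summary$snr < criteria$min_snr] <- "snr"
  reason[summary$bandwidth_Hz > criteria$max_bandwidth] <- "bandwidth"
  reason[summary$peak_power < criteria$min_power] <- "power"
  summary$kept <- is.na(reason)
  summary$reason <- reason
  summary
}

#' Full clamp-current analysis pipeline
#'
#' Convenience wrapper chaining the steps applied to every recorded or
#' simulated current trace: zero-phase 50-200 Hz band-pass, per-cycle
#' Morlet scalograms with first-cycle and artifact exclusion, and peak
#' extraction.
#'
#' @param trace Current trace (pA) starting at drive phase 0.
#' @param fs Sampling rate (Hz).
#' @param f_theta Theta frequency (Hz).
#' @param mode Exclusion mode, `"thy1"` or `"pv"`.
#' @param n_cycles Analyzed cycles (`NULL` = all after the first).
#' @param filter An [filter_spec()].
#' @param freqs Scalogram frequency grid.
#' @param omega0 Morlet center parameter.
#' @return List with `scalogram` (`mec_scalogram`) and `summary` (tibble
#'   from [peak_gamma()] + [apply_exclusions()]).
#' @export
analyze_trace <- function(trace, fs, f_theta = 8, mode = "thy1",
                          n_cycles = NULL, filter = filter_spec(),
                          freqs = cwt_freq_grid(), omega0 = 6) {
  criteria <- exclusion_criteria(mode)
  filtered <- zero_phase_bandpass(trace, fs, filter)
  scal <- cycle_scalograms(filtered, fs, f_theta, freqs, omega0, criteria,
                           n_cycles = n_cycles, raw_trace = trace)
  summ <- apply_exclusions(peak_gamma(scal, band = c(filter$low,
                                                     filter$high)),
                           criteria)
  list(scalogram = scal, summary = summ)
}
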