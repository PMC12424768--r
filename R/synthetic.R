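# Ground-truth synthetic signals: theta-nested gamma current traces and
# phase-structured spike trains with known parameters, for testing every
# analysis stage without running the network.

#' Synthetic theta-nested gamma trace specification
#'
#' @param f_theta Theta (envelope) frequency (Hz).
#' @param f_gamma Gamma (carrier) frequency (Hz).
#' @param amplitude_pA Peak gamma amplitude (pA).
#' @param noise_sd_pA White-noise standard deviation (pA).
#' @param artifact_cycles Integer vector of 1-based theta-cycle indices to
#'   contaminate with a large square artifact.
#' @param artifact_amplitude_pA Artifact amplitude (pA).
#' @param n_cycles Number of theta cycles.
#' @param fs Sampling rate (Hz); must exceed `2 * f_gamma`.
#' @param noise_kind `"white"` or `"pink"` (1/f, via cumulative-filtered
#'   white noise).
#' @return An object of class `mec_synth_spec`.
#' @export
synth_trace_spec <- function(f_theta = 8, f_gamma = 125,
                             amplitude_pA = 100, noise_sd_pA = 10,
                             artifact_cycles = integer(0),
                             artifact_amplitude_pA = 5000,
                             n_cycles = 41, fs = 2000,
                             noise_kind = c("white", "pink")) {
  stopifnot(fs > 2 * f_gamma, amplitude_pA >= 0, noise_sd_pA >= 0,
            n_cycles >= 1)
  structure(list(f_theta = f_theta, f_gamma = f_gamma,
                 amplitude_pA = amplitude_pA, noise_sd_pA = noise_sd_pA,
                 artifact_cycles = as.integer(artifact_cycles),
                 artifact_amplitude_pA = artifact_amplitude_pA,
                 n_cycles = as.integer(n_cycles), fs = fs,
                 noise_kind = match.arg(noise_kind)),
            class = "mec_synth_spec")
}

#' Generate a synthetic theta-nested gamma current trace
#'
#' `I(t) = A env(t) sin(2 pi f_gamma t) + noise + artifacts`, with a
#' raised-cosine theta envelope (`env = (1 - cos(2 pi f_theta t)) / 2`,
#' zero at each cycle trough) emulating the statistical structure of
#' clamp-current recordings: theta-gated gamma bursts plus noise and
#' optional rare large artifacts. The generating parameters are returned
#' alongside so analysis tests assert recovery, never regeneration.
#'
#' @param spec An [synth_trace_spec()].
#' @param seed RNG seed; the trace is deterministic given the seed.
#' @return A list: `trace` (tibble `time_ms`, `current_pA`),
#'   `ground_truth` (the spec plus the seed).
#' @export
make_theta_nested_gamma <- function(spec = synth_trace_spec(), seed = 1L) {
  stopifnot(inherits(spec, "mec_synth_spec"))
  n <- as.integer(round(spec$n_cycles * spec$fs / spec$f_theta))
  t_s <- (seq_len(n) - 1) / spec$fs
  env <- (1 - cos(2 * pi * spec$f_theta * t_s)) / 2
  x <- spec$amplitude_pA * env * sin(2 * pi * spec$f_gamma * t_s)
  if (spec$noise_sd_pA > 0) {
    with_seed(seed, {
      eps <- rnorm(n, 0, spec$noise_sd_pA)
      if (spec$noise_kind == "pink") {
        # shape white noise to ~1/f by cumulative smoothing, then rescale
        eps <- stats::filter(eps, 0.95, method = "recursive")
        eps <- as.numeric(eps) / sd(eps) * spec$noise_sd_pA
      }
      x <- x + eps
    })
  }
  spc <- spec$fs / spec$f_theta
  for (k in spec$artifact_cycles) {
    idx <- round((k - 1) * spc) + seq_len(round(spc / 10))
    idx <- idx[idx <= n]
    x[idx] <- x[idx] + spec$artifact_amplitude_pA
  }
  list(trace = tibble::tibble(time_ms = t_s * 1000, current_pA = x),
       ground_truth = c(unclass(spec), list(seed = seed)))
}

#' Generate phase-locked spike trains
#'
#' Spike trains with a known per-cycle count distribution and a known
#' within-cycle phase structure, so phase histograms, interspike-rate
#' histograms and per-cycle counts have closed-form expectations.
#'
#' @param f_theta Theta frequency (Hz).
#' @param n_cycles Number of cycles.
#' @param count One of: a single integer (that many spikes every cycle),
#'   or a function `(n)` returning `n` integer counts (e.g. Poisson).
#' @param phase Either a single phase in `[0, 2 pi)` (burst onset; spikes
#'   within a burst are spaced by `intra_isi_ms`), or a function `(n)`
#'   drawing `n` phases.
#' @param intra_isi_ms Interval between spikes of a within-cycle burst
#'   (ms).
#' @param seed RNG seed.
#' @return Sorted spike times (ms) spanning `n_cycles / f_theta` seconds.
#' @export
make_phase_locked_spikes <- function(f_theta = 8, n_cycles = 40,
                                     count = 1, phase = pi,
                                     intra_isi_ms = 10, seed = 1L) {
  period <- 1000 / f_theta
  counts <- if (is.function(count)) {
    with_seed(seed, as.integer(count(n_cycles)))
  } else rep(as.integer(count), n_cycles)
  stopifnot(all(counts >= 0))
  spikes <- numeric(0)
  draw_phase <- is.function(phase)
  phases_needed <- sum(counts)
  drawn <- if (draw_phase && phases_needed > 0) {
    with_seed(seed + 1L, phase(phases_needed))
  } else NULL
  ptr <- 0L
  for (k in seq_len(n_cycles)) {
    m <- counts[k]
    if (m == 0) next
    t0 <- (k - 1) * period
    if (draw_phase) {
      ph <- drawn[ptr + seq_len(m)]
      ptr <- ptr + m
      spikes <- c(spikes, t0 + (ph %% (2 * pi)) / (2 * pi) * period)
    } else {
      onset <- t0 + phase / (2 * pi) * period
      spikes <- c(spikes, onset + (seq_len(m) - 1) * intra_isi_ms)
    }
  }
  sort(spikes)
}
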