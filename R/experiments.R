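# In-silico experiments: E->I conductance sweep across connectivity seeds,
# simulated AMPA blockade, GABA-A reversal-potential variants, regime
# classification, physiological-conductance estimation.

#' Build, run and summarize one network condition
#'
#' Assembles a network with the given per-edge E-to-I conductance and I-to-I
#' reversal, runs it, and analyzes the clamp current of the first
#' E-population readout (band-pass, cycle scalograms, peak extraction).
#'
#' @param g_ei Per-edge (unitary) E-to-I peak conductance (nS), the
#'   value on the regime-sweep axis.
#' @param seed Connectivity / heterogeneity / noise seed.
#' @param egaba_ii I-to-I GABA-A reversal (mV, or `"distributed"`).
#' @param n_theta_cycles Simulated theta cycles (first discarded by the
#'   analysis); default 11 = 1 discarded + 10 analyzed (desk scale).
#' @param mode Exclusion mode for the analysis (`"thy1"` or `"pv"`).
#' @param readout Which E readout to analyze (default 1). If every theta
#'   cycle of that readout's current is rejected by the artifact rule,
#'   the remaining readouts are tried in order, mirroring the
#'   experimental practice of recording another cell when one fails
#'   quality control.
#' @param conn Base [connectivity_config()]; its `g_ei` (per-edge
#'   semantics) is overridden by the `g_ei` argument.
#' @param keep_sim Return the `mec_sim` object too (larger).
#' @param ... Passed to [assemble_network()] (e.g. `conn`, `drive`).
#' @return A list: `summary` (one-row tibble with the gamma peak,
#'   exclusions applied, plus `g_ei`, `seed`), `scalogram`,
#'   `network`, and optionally `sim`.
#' @export
run_condition <- function(g_ei, seed = 1L, egaba_ii = -75,
                          n_theta_cycles = 11, mode = "thy1",
                          readout = 1, conn = connectivity_config(),
                          keep_sim = FALSE, ...) {
  conn$g_ei <- g_ei
  conn$g_ei_semantics <- "per_edge"
  net <- assemble_network(conn = conn, egaba_ii = egaba_ii, seed = seed,
                          ...)
  cfg <- sim_config(n_theta_cycles = n_theta_cycles)
  sim <- run_simulation(net, cfg)
  fs <- 1000 / cfg$record_dt
  ana <- NULL
  for (rd in c(readout, setdiff(seq_len(net$n_readouts), readout))) {
    tr <- clamp_current(sim, "E_readout", rd)
    ana <- tryCatch(
      analyze_trace(tr$current_pA, fs, f_theta = net$drive$f_theta,
                    mode = mode, n_cycles = n_theta_cycles - 1),
      error = function(e) NULL)
    if (!is.null(ana)) break
  }
  if (is.null(ana)) {
    stop("all readouts rejected by the artifact criterion", call. = FALSE)
  }
  summ <- dplyr::mutate(ana$summary, g_ei = g_ei, seed = seed,
                        .before = 1)
  out <- list(summary = summ, scalogram = ana$scalogram, network = net)
  if (keep_sim) out$sim <- sim
  out
}

#' Sweep the E-to-I conductance across connectivity seeds
#'
#' Runs the full simulation and analysis pipeline for every combination
#' of swept conductance value and seed, reproducing the regime analysis:
#' fast interneuron-paced (ING) gamma at weak coupling gives way to a
#' slower excitation-paced (PING) rhythm as the E-to-I conductance grows.
#'
#' @param g_values Swept per-edge E-to-I conductances (nS). The default
#'   grid brackets the regime transition near 12 nS.
#' @param n_seeds Number of connectivity seeds per value (default 10).
#' @param seeds Explicit seed vector (overrides `n_seeds`).
#' @param egaba_ii I-to-I reversal (mV).
#' @param n_theta_cycles Simulated cycles per run.
#' @param threshold_Hz Regime classification threshold (Hz).
#' @param ... Passed to [run_condition()].
#' @return An object of class `mec_sweep`: a tibble with one row per
#'   (g_ei, seed) carrying the peak summary, exclusion columns and
#'   `regime` label.
#' @export
run_ei_sweep <- function(g_values = c(3.6, 6, 8, 10, 12, 14, 18),
                         n_seeds = 10, seeds = NULL, egaba_ii = -75,
                         n_theta_cycles = 11, threshold_Hz = 90, ...) {
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  grid <- tidyr::expand_grid(g_ei = g_values, seed = as.integer(seeds))
  rows <- purrr::pmap(grid, function(g_ei, seed) {
    res <- tryCatch(
      run_condition(g_ei, seed = seed, egaba_ii = egaba_ii,
                    n_theta_cycles = n_theta_cycles, ...)$summary,
      error = function(e) {
        tibble::tibble(g_ei = g_ei, seed = seed,
                       peak_frequency_Hz = NA_real_,
                       peak_power = NA_real_, bandwidth_Hz = NA_real_,
                       snr = NA_real_, n_cycles_used = NA_integer_,
                       kept = FALSE, reason = paste0("error: ",
                                                     conditionMessage(e)))
      })
    res
  })
  out <- dplyr::bind_rows(rows)
  out$regime <- classify_regime(out$peak_frequency_Hz, threshold_Hz)
  out$regime[!out$kept] <- NA_character_
  structure(out, threshold_Hz = threshold_Hz,
            class = c("mec_sweep", class(out)))
}

#' Box statistics of a sweep
#'
#' @param x An `mec_sweep`.
#' @param ... Unused.
#' @return A tibble with per-conductance median/quartiles/whiskers of the
#'   peak frequency and power.
#' @export
glance.mec_sweep <- function(x, ...) {
  x |>
    dplyr::filter(!is.na(.data$peak_frequency_Hz)) |>
    dplyr::group_by(.data$g_ei) |>
    dplyr::summarise(
      n = dplyr::n(),
      freq_median = median(.data$peak_frequency_Hz),
      freq_q1 = quantile(.data$peak_frequency_Hz, 0.25),
      freq_q3 = quantile(.data$peak_frequency_Hz, 0.75),
      freq_min = min(.data$peak_frequency_Hz),
      freq_max = max(.data$peak_frequency_Hz),
      power_median = median(.data$peak_power),
      power_q1 = quantile(.data$peak_power, 0.25),
      power_q3 = quantile(.data$peak_power, 0.75),
      n_slow = sum(.data$regime == "PING-dominant", na.rm = TRUE),
      .groups = "drop")
}

#' Classify the oscillation regime from the peak frequency
#'
#' Fast interneuron-paced rhythms (roughly 100-140 Hz) are labelled
#' `"ING-dominant"`, slower excitation-paced rhythms (60-80 Hz)
#' `"PING-dominant"`. The default threshold of 90 Hz lies midway between
#' the two bands; a peak exactly at threshold is labelled ING-dominant.
#'
#' @param peak_frequency_Hz Peak frequency (Hz), vectorized; `NA` yields
#'   `NA`.
#' @param threshold_Hz Classification threshold (Hz).
#' @return Character vector of regime labels.
#' @export
classify_regime <- function(peak_frequency_Hz, threshold_Hz = 90) {
  ifelse(is.na(peak_frequency_Hz), NA_character_,
         ifelse(peak_frequency_Hz < threshold_Hz, "PING-dominant",
                "ING-dominant"))
}

#' Simulated AMPA blockade (paired control / blocked runs)
#'
#' Runs the network twice with identical connectivity, weights,
#' heterogeneity and drive-noise realization, once as configured and once
#' with the E-to-I conductance set to zero — the in-silico analog of
#' bath-applying the AMPA antagonist DNQX. The paired design means any
#' difference between the runs is attributable to the E-to-I synapses.
#'
#' @param g_ei Control per-edge E-to-I conductance (nS).
#' @param seed Shared seed for both runs.
#' @param egaba_ii I-to-I reversal (mV or `"distributed"`).
#' @param n_theta_cycles Simulated cycles.
#' @param mode Exclusion mode.
#' @param ... Passed to [run_condition()].
#' @return A tibble with two rows (`condition` = `"control"`,
#'   `"ampa_block"`) carrying the peak summaries, plus attribute
#'   `scalograms` (named list).
#' @export
simulate_ampa_block <- function(g_ei = 3.6, seed = 1L, egaba_ii = -75,
                                n_theta_cycles = 11, mode = "thy1", ...) {
  ctrl <- run_condition(g_ei, seed = seed, egaba_ii = egaba_ii,
                        n_theta_cycles = n_theta_cycles, mode = mode, ...)
  blk <- run_condition(0, seed = seed, egaba_ii = egaba_ii,
                       n_theta_cycles = n_theta_cycles, mode = mode, ...)
  out <- dplyr::bind_rows(
    dplyr::mutate(ctrl$summary, condition = "control", .before = 1),
    dplyr::mutate(blk$summary, condition = "ampa_block", .before = 1))
  attr(out, "scalograms") <- list(control = ctrl$scalogram,
                                  ampa_block = blk$scalogram)
  out
}

#' GABA-A reversal-potential variants under strong E-to-I coupling
#'
#' For each I-to-I reversal variant (hyperpolarizing -75 mV, distributed
#' uniform \[-75, -55\] mV, shunting -55 mV), runs the paired
#' control/AMPA-blocked experiment with identical seeds and summarizes
#' the gamma peak in each condition.
#'
#' @param g_ei Control per-edge E-to-I conductance (nS; default 120,
#'   the strongly coupled regime).
#' @param variants Named list of reversals; defaults to the three
#'   canonical variants.
#' @param seed Shared seed.
#' @param n_theta_cycles Simulated cycles.
#' @param ... Passed to [simulate_ampa_block()].
#' @return A tibble with one row per (variant, condition), exclusion
#'   columns included.
#' @export
run_egaba_variants <- function(g_ei = 120,
                               variants = list(hyperpolarizing = -75,
                                               distributed = "distributed",
                                               shunting = -55),
                               seed = 1L, n_theta_cycles = 11, ...) {
  purrr::imap(variants, function(egaba, nm) {
    simulate_ampa_block(g_ei = g_ei, seed = seed, egaba_ii = egaba,
                        n_theta_cycles = n_theta_cycles, ...) |>
      dplyr::mutate(variant = nm, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Estimate the physiological E-to-I conductance range
#'
#' Reproduces the estimation procedure applied to voltage-clamped
#' fast-spiking interneurons: band-pass the excitatory current recorded
#' at the holding potential, measure the gamma-frequency peak-to-peak
#' amplitude in each theta cycle, and divide by the driving force
#' `|V_hold - E_AMPA|` to convert current to conductance.
#'
#' @param trace Excitatory current trace (pA) recorded at `v_hold`.
#' @param fs Sampling rate (Hz).
#' @param f_theta Theta frequency (Hz).
#' @param v_hold Holding potential (mV; default -70).
#' @param e_ampa AMPA reversal (mV; default 0).
#' @param bandpass Apply the 50-200 Hz zero-phase band-pass first
#'   (default `TRUE`; set `FALSE` if `trace` is already filtered).
#' @param drop_first Discard the first theta cycle.
#' @return A tibble: `g_min_nS`, `g_max_nS` (range across cycles),
#'   `g_median_nS`, `n_cycles`.
#' @export
estimate_physiological_gei <- function(trace, fs, f_theta = 8,
                                       v_hold = -70, e_ampa = 0,
                                       bandpass = TRUE,
                                       drop_first = TRUE) {
  stopifnot(v_hold != e_ampa)
  x <- if (bandpass) zero_phase_bandpass(trace, fs) else trace
  spc <- as.integer(floor(fs / f_theta))
  total_cycles <- floor(length(x) / spc)
  first <- if (drop_first) 2L else 1L
  if (total_cycles < first) stop("trace shorter than one theta cycle",
                                 call. = FALSE)
  p2p <- vapply(seq(first, total_cycles), function(k) {
    seg <- x[((k - 1L) * spc + 1L):(k * spc)]
    max(seg) - min(seg)
  }, numeric(1))
  g <- p2p / abs(v_hold - e_ampa)
  tibble::tibble(g_min_nS = min(g), g_max_nS = max(g),
                 g_median_nS = median(g), n_cycles = length(g))
}
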