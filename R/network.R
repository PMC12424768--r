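# Network construction: populations, random connectivity, synapse kinetics,
# theta drive, readout designation.

#' Synapse specification
#'
#' @param kind `"exp"` (single-exponential decay) or `"biexp"`
#'   (difference of exponentials normalized so the peak conductance equals
#'   the weight).
#' @param tau_rise Rise time constant (ms, bi-exponential only; must be
#'   `< tau_decay`).
#' @param tau_decay Decay time constant (ms).
#' @param e_rev Reversal potential (mV).
#' @param g_max Peak conductance (nS) of a unit event.
#' @param delay Synaptic (axonal plus transmission) delay (ms).
#' @return An object of class `mec_synapse_spec`.
#' @export
synapse_spec <- function(kind = c("biexp", "exp"), tau_rise = NA,
                         tau_decay, e_rev, g_max = 1, delay = 0) {
  kind <- match.arg(kind)
  stopifnot(tau_decay > 0, g_max >= 0, delay >= 0)
  if (kind == "biexp") {
    stopifnot(!is.na(tau_rise), tau_rise > 0, tau_rise < tau_decay)
  }
  structure(list(kind = kind, tau_rise = tau_rise, tau_decay = tau_decay,
                 e_rev = e_rev, g_max = g_max, delay = delay),
            class = "mec_synapse_spec")
}

#' Default synapse kinetics
#'
#' The calibrated kinetic set: I-to-E GABA-A with 0.4 ms rise / 6 ms
#' decay and reversal -65 mV; E-to-I AMPA single-exponential with 1 ms
#' decay and reversal 0 mV; I-to-I GABA-A with the same bi-exponential
#' shape as I-to-E and a hyperpolarizing -75 mV reversal (overridden by
#' the `egaba_ii` argument of [assemble_network()]).
#'
#' @return Named list of [synapse_spec()] objects (`ie`, `ei`, `ii`).
#' @export
default_synapses <- function() {
  list(
    # I -> E: GABA-A onto stellate cells, rise 0.4 ms / decay 6 ms,
    # E_GABA = -65 mV; per-edge peak conductance drawn lognormal.
    ie = synapse_spec("biexp", tau_rise = 0.4, tau_decay = 6, e_rev = -65),
    # E -> I: AMPA onto interneurons, single-exponential decay 1 ms,
    # E_AMPA = 0 mV; 2 ms axonal + synaptic delay.
    ei = synapse_spec("exp", tau_decay = 1, e_rev = 0, delay = 2),
    # I -> I: GABA-A between interneurons; fast perisomatic kinetics
    # (rise 0.4 ms / decay 3 ms), hyperpolarizing by default (-75 mV);
    # the shunting and distributed variants override `e_rev`.
    ii = synapse_spec("biexp", tau_rise = 0.4, tau_decay = 3, e_rev = -75)
  )
}

#' Connectivity configuration
#'
#' Bernoulli random connectivity between and within populations. There are
#' never E-to-E connections (stellate cells are not connected with each
#' other) and never autapses. I-to-E peak conductances are drawn from a
#' lognormal distribution; E-to-I and I-to-I conductances are uniform
#' per class.
#'
#' @param p_ei Probability of an E-to-I connection (default 0.4).
#' @param p_ie Probability of an I-to-E connection (default 0.3).
#' @param p_ii Probability of an I-to-I connection (default 0.3).
#' @param ie_weight_meanlog,ie_weight_sdlog Lognormal parameters of the
#'   I-to-E peak conductance (nS scale).
#' @param g_ei E-to-I peak conductance (nS). With the default
#'   `"per_edge"` semantics this is the unitary (per-connection) AMPA
#'   conductance, the quantity on the sweep axis of [run_ei_sweep()];
#'   with `"total"` semantics it is the expected summed conductance per
#'   interneuron and the per-edge value is `g_ei / (p_ei * n_E)`.
#' @param g_ei_semantics `"per_edge"` or `"total"` (see `g_ei`).
#' @param g_ii Per-edge I-to-I peak conductance (nS).
#' @return An object of class `mec_connectivity_config`.
#' @export
connectivity_config <- function(p_ei = 0.4, p_ie = 0.3, p_ii = 0.3,
                                ie_weight_meanlog = log(1),
                                ie_weight_sdlog = 0.5,
                                g_ei = 3.6,
                                g_ei_semantics = c("per_edge", "total"),
                                g_ii = 0.25) {
  g_ei_semantics <- match.arg(g_ei_semantics)
  probs <- c(p_ei = p_ei, p_ie = p_ie, p_ii = p_ii)
  if (any(probs < 0 | probs > 1)) {
    stop("connection probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(ie_weight_sdlog >= 0, g_ei >= 0, g_ii >= 0)
  structure(list(p_ei = p_ei, p_ie = p_ie, p_ii = p_ii,
                 ie_weight_meanlog = ie_weight_meanlog,
                 ie_weight_sdlog = ie_weight_sdlog,
                 g_ei = g_ei, g_ei_semantics = g_ei_semantics,
                 g_ii = g_ii),
            class = "mec_connectivity_config")
}

#' Theta drive specification
#'
#' The simulated optogenetic drive: a non-negative sinusoidal conductance
#' `g(t) = (g_peak / 2) (1 - cos(2 pi f t))` with reversal potential 0 mV
#' (a raised cosine: zero at the cycle trough, `g_peak` at the crest). A
#' small Ornstein-Uhlenbeck conductance noise is added to each
#' interneuron's drive to prevent the theta drive alone from synchronizing
#' the population.
#'
#' @param f_theta Drive frequency (Hz; default 8).
#' @param g_peak_i Peak conductance onto each interneuron (nS; default 7).
#' @param g_peak_e Peak conductance onto each stellate cell (nS; default
#'   3).
#' @param e_rev Drive reversal potential (mV; default 0).
#' @param noise_sd Stationary standard deviation of the OU noise (nS;
#'   default 5% of `g_peak_i`).
#' @param noise_tau OU correlation time (ms).
#' @return An object of class `mec_drive_spec`.
#' @export
theta_drive_spec <- function(f_theta = 8, g_peak_i = 7, g_peak_e = 3,
                             e_rev = 0, noise_sd = 0.05 * g_peak_i,
                             noise_tau = 1) {
  stopifnot(f_theta > 0, g_peak_i >= 0, g_peak_e >= 0, noise_sd >= 0,
            noise_tau > 0)
  structure(list(f_theta = f_theta, g_peak_i = g_peak_i,
                 g_peak_e = g_peak_e, e_rev = e_rev,
                 noise_sd = noise_sd, noise_tau = noise_tau),
            class = "mec_drive_spec")
}

#' Theta drive conductance waveform
#'
#' @param t Time (ms), scalar or vector.
#' @param g_peak Peak conductance (nS).
#' @param f_theta Drive frequency (Hz).
#' @return Conductance `g(t)` (nS): zero at each cycle trough (t = 0,
#'   1/f, ...), `g_peak` at each crest, mean `g_peak / 2`.
#' @export
theta_conductance <- function(t, g_peak = 7, f_theta = 8) {
  g_peak / 2 * (1 - cos(2 * pi * f_theta * t / 1000))
}

#' Ornstein-Uhlenbeck conductance noise
#'
#' Exact-discretization OU process with mean 0, stationary standard
#' deviation `sd` and correlation time `tau`, sampled on the simulation
#' grid. Initial values are drawn from the stationary distribution. The
#' engine clips total drive at zero, so the summed drive conductance never
#' goes negative.
#'
#' @param sd Stationary standard deviation (nS). `sd = 0` returns zeros.
#' @param tau Correlation time (ms).
#' @param dt Time step (ms).
#' @param duration Total duration (ms); output has `duration/dt + 1` rows.
#' @param seed RNG seed.
#' @param n Number of independent traces (columns).
#' @return Numeric matrix, `duration/dt + 1` rows by `n` columns.
#' @export
make_drive_noise <- function(sd, tau, dt, duration, seed, n = 1) {
  stopifnot(sd >= 0, tau > 0, dt > 0, n >= 1)
  n_steps <- as.integer(round(duration / dt))
  out <- matrix(0, n_steps + 1L, n)
  if (sd == 0) return(out)
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  with_seed(seed, {
    x <- rnorm(n, 0, sd)
    out[1, ] <- x
    # vectorized over columns, sequential over time
    eps <- matrix(rnorm(n_steps * n, 0, innov_sd), n_steps, n)
    for (s in seq_len(n_steps)) {
      x <- a * x + eps[s, ]
      out[s + 1L, ] <- x
    }
  })
  out
}

#' Sample random connectivity
#'
#' Each ordered (pre, post) pair in the allowed population pairs is
#' connected independently with its class probability. E-to-E connections
#' and autapses are never created. Readout cells receive afferents by the
#' same rules but have no efferents.
#'
#' @param config An `mec_connectivity_config`.
#' @param n_e,n_i Population sizes.
#' @param n_e_readout,n_i_readout Number of readout (observer) cells per
#'   population.
#' @param seed RNG seed; adjacency is deterministic given the seed.
#' @return A tibble of edges: `pre`, `post` (1-based cell ids; I cells
#'   first, then E cells, then I readouts, then E readouts), `class`
#'   (`"EI"`, `"IE"`, `"II"`), `weight_nS`.
#' @export
sample_connectivity <- function(config, n_e, n_i, n_e_readout = 0,
                                n_i_readout = 0, seed = 1L) {
  stopifnot(inherits(config, "mec_connectivity_config"))
  id_i <- seq_len(n_i)
  id_e <- n_i + seq_len(n_e)
  id_ir <- n_i + n_e + seq_len(n_i_readout)
  id_er <- n_i + n_e + n_i_readout + seq_len(n_e_readout)
  w_ei <- if (config$g_ei_semantics == "per_edge") config$g_ei
          else if (config$p_ei > 0) config$g_ei / (config$p_ei * n_e)
          else 0

  bern_pairs <- function(pre_ids, post_ids, p, forbid_autapse = FALSE) {
    if (p == 0 || length(pre_ids) == 0 || length(post_ids) == 0) {
      return(data.frame(pre = integer(0), post = integer(0)))
    }
    grid <- expand.grid(pre = pre_ids, post = post_ids,
                        KEEP.OUT.ATTRS = FALSE)
    if (forbid_autapse) grid <- grid[grid$pre != grid$post, ]
    keep <- runif(nrow(grid)) < p
    grid[keep, , drop = FALSE]
  }

  with_seed(seed, {
    ei <- bern_pairs(id_e, c(id_i, id_ir), config$p_ei)
    ie <- bern_pairs(id_i, c(id_e, id_er), config$p_ie)
    ii <- bern_pairs(id_i, c(id_i, id_ir), config$p_ii,
                     forbid_autapse = TRUE)
    w_ie <- rlnorm(nrow(ie), config$ie_weight_meanlog,
                   config$ie_weight_sdlog)
  })

  edges <- dplyr::bind_rows(
    tibble::tibble(pre = ei$pre, post = ei$post, class = "EI",
                   weight_nS = rep(w_ei, nrow(ei))),
    tibble::tibble(pre = ie$pre, post = ie$post, class = "IE",
                   weight_nS = w_ie),
    tibble::tibble(pre = ii$pre, post = ii$post, class = "II",
                   weight_nS = rep(config$g_ii, nrow(ii)))
  )
  edges
}

#' Sample lognormal I-to-E weights
#'
#' @param n Number of weights.
#' @param meanlog,sdlog Lognormal parameters (log-nS scale).
#' @param seed RNG seed.
#' @return Strictly positive numeric vector of peak conductances (nS) with
#'   median `exp(meanlog)`.
#' @export
sample_ie_weights <- function(n, meanlog = log(1), sdlog = 0.5, seed = 1L) {
  stopifnot(sdlog >= 0)
  with_seed(seed, rlnorm(n, meanlog, sdlog))
}

#' Assemble the mEC network
#'
#' Builds the full model: `n_i` fast-spiking interneurons and `n_e`
#' stellate cells with jittered conductances, Bernoulli connectivity
#' (E-to-I, I-to-E, I-to-I; never E-to-E), synaptic kinetics, the 8 Hz
#' conductance drive, and `n_readouts` voltage-clamped observer cells per
#' population. Readouts are wired with the same afferent rules but emit no
#' spikes and no efferent events, so the spiking network is unchanged by
#' their presence; their clamp current at 0 mV reports the inhibition a
#' cell of that population receives.
#'
#' @param n_i,n_e Population sizes (defaults 100 and 400).
#' @param conn An `mec_connectivity_config`.
#' @param drive An `mec_drive_spec`.
#' @param synapses List with elements `ie`, `ei`, `ii`
#'   (`mec_synapse_spec`); defaults to the calibrated kinetics.
#' @param egaba_ii I-to-I GABA-A reversal: a number (mV; e.g. -75
#'   hyperpolarizing, -55 shunting) or `"distributed"` (one value per
#'   postsynaptic interneuron, uniform on \[-75, -55\] mV).
#' @param fs_base,stellate_base Base cell parameters.
#' @param jitter_cv Conductance jitter coefficient of variation.
#' @param jitter_cv_i,jitter_cv_e Per-population overrides of
#'   `jitter_cv` for the interneuron and stellate populations.
#' @param n_readouts Readout cells per population (default 5).
#' @param v_hold Readout holding potential (mV; default 0).
#' @param seed Seed controlling connectivity, weights, heterogeneity and
#'   the drive noise realization.
#' @return An object of class `mec_network`.
#' @export
assemble_network <- function(n_i = 100, n_e = 400,
                             conn = connectivity_config(),
                             drive = theta_drive_spec(),
                             synapses = default_synapses(),
                             egaba_ii = -75,
                             fs_base = fs_params(),
                             stellate_base = stellate_params(),
                             jitter_cv = 0.1,
                             jitter_cv_i = jitter_cv,
                             jitter_cv_e = jitter_cv,
                             n_readouts = 5,
                             v_hold = 0,
                             seed = 1L) {
  stopifnot(n_i > 0, n_e > 0, n_readouts >= 0)
  seed <- as.integer(seed)

  # cell table: I, E, I readouts, E readouts
  i_pop <- jitter_population(population_spec(n_i, fs_base, jitter_cv_i,
                                             seed = seed))
  e_pop <- jitter_population(population_spec(n_e, stellate_base,
                                             jitter_cv_e,
                                             seed = seed + 1000L))
  ir <- jitter_population(population_spec(max(n_readouts, 1), fs_base, 0,
                                          seed = seed))[
    seq_len(n_readouts), , drop = FALSE]
  er <- jitter_population(population_spec(max(n_readouts, 1), stellate_base,
                                          0, seed = seed))[
    seq_len(n_readouts), , drop = FALSE]
  cells <- dplyr::bind_rows(
    dplyr::mutate(i_pop, population = "I", is_readout = FALSE),
    dplyr::mutate(e_pop, population = "E", is_readout = FALSE),
    dplyr::mutate(ir, population = "I_readout", is_readout = TRUE),
    dplyr::mutate(er, population = "E_readout", is_readout = TRUE)
  )
  cells$cell <- seq_len(nrow(cells))

  edges <- sample_connectivity(conn, n_e = n_e, n_i = n_i,
                               n_e_readout = n_readouts,
                               n_i_readout = n_readouts, seed = seed)

  # per-cell GABA reversal: E cells get the I->E value; I cells get the
  # I->I variant
  is_i_cell <- cells$population %in% c("I", "I_readout")
  gaba_e_rev <- ifelse(is_i_cell, NA_real_, synapses$ie$e_rev)
  if (identical(egaba_ii, "distributed")) {
    with_seed(seed + 2000L,
              gaba_e_rev[is_i_cell] <- runif(sum(is_i_cell), -75, -55))
  } else {
    stopifnot(is.numeric(egaba_ii), length(egaba_ii) == 1)
    gaba_e_rev[is_i_cell] <- egaba_ii
  }
  cells$gaba_e_rev <- gaba_e_rev

  structure(list(cells = cells, edges = edges, conn = conn, drive = drive,
                 synapses = synapses, egaba_ii = egaba_ii,
                 n_i = n_i, n_e = n_e, n_readouts = n_readouts,
                 v_hold = v_hold, seed = seed),
            fs_base = fs_base, stellate_base = stellate_base,
            jitter_cv = jitter_cv,
            class = "mec_network")
}

#' @export
print.mec_network <- function(x, ...) {
  cat("<mec_network> ", x$n_i, " I + ", x$n_e, " E cells, ",
      x$n_readouts, "+", x$n_readouts, " readouts clamped at ",
      x$v_hold, " mV\n", sep = "")
  cat("  edges:", nrow(x$edges), "(",
      paste(names(table(x$edges$class)), table(x$edges$class),
            collapse = ", "), ")\n")
  cat("  E->I total conductance:", signif(x$conn$g_ei_total, 4),
      "nS; I-I E_GABA:",
      if (identical(x$egaba_ii, "distributed")) "distributed [-75, -55]"
      else paste(x$egaba_ii, "mV"), "\n")
  invisible(x)
}

#' Rescale all synapses of a class
#'
#' Sets the maximal conductance of every edge of a connection class, the
#' in-silico analog of a pharmacological manipulation (`g = 0` on `"EI"`
#' simulates AMPA-receptor blockade with DNQX). For `"EI"` and `"II"` the
#' value is applied with the chosen semantics; for `"IE"` the lognormal
#' weights are rescaled (preserving their relative spread) so the per-edge
#' mean or expected per-target sum equals `g`.
#'
#' @param network An `mec_network`.
#' @param class `"EI"`, `"IE"` or `"II"`.
#' @param g Conductance (nS).
#' @param semantics `"per_edge"` (unitary conductance; the sweep-axis
#'   convention) or `"total"` (expected summed peak conductance per
#'   postsynaptic cell).
#' @return The modified `mec_network`.
#' @export
set_class_conductance <- function(network, class, g,
                                  semantics = c("per_edge", "total")) {
  stopifnot(inherits(network, "mec_network"), g >= 0)
  semantics <- match.arg(semantics)
  if (!class %in% c("EI", "IE", "II")) {
    stop("unknown connection class: ", class, call. = FALSE)
  }
  sel <- network$edges$class == class
  n_pre <- if (class == "EI") network$n_e else network$n_i
  p <- switch(class, EI = network$conn$p_ei, IE = network$conn$p_ie,
              II = network$conn$p_ii)
  if (semantics == "per_edge") {
    per_edge <- g
    if (class == "IE") {
      w <- network$edges$weight_nS[sel]
      network$edges$weight_nS[sel] <- w * per_edge / mean(w)
    } else {
      network$edges$weight_nS[sel] <- per_edge
    }
  } else {
    expected_edges <- p * n_pre
    if (expected_edges == 0 && g > 0) {
      stop("class ", class, " has zero expected connectivity", call. = FALSE)
    }
    if (class == "IE") {
      w <- network$edges$weight_nS[sel]
      target_mean <- g / expected_edges
      network$edges$weight_nS[sel] <- w * target_mean / mean(w)
    } else {
      network$edges$weight_nS[sel] <- g / expected_edges
    }
  }
  if (class == "EI") {
    network$conn$g_ei <- g
    network$conn$g_ei_semantics <- semantics
  }
  network
}

#' Summarize realized class conductances
#'
#' Reports, for each connection class, the per-edge mean peak conductance
#' and the realized mean per-target summed conductance, resolving the
#' per-edge versus per-target-total parameterizations.
#'
#' @param network An `mec_network`.
#' @return A tibble with one row per class.
#' @export
class_conductance_summary <- function(network) {
  stopifnot(inherits(network, "mec_network"))
  spiking <- network$cells$cell[!network$cells$is_readout]
  network$edges |>
    dplyr::filter(.data$post %in% spiking) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_edges = dplyr::n(),
      mean_weight_nS = mean(.data$weight_nS),
      mean_total_per_target_nS = sum(.data$weight_nS) /
        length(unique(.data$post)),
      .groups = "drop")
}
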