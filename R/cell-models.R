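#' Fast-spiking interneuron parameters
#'
#' Single-compartment conductance-based model of a parvalbumin-positive
#' fast-spiking (FS) interneuron in the Wang-Buzsaki formalism: transient
#' sodium with instantaneous activation, delayed-rectifier potassium, and
#' leak, with a temperature-like factor `phi` accelerating the gating
#' kinetics so the cell sustains firing well above 100 Hz without
#' adaptation. All conductances are absolute (nS) for a nominal membrane
#' area folded into `c_m`.
#'
#' @param c_m Membrane capacitance (pF).
#' @param g_na,g_k,g_l Maximal sodium, delayed-rectifier and leak
#'   conductances (nS).
#' @param e_na,e_k,e_l Reversal potentials (mV); must satisfy
#'   `e_na > e_l > e_k`.
#' @param phi Dimensionless gating rate factor.
#' @return An object of class `mec_cell_params`.
#' @seealso [stellate_params()], [make_fs_cell()]
#' @export
fs_params <- function(c_m = 100, g_na = 3500, g_k = 900, g_l = 10,
                      e_na = 55, e_k = -90, e_l = -65, phi = 5) {
  new_cell_params(
    type = "fs",
    values = list(c_m = c_m, g_na = g_na, g_k = g_k, g_l = g_l,
                  e_na = e_na, e_k = e_k, e_l = e_l, phi = phi,
                  g_nap = 0, g_hf = 0, g_hs = 0, e_h = -20)
  )
}

#' Stellate cell parameters
#'
#' Single-compartment Hodgkin-Huxley-type model of a medial entorhinal
#' cortex layer II stellate cell: transient sodium, delayed-rectifier
#' potassium and leak, augmented with a persistent sodium conductance
#' (`g_nap`) and a two-component hyperpolarization-activated H conductance
#' (`g_hf` fast, `g_hs` slow). The interplay of the amplifying persistent
#' sodium and the slow restorative H current gives the cell its hallmark
#' subthreshold resonance in the theta band (see [impedance_profile()]).
#' Setting `g_nap = g_hf = g_hs = 0` recovers a classic non-resonant HH
#' cell.
#'
#' @inheritParams fs_params
#' @param g_nap Persistent sodium maximal conductance (nS).
#' @param g_hf,g_hs Fast and slow H-current maximal conductances (nS).
#' @param e_h H-current reversal potential (mV).
#' @return An object of class `mec_cell_params`.
#' @export
stellate_params <- function(c_m = 200, g_na = 7000, g_k = 1500, g_l = 25,
                            g_nap = 15, g_hf = 32, g_hs = 20,
                            e_na = 55, e_k = -90, e_l = -65, e_h = -20,
                            phi = 1) {
  new_cell_params(
    type = "stellate",
    values = list(c_m = c_m, g_na = g_na, g_k = g_k, g_l = g_l,
                  e_na = e_na, e_k = e_k, e_l = e_l, phi = phi,
                  g_nap = g_nap, g_hf = g_hf, g_hs = g_hs, e_h = e_h)
  )
}

new_cell_params <- function(type, values) {
  g <- values[c("g_na", "g_k", "g_l", "g_nap", "g_hf", "g_hs")]
  if (any(unlist(g) < 0)) {
    stop("all maximal conductances must be >= 0", call. = FALSE)
  }
  if (values$c_m <= 0) stop("c_m must be positive", call. = FALSE)
  if (!(values$e_na > values$e_l && values$e_l > values$e_k)) {
    stop("reversal potentials must satisfy e_na > e_l > e_k", call. = FALSE)
  }
  structure(c(list(type = type), values), class = "mec_cell_params")
}

#' @export
print.mec_cell_params <- function(x, ...) {
  cat("<mec_cell_params> type:", x$type, "\n")
  vals <- unlist(x[setdiff(names(x), "type")])
  print(vals)
  invisible(x)
}

# engine column order: C, gNa, gK, gL, ENa, EK, EL, phi, gNaP, gHf, gHs, EH
param_vector <- function(p) {
  as.numeric(c(p$c_m, p$g_na, p$g_k, p$g_l, p$e_na, p$e_k, p$e_l, p$phi,
               p$g_nap, p$g_hf, p$g_hs, p$e_h))
}

cell_type_code <- function(type) {
  switch(type, fs = 0L, stellate = 1L,
         stop("unknown cell type: ", type, call. = FALSE))
}

#' Construct a fast-spiking interneuron model
#'
#' Packages validated parameters together with the membrane
#' right-hand-side so the cell can be simulated ([simulate_cell()]),
#' probed for impedance ([impedance_profile()]) or embedded in a network
#' ([assemble_network()]). A spike is registered on an upward crossing of
#' 0 mV with a 2 ms refractory period for event registration.
#'
#' @param params An `mec_cell_params` object from [fs_params()].
#' @return An object of class `mec_cell`.
#' @export
make_fs_cell <- function(params = fs_params()) {
  stopifnot(inherits(params, "mec_cell_params"))
  if (params$type != "fs") stop("params are not fast-spiking parameters",
                                call. = FALSE)
  structure(list(type = "fs", params = params), class = "mec_cell")
}

#' Construct a stellate cell model
#'
#' @param params An `mec_cell_params` object from [stellate_params()].
#' @return An object of class `mec_cell`.
#' @rdname make_fs_cell
#' @export
make_stellate_cell <- function(params = stellate_params()) {
  stopifnot(inherits(params, "mec_cell_params"))
  if (params$type != "stellate") stop("params are not stellate parameters",
                                      call. = FALSE)
  structure(list(type = "stellate", params = params), class = "mec_cell")
}

#' @export
print.mec_cell <- function(x, ...) {
  cat("<mec_cell>", x$type, "cell\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Membrane equations in R (reference form; the network engine implements the
# same equations in compiled code)
# ---------------------------------------------------------------------------

vtrap <- function(x, k) ifelse(abs(x / k) < 1e-6, k * (1 + x / (2 * k)),
                               x / (1 - exp(-x / k)))

fs_gate_rates <- function(v, phi) {
  am <- 0.1 * vtrap(v + 35, 10); bm <- 4 * exp(-(v + 60) / 18)
  ah <- 0.07 * exp(-(v + 58) / 20); bh <- 1 / (1 + exp(-(v + 28) / 10))
  an <- 0.01 * vtrap(v + 34, 10); bn <- 0.125 * exp(-(v + 44) / 80)
  list(m_inf = am / (am + bm),
       h_inf = ah / (ah + bh), h_tau = 1 / (phi * (ah + bh)),
       n_inf = an / (an + bn), n_tau = 1 / (phi * (an + bn)))
}

stellate_gate_rates <- function(v) {
  am <- 0.1 * vtrap(v + 23, 10); bm <- 4 * exp(-(v + 48) / 18)
  ah <- 0.07 * exp(-(v + 37) / 20); bh <- 1 / (1 + exp(-(v + 7) / 10))
  an <- 0.01 * vtrap(v + 27, 10); bn <- 0.125 * exp(-(v + 37) / 80)
  list(m_inf = am / (am + bm), m_tau = 1 / (am + bm),
       h_inf = ah / (ah + bh), h_tau = 1 / (ah + bh),
       n_inf = an / (an + bn), n_tau = 1 / (an + bn),
       p_inf = 1 / (1 + exp(-(v + 38) / 6.5)),
       hf_inf = 1 / (1 + exp((v + 79.2) / 9.78)),
       hf_tau = 0.51 / (exp((v - 1.7) / 10) + exp(-(v + 340) / 52)) + 1,
       hs_inf = 1 / (1 + exp((v + 71.3) / 7.9)),
       hs_tau = 5.6 / (exp((v - 1.7) / 14) + exp(-(v + 260) / 43)) + 1)
}

#' Membrane state derivatives of a cell model
#'
#' Returns the time derivatives of the membrane potential and gating
#' variables at a given state, for use with general-purpose ODE solvers or
#' for inspection of the model equations. State layout: fast-spiking cells
#' use `c(v, h, n)`; stellate cells use `c(v, m, h, n, hf, hs)`.
#'
#' @param cell An `mec_cell`.
#' @param state Named or positional numeric state vector (see Details).
#' @param i_ext External injected current (pA, inward positive).
#' @return Numeric vector of derivatives (per ms), same layout as `state`.
#' @export
cell_derivatives <- function(cell, state, i_ext = 0) {
  p <- cell$params
  v <- state[[1]]
  if (cell$type == "fs") {
    r <- fs_gate_rates(v, p$phi)
    h <- state[[2]]; n <- state[[3]]
    i_ion <- p$g_na * r$m_inf^3 * h * (v - p$e_na) +
      p$g_k * n^4 * (v - p$e_k) + p$g_l * (v - p$e_l)
    c(v = (-i_ion + i_ext) / p$c_m,
      h = (r$h_inf - h) / r$h_tau,
      n = (r$n_inf - n) / r$n_tau)
  } else {
    r <- stellate_gate_rates(v)
    m <- state[[2]]; h <- state[[3]]; n <- state[[4]]
    hf <- state[[5]]; hs <- state[[6]]
    i_ion <- p$g_na * m^3 * h * (v - p$e_na) +
      p$g_k * n^4 * (v - p$e_k) +
      p$g_nap * r$p_inf * (v - p$e_na) +
      (p$g_hf * hf + p$g_hs * hs) * (v - p$e_h) +
      p$g_l * (v - p$e_l)
    c(v = (-i_ion + i_ext) / p$c_m,
      m = (r$m_inf - m) / r$m_tau,
      h = (r$h_inf - h) / r$h_tau,
      n = (r$n_inf - n) / r$n_tau,
      hf = (r$hf_inf - hf) / r$hf_tau,
      hs = (r$hs_inf - hs) / r$hs_tau)
  }
}

#' Steady-state gating values at a voltage
#'
#' @inheritParams cell_derivatives
#' @param v Membrane potential (mV).
#' @return Named numeric vector of steady-state gating values, prefixed by
#'   `v` itself, in the state layout of [cell_derivatives()].
#' @export
cell_steady_state <- function(cell, v) {
  if (cell$type == "fs") {
    r <- fs_gate_rates(v, cell$params$phi)
    c(v = v, h = r$h_inf, n = r$n_inf)
  } else {
    r <- stellate_gate_rates(v)
    c(v = v, m = r$m_inf, h = r$h_inf, n = r$n_inf,
      hf = r$hf_inf, hs = r$hs_inf)
  }
}

# ---------------------------------------------------------------------------
# Single-cell simulation
# ---------------------------------------------------------------------------

#' Simulate a single cell
#'
#' Integrates one cell with the package's fixed-step scheme (exponential
#' Euler for gating, forward Euler for the voltage, default
#' `dt = 0.025` ms) under an injected current and/or a conductance drive
#' with a fixed reversal potential.
#'
#' @param cell An `mec_cell`.
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param i_inj Injected current: a single value (pA), a vector of length
#'   `duration/dt + 1`, or a function of time (ms) returning pA.
#' @param g_drive Drive conductance (nS): same forms as `i_inj`.
#' @param e_drive Drive reversal potential (mV).
#' @param v0 Initial membrane potential (mV); defaults to the leak
#'   reversal.
#' @return A list with `trace` (tibble: `time_ms`, `v_mV`) and `spikes`
#'   (numeric vector of spike times, ms).
#' @export
simulate_cell <- function(cell, duration, dt = 0.025, i_inj = NULL,
                          g_drive = NULL, e_drive = 0, v0 = NULL) {
  stopifnot(inherits(cell, "mec_cell"))
  n_steps <- as.integer(round(duration / dt))
  tgrid <- seq(0, by = dt, length.out = n_steps + 1)
  expand <- function(x) {
    if (is.null(x)) return(numeric(0))
    if (is.function(x)) return(as.numeric(x(tgrid)))
    if (length(x) == 1) return(rep(as.numeric(x), n_steps + 1))
    stopifnot(length(x) >= n_steps + 1)
    as.numeric(x)
  }
  if (is.null(v0)) v0 <- cell$params$e_l
  res <- simulate_cell_cpp(cell_type_code(cell$type),
                           param_vector(cell$params), v0, dt, n_steps,
                           expand(i_inj), expand(g_drive), e_drive,
                           spike_threshold = 0, refractory_ms = 2)
  list(trace = tibble::tibble(time_ms = tgrid, v_mV = res$v),
       spikes = as.numeric(res$spikes))
}

# ---------------------------------------------------------------------------
# Population heterogeneity
# ---------------------------------------------------------------------------

#' Specify a heterogeneous cell population
#'
#' @param n Number of cells.
#' @param base Base `mec_cell_params` for the population.
#' @param jitter_cv Coefficient of variation of the Gaussian jitter applied
#'   independently to each maximal conductance (dimensionless); 0 gives
#'   `n` identical copies.
#' @param seed RNG seed; jittering is deterministic given the seed.
#' @return An object of class `mec_population_spec`.
#' @export
population_spec <- function(n, base, jitter_cv = 0.1, seed = 1L) {
  stopifnot(n > 0, jitter_cv >= 0, inherits(base, "mec_cell_params"))
  structure(list(n = as.integer(n), base = base,
                 jitter_cv = jitter_cv, seed = as.integer(seed)),
            class = "mec_population_spec")
}

#' Draw jittered conductance parameters for a population
#'
#' Each maximal conductance of each cell is drawn independently from
#' `Normal(base, cv * base)` and truncated at zero, introducing the
#' cell-to-cell heterogeneity seen in real populations.
#'
#' @param spec An `mec_population_spec`.
#' @return A tibble with one row per cell and one column per parameter
#'   (engine layout plus `cell` index).
#' @export
jitter_population <- function(spec) {
  stopifnot(inherits(spec, "mec_population_spec"))
  base <- spec$base
  jitter_fields <- c("g_na", "g_k", "g_l", "g_nap", "g_hf", "g_hs")
  fixed_fields <- c("c_m", "e_na", "e_k", "e_l", "phi", "e_h")
  out <- tibble::tibble(cell = seq_len(spec$n))
  with_seed(spec$seed, {
    for (f in jitter_fields) {
      mu <- base[[f]]
      if (spec$jitter_cv == 0 || mu == 0) {
        out[[f]] <- rep(mu, spec$n)
      } else {
        out[[f]] <- pmax(0, rnorm(spec$n, mean = mu, sd = spec$jitter_cv * mu))
      }
    }
  })
  for (f in fixed_fields) out[[f]] <- rep(base[[f]], spec$n)
  out$type <- base$type
  out
}

# evaluate code under a fixed seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

params_from_row <- function(row) {
  if (row$type == "fs") {
    fs_params(c_m = row$c_m, g_na = row$g_na, g_k = row$g_k, g_l = row$g_l,
              e_na = row$e_na, e_k = row$e_k, e_l = row$e_l, phi = row$phi)
  } else {
    stellate_params(c_m = row$c_m, g_na = row$g_na, g_k = row$g_k,
                    g_l = row$g_l, g_nap = row$g_nap, g_hf = row$g_hf,
                    g_hs = row$g_hs, e_na = row$e_na, e_k = row$e_k,
                    e_l = row$e_l, e_h = row$e_h, phi = row$phi)
  }
}

# ---------------------------------------------------------------------------
# Impedance
# ---------------------------------------------------------------------------

#' Subthreshold impedance profile of a cell
#'
#' Injects a subthreshold ZAP (linear chirp) current and returns the
#' impedance magnitude `|FFT(V)| / |FFT(I)|` across the chirp band. For a
#' passive cell the profile is low-pass (maximal at the lowest frequency);
#' the stellate model's H/persistent-sodium combination produces a
#' resonance peak in the theta band.
#'
#' @param cell An `mec_cell`.
#' @param f_min,f_max Chirp frequency range (Hz).
#' @param duration Chirp duration (ms).
#' @param amplitude_pA Chirp amplitude (pA); must remain subthreshold.
#' @param i_dc Constant holding current added to the chirp (pA), or
#'   `NULL` (default) to compute the bias that holds the cell at
#'   `v_hold` from the steady-state current-voltage relation.
#' @param v_hold Subthreshold holding potential (mV) used when `i_dc` is
#'   `NULL`.
#' @param dt Time step (ms).
#' @return A tibble (`frequency_Hz`, `impedance_MOhm`) with attribute
#'   `resonance_frequency_Hz`; class `mec_impedance`.
#' @export
impedance_profile <- function(cell, f_min = 0.5, f_max = 20,
                              duration = 30000, amplitude_pA = 20,
                              i_dc = NULL, v_hold = -62, dt = 0.05) {
  stopifnot(inherits(cell, "mec_cell"), f_min > 0, f_max > f_min)
  v0 <- NULL
  if (is.null(i_dc)) {
    # bias current balancing the steady-state ionic current at v_hold
    ss <- cell_steady_state(cell, v_hold)
    i_dc <- -cell_derivatives(cell, ss)[[1]] * cell$params$c_m
    v0 <- v_hold
  }
  n_steps <- as.integer(round(duration / dt))
  tgrid <- seq(0, by = dt, length.out = n_steps + 1)
  t_s <- tgrid / 1000
  dur_s <- duration / 1000
  # linear chirp f(t) = f_min + (f_max - f_min) t / T
  phase <- 2 * pi * (f_min * t_s + (f_max - f_min) * t_s^2 / (2 * dur_s))
  zap <- amplitude_pA * sin(phase)
  sim <- simulate_cell(cell, duration, dt = dt, i_inj = zap + i_dc,
                       v0 = v0)
  if (length(sim$spikes) > 0) {
    stop("ZAP drive caused spiking; impedance profile invalid ",
         "(reduce amplitude_pA or i_dc)", call. = FALSE)
  }
  # drop the first 10% to let slow gates settle
  skip <- floor(n_steps * 0.1)
  v <- sim$trace$v_mV[-seq_len(skip)]
  i <- zap[-seq_len(skip)]
  v <- v - mean(v)
  i <- i - mean(i)
  nfft <- length(v)
  fs <- 1000 / dt
  freqs <- seq(0, fs / 2, by = fs / nfft)
  vf <- Mod(fft(v))[seq_along(freqs)]
  iff <- Mod(fft(i))[seq_along(freqs)]
  keep <- freqs >= f_min & freqs <= f_max
  # mV / pA = GOhm; report MOhm
  z <- 1000 * vf[keep] / iff[keep]
  out <- tibble::tibble(frequency_Hz = freqs[keep], impedance_MOhm = z)
  # light smoothing against FFT bin noise
  out$impedance_MOhm <- stats::filter(out$impedance_MOhm, rep(1 / 5, 5),
                                      sides = 2)
  out <- out[!is.na(out$impedance_MOhm), ]
  out$impedance_MOhm <- as.numeric(out$impedance_MOhm)
  res_f <- out$frequency_Hz[which.max(out$impedance_MOhm)]
  structure(out, resonance_frequency_Hz = res_f,
            class = c("mec_impedance", class(out)))
}

#' @export
print.mec_impedance <- function(x, ...) {
  cat("<mec_impedance> resonance at",
      round(attr(x, "resonance_frequency_Hz"), 2), "Hz\n")
  NextMethod()
}

#' Resonance frequency of an impedance profile
#'
#' @param x An `mec_impedance` object.
#' @return Resonance frequency (Hz).
#' @export
resonance_frequency <- function(x) {
  attr(x, "resonance_frequency_Hz")
}
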