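# Independent fixed-step RK4 integrator over the package's membrane
# equations, used as the oracle for the engine's exponential-Euler scheme.
rk4_cell <- function(cell, duration, dt, i_inj = function(t) 0,
                     v0 = cell$params$e_l) {
  n <- round(duration / dt)
  state <- cell_steady_state(cell, v0)
  out <- matrix(NA_real_, n + 1, length(state))
  out[1, ] <- state
  inj <- if (is.function(i_inj)) i_inj else function(t) i_inj
  for (s in seq_len(n)) {
    t <- (s - 1) * dt
    k1 <- cell_derivatives(cell, state, inj(t))
    k2 <- cell_derivatives(cell, state + dt / 2 * k1, inj(t + dt / 2))
    k3 <- cell_derivatives(cell, state + dt / 2 * k2, inj(t + dt / 2))
    k4 <- cell_derivatives(cell, state + dt * k3, inj(t + dt))
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[s + 1, ] <- state
  }
  colnames(out) <- names(state)
  out
}

# spike count of a voltage trace by upward 0-crossings with refractory
count_upcrossings <- function(v, dt, thr = 0, refr = 2) {
  idx <- which(v[-length(v)] < thr & v[-1] >= thr)
  if (length(idx) == 0) return(0L)
  t <- idx * dt
  keep <- c(TRUE, diff(t) >= refr)
  # enforce sequential refractory
  n <- 0L; last <- -Inf
  for (tt in t) if (tt - last >= refr) { n <- n + 1L; last <- tt }
  n
}

# Brute-force discrete CWT: direct summation against sampled analytic
# Morlet atoms, matching the package's normalization (unit tone -> |W| = 1).
cwt_direct <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  idx <- seq_len(n)
  out <- matrix(0i, length(freqs), n)
  for (k in seq_along(freqs)) {
    a <- omega0 / (2 * pi * freqs[k])          # scale (s)
    coef <- 2 / (sqrt(2 * pi) * a * fs)
    for (m in idx) {
      tt <- (m - idx) / fs
      h <- coef * exp(1i * omega0 * tt / a - (tt / a)^2 / 2)
      out[k, m] <- sum(x * h)
    }
  }
  out
}

# Best-Fisher rejection sampler for the von Mises distribution
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c <- kappa * (r - f)
    if (c * (2 - c) - u[2] > 0 || log(c / u[2]) + 1 - c >= 0) {
      i <- i + 1
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}
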