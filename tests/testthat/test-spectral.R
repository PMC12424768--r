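fs <- 2000

test_that("zero-phase band-pass preserves the passband and kills theta", {
  t <- seq(0, 2, by = 1 / fs)
  x100 <- sin(2 * pi * 100 * t)
  y <- zero_phase_bandpass(x100, fs)
  core <- seq(round(0.25 * fs), round(1.75 * fs))  # avoid edge transients
  amp <- max(abs(y[core]))
  expect_lt(abs(amp - 1), 0.05)
  # zero net phase shift: cross-correlation peaks at lag 0
  cc <- ccf(y[core], x100[core], lag.max = 5, plot = FALSE)
  expect_equal(which.max(cc$acf), 6L)  # lag 0 (1 sample ~ 18 deg at 100 Hz)

  x8 <- sin(2 * pi * 8 * t)
  y8 <- zero_phase_bandpass(x8, fs)
  expect_lt(max(abs(y8[core])), 0.05)
})

test_that("filtering commutes with time reversal (zero-phase symmetry)", {
  set.seed(42)
  x <- rnorm(2000)
  y <- zero_phase_bandpass(x, fs)
  yr <- zero_phase_bandpass(rev(x), fs)
  # compare away from the ends, where filtfilt initialization differs
  core <- 501:1500
  expect_equal(rev(yr)[core], y[core], tolerance = 1e-6)
})

test_that("band-pass rejects too-low sampling rates", {
  expect_error(zero_phase_bandpass(rnorm(100), fs = 300), "sampling rate")
})

test_that("FFT-based Morlet CWT matches direct convolution within 1%", {
  n <- 400
  t <- seq_len(n) / fs
  x <- sin(2 * pi * 90 * t) + 0.5 * sin(2 * pi * 140 * t)
  freqs <- c(60, 90, 120, 140, 180)
  w_fft <- morlet_cwt(x, fs, freqs)
  w_dir <- cwt_direct(x, fs, freqs)
  # compare away from the edges, where the direct sum is also complete
  core <- 100:300
  rel <- Mod(w_fft[, core])^2 - Mod(w_dir[, core])^2
  denom <- max(Mod(w_dir[, core])^2)
  expect_lt(max(abs(rel)) / denom, 0.01)
})

test_that("a unit tone yields unit scalogram power at its frequency", {
  t <- seq_len(4000) / fs
  a <- 3.7
  x <- a * sin(2 * pi * 100 * t)
  w <- morlet_cwt(x, fs, freqs = c(100))
  core <- 1000:3000
  expect_equal(median(Mod(w[1, core])^2), a^2, tolerance = 0.02)
})

test_that("scalogram power is quadratic in the trace amplitude", {
  set.seed(7)
  x <- rnorm(1000)
  f <- cwt_freq_grid(50, 200, 8)
  w1 <- Mod(morlet_cwt(x, fs, f))^2
  w3 <- Mod(morlet_cwt(3 * x, fs, f))^2
  expect_equal(w3, 9 * w1, tolerance = 1e-10)
})

test_that("cycle scalograms: DC trace, artifact rejection, first-cycle drop", {
  spc <- fs / 8
  n_cyc <- 6
  x <- rep(5, n_cyc * spc)
  scal <- cycle_scalograms(x, fs, 8)
  # negligible relative to the DC level squared (residual comes from the
  # trace's edge discontinuity leaking into the last cycle)
  expect_lt(max(scal$power), 0.01 * 5^2)
  expect_equal(scal$n_cycles_used, n_cyc - 1L)          # first discarded
  expect_equal(scal$cycles_used, 2:n_cyc)

  # one artifact cycle is dropped, and exactly that one
  synth <- make_theta_nested_gamma(
    synth_trace_spec(f_gamma = 125, n_cycles = 6, artifact_cycles = 4L,
                     noise_sd_pA = 5), seed = 3)
  tr <- synth$trace$current_pA
  scal2 <- cycle_scalograms(zero_phase_bandpass(tr, fs), fs, 8,
                            raw_trace = tr)
  expect_equal(scal2$n_cycles_used, n_cyc - 2L)
  expect_false(4L %in% scal2$cycles_used)
})

test_that("peak extraction finds tones and scales with amplitude squared", {
  t <- seq_len(8 * fs / 8) / fs   # 8 theta cycles
  env <- (1 - cos(2 * pi * 8 * t)) / 2
  step <- 2^(1 / 32)
  for (a in c(50, 100)) {
    x <- a * env * sin(2 * pi * 100 * t)
    scal <- cycle_scalograms(x, fs, 8)
    pk <- peak_gamma(scal)
    expect_lt(abs(log2(pk$peak_frequency_Hz / 100)), 1.5 / 32)
  }
  p1 <- peak_gamma(cycle_scalograms(50 * env * sin(2 * pi * 100 * t), fs, 8))
  p2 <- peak_gamma(cycle_scalograms(100 * env * sin(2 * pi * 100 * t), fs, 8))
  expect_equal(p2$peak_power / p1$peak_power, 4, tolerance = 0.01)

  # two tones: the stronger one wins
  x2 <- env * (sin(2 * pi * 80 * t) + 1.6 * sin(2 * pi * 140 * t))
  pk2 <- peak_gamma(cycle_scalograms(x2, fs, 8))
  expect_lt(abs(log2(pk2$peak_frequency_Hz / 140)), 1.5 / 32)
})

test_that("white noise alone fails the SNR criterion", {
  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(6 * fs / 8, sd = 30)
    pk <- peak_gamma(cycle_scalograms(zero_phase_bandpass(x, fs), fs, 8,
                                      raw_trace = x))
    expect_lt(pk$snr, 5)
  }
})

test_that("exclusion rules apply mode-specific thresholds", {
  mk <- function(power, bw, snr) {
    tibble::tibble(peak_frequency_Hz = 120, peak_power = power,
                   bandwidth_Hz = bw, snr = snr, n_cycles_used = 40L)
  }
  r1 <- apply_exclusions(mk(19, 50, 10), mode = "thy1")
  expect_false(r1$kept); expect_equal(r1$reason, "power")
  r2 <- apply_exclusions(mk(50, 105, 10), mode = "pv")
  expect_true(r2$kept)
  r3 <- apply_exclusions(mk(50, 105, 10), mode = "thy1")
  expect_false(r3$kept); expect_equal(r3$reason, "bandwidth")
  r4 <- apply_exclusions(mk(50, 50, 4.9), mode = "thy1")
  expect_false(r4$kept); expect_equal(r4$reason, "snr")
})

test_that("gamma frequency is recovered across the 60-150 Hz band", {
  set.seed(21)
  f_true <- runif(100, 60, 150)
  err_steps <- vapply(seq_along(f_true), function(i) {
    synth <- make_theta_nested_gamma(
      synth_trace_spec(f_gamma = f_true[i], amplitude_pA = 100,
                       noise_sd_pA = 10, n_cycles = 6), seed = 100 + i)
    tr <- synth$trace$current_pA
    pk <- peak_gamma(cycle_scalograms(zero_phase_bandpass(tr, fs), fs, 8,
                                      raw_trace = tr))
    abs(log2(pk$peak_frequency_Hz / f_true[i])) * 32
  }, numeric(1))
  expect_lte(median(err_steps), 1)
})
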