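test_that("spike detection finds constructed peaks and ignores subthreshold", {
  fs <- 20000
  t <- seq(0, 0.5, by = 1 / fs) * 1000  # ms
  expect_length(detect_spikes(-65 + 5 * sin(2 * pi * 8 * t / 1000), fs), 0)

  # 5 spikes per cycle, 4 cycles: triangular 1 ms bumps to +30 mV
  v <- rep(-65, length(t))
  spike_times <- as.vector(outer(seq(10, 50, 10), (0:3) * 125, "+"))
  for (st in spike_times) {
    idx <- round(st * fs / 1000) + 1
    v[idx] <- 30
    v[idx + c(-1, 1)] <- 0
  }
  det <- detect_spikes(v, fs)
  expect_length(det, 20)
  expect_equal(det, sort(spike_times), tolerance = 0.1)
})

test_that("spike detection agrees with the simulator's event count", {
  cell <- make_fs_cell()
  sim <- simulate_cell(cell, 1000, g_drive = function(t)
    theta_conductance(t, 7, 8), e_drive = 0)
  det <- detect_spikes(sim$trace$v_mV, fs = 1000 / 0.025)
  expect_length(det, length(sim$spikes))
})

test_that("phase histogram normalizes per cycle and conserves mass", {
  # one spike per cycle at the cycle midpoint
  st <- make_phase_locked_spikes(f_theta = 8, n_cycles = 41, count = 1,
                                 phase = pi)
  h <- phase_histogram(st, n_cycles = 40)
  expect_equal(sum(h$count), 40)
  expect_equal(max(h$per_cycle), 1)
  expect_equal(sum(h$per_cycle > 0), 1)
  mid_bin <- which(h$bin_left_rad <= pi & pi < h$bin_right_rad)
  expect_equal(h$per_cycle[mid_bin], 1)

  h0 <- phase_histogram(numeric(0))
  expect_true(all(h0$per_cycle == 0))
})

test_that("phase histogram is invariant to whole-period shifts", {
  set.seed(5)
  st <- sort(runif(200, 125, 5125))
  h1 <- phase_histogram(st)
  h2 <- phase_histogram(st + 3 * 125)  # 3 theta periods
  # shifted spikes fall outside the window; compare using all cycles
  h1b <- phase_histogram(st, n_cycles = 80, drop_first = FALSE)
  h2b <- phase_histogram(st + 3 * 125, n_cycles = 80, drop_first = FALSE)
  expect_equal(h1b$count, h2b$count)
})

test_that("phase histogram matches a von Mises generating density", {
  set.seed(9)
  ph <- rvonmises(4000, mu = pi, kappa = 2)
  st <- make_phase_locked_spikes(f_theta = 8, n_cycles = 4000,
                                 count = 1, phase = function(n) ph)
  h <- phase_histogram(st, n_cycles = 4000, drop_first = FALSE,
                       n_bins = 30)
  # chi-squared goodness of fit against the binned von Mises density
  dens <- function(x) exp(2 * cos(x - pi)) / (2 * pi * besselI(2, 0))
  p_bin <- vapply(seq_len(30), function(b) {
    integrate(dens, h$bin_left_rad[b], h$bin_right_rad[b])$value
  }, numeric(1))
  gof <- suppressWarnings(chisq.test(h$count, p = p_bin / sum(p_bin)))
  expect_gt(gof$p.value, 0.001)
})

test_that("interspike rate histogram bins 1/ISI into 10 Hz bins", {
  # perfectly periodic 100 Hz train
  st <- seq(0, 1000, by = 10)
  h <- isi_rate_histogram(st, n_cycles = 8)
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_left_Hz, 100)
  expect_equal(h$count, 100)

  # ~154 Hz train (6.5 ms ISIs): all mass in [150, 160)
  st150 <- seq(0, 1000, by = 6.5)
  h150 <- isi_rate_histogram(st150, n_cycles = 8)
  expect_equal(h150$bin_left_Hz, 150)

  # constructed mixture of 10 ms and 25 ms intervals
  isis <- c(rep(10, 30), rep(25, 10))
  st_mix <- cumsum(c(0, sample(isis)))
  h_mix <- isi_rate_histogram(st_mix, n_cycles = 40)
  expect_equal(h_mix$count[h_mix$bin_left_Hz == 100], 30)
  expect_equal(h_mix$count[h_mix$bin_left_Hz == 40], 10)
  expect_equal(sum(h_mix$count), length(isis))

  expect_equal(nrow(isi_rate_histogram(c(5), n_cycles = 40)), 0)
})

test_that("spikes per cycle: exact trains and Poisson fixtures", {
  expect_equal(spikes_per_cycle(numeric(0)),
               tibble::tibble(mean = 0, sem = 0))
  st <- make_phase_locked_spikes(f_theta = 8, n_cycles = 41, count = 2,
                                 phase = pi / 2, intra_isi_ms = 8)
  r <- spikes_per_cycle(st)
  expect_equal(r$mean, 2)
  expect_equal(r$sem, 0)

  set.seed(13)
  lam <- 2.4
  stp <- make_phase_locked_spikes(
    f_theta = 8, n_cycles = 41,
    count = function(n) rpois(n, lam),
    phase = function(n) runif(n, 0.2 * pi, 1.8 * pi), seed = 17)
  rp <- spikes_per_cycle(stp)
  expect_lt(abs(rp$mean - lam), 3 * max(rp$sem, 1e-9))
})
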