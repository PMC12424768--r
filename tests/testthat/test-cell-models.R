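test_that("parameter constructors validate their inputs", {
  expect_error(fs_params(g_na = -1), "conductances")
  expect_error(stellate_params(g_nap = -5), "conductances")
  expect_error(fs_params(e_na = -100), "e_na > e_l > e_k")
  expect_error(make_fs_cell(stellate_params()), "not fast-spiking")
})

test_that("FS cell rests quietly at zero drive and fires under drive", {
  cell <- make_fs_cell()
  sim <- simulate_cell(cell, 500)
  expect_length(sim$spikes, 0)
  # settles to a fixed point near the leak reversal
  v_late <- tail(sim$trace$v_mV, 2000)
  expect_lt(diff(range(v_late)), 0.01)
  expect_lt(abs(tail(v_late, 1) - cell$params$e_l), 5)

  # sustained 7 nS excitatory conductance: repetitive firing
  sim7 <- simulate_cell(cell, 1000, g_drive = 7, e_drive = 0)
  expect_gt(length(sim7$spikes), 50)
})

test_that("FS cell fires tonically for 5 s without adaptation failure", {
  cell <- make_fs_cell()
  sim <- simulate_cell(cell, 5000, g_drive = 7, e_drive = 0)
  isi <- diff(sim$spikes)
  # steady state: no progressive slowing, no cessation
  expect_gt(max(sim$spikes), 4990)
  expect_lt(sd(tail(isi, 100)), 0.05 * mean(tail(isi, 100)))
})

test_that("engine f-I curve matches an independent RK4 integration", {
  # compare at a fine, matched step so both schemes are converged; the
  # faster-firing case uses a finer step over a shorter window
  cell <- make_fs_cell()
  cases <- list(list(i = 150, dt = 0.005, dur = 1000),
                list(i = 400, dt = 0.0025, dur = 500))
  for (cs in cases) {
    sim <- simulate_cell(cell, cs$dur, dt = cs$dt, i_inj = cs$i)
    vr <- rk4_cell(cell, cs$dur, dt = cs$dt, i_inj = cs$i)
    n_oracle <- count_upcrossings(vr[, "v"], dt = cs$dt)
    expect_lte(abs(length(sim$spikes) - n_oracle), 1)
  }
})

test_that("subthreshold trajectories agree with RK4 to < 0.1 mV", {
  # hold each cell at -70 mV with its steady-state balancing current,
  # then probe with a small sine: well below threshold for both types
  for (cell in list(make_fs_cell(), make_stellate_cell())) {
    ss <- cell_steady_state(cell, -70)
    hold <- -cell_derivatives(cell, ss)[[1]] * cell$params$c_m
    inj <- function(t) hold - 20 * sin(2 * pi * 5 * t / 1000)
    sim <- simulate_cell(cell, 1000, dt = 0.0125,
                         i_inj = inj(seq(0, 1000, by = 0.0125)),
                         v0 = -70)
    expect_length(sim$spikes, 0)
    vr <- rk4_cell(cell, 1000, dt = 0.0125, i_inj = inj, v0 = -70)
    expect_lt(max(abs(sim$trace$v_mV - vr[, "v"])), 0.1)
  }
})

test_that("stellate with resonance conductances removed is non-resonant", {
  plain <- make_stellate_cell(stellate_params(g_nap = 0, g_hf = 0,
                                              g_hs = 0))
  z <- impedance_profile(plain, f_min = 1, f_max = 20)
  # peak at the lowest frequencies: low-pass, no interior resonance
  expect_lt(resonance_frequency(z), 4)
})

test_that("default stellate resonates in the theta band (4-12 Hz)", {
  z <- impedance_profile(make_stellate_cell())
  fr <- resonance_frequency(z)
  expect_gte(fr, 4)
  expect_lte(fr, 12)
  # a genuine interior peak: impedance at resonance exceeds both ends
  expect_gt(max(z$impedance_MOhm), 1.05 * z$impedance_MOhm[1])
})

test_that("passive-cell impedance is low-pass with DC value 1/g", {
  pas <- make_fs_cell(fs_params(g_na = 0, g_k = 0, g_l = 10))
  z <- impedance_profile(pas, f_min = 0.5, f_max = 20)
  expect_lt(resonance_frequency(z), 4)
  expect_equal(z$impedance_MOhm[1], 1000 / 10, tolerance = 0.05)
  # decreasing beyond the RC corner, modulo small spectral ripple
  upper <- z$impedance_MOhm[z$frequency_Hz > 5]
  expect_true(all(diff(upper) < 0.02 * max(upper)))
})

test_that("impedance probe rejects spiking trajectories", {
  cell <- make_stellate_cell()
  expect_error(impedance_profile(cell, amplitude_pA = 600),
               "spiking")
})

test_that("population jitter is seeded, truncated and unbiased", {
  base <- stellate_params()
  spec0 <- population_spec(10, base, jitter_cv = 0, seed = 1)
  pop0 <- jitter_population(spec0)
  expect_true(all(pop0$g_na == base$g_na))

  spec <- population_spec(400, base, jitter_cv = 0.1, seed = 7)
  pop1 <- jitter_population(spec)
  pop2 <- jitter_population(spec)
  expect_identical(pop1, pop2)
  expect_equal(nrow(pop1), 400)
  expect_true(all(pop1$g_nap >= 0))
  for (f in c("g_na", "g_k", "g_l", "g_nap")) {
    se <- 0.1 * base[[f]] / sqrt(400)
    expect_lt(abs(mean(pop1[[f]]) - base[[f]]), 3 * se)
  }
})
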