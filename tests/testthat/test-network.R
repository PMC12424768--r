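test_that("connectivity sampling respects probabilities and exclusions", {
  cfg0 <- connectivity_config(p_ei = 0, p_ie = 0, p_ii = 0)
  e0 <- sample_connectivity(cfg0, n_e = 50, n_i = 20, seed = 1)
  expect_equal(nrow(e0), 0)

  cfg <- connectivity_config()
  edges <- sample_connectivity(cfg, n_e = 400, n_i = 100, seed = 1)
  # expected E afferents per I cell: 400 x 0.4 = 160
  ei <- dplyr::filter(edges, class == "EI")
  expect_equal(nrow(ei) / 100, 160, tolerance = 0.05)
  # no autapses in I-I
  ii <- dplyr::filter(edges, class == "II")
  expect_false(any(ii$pre == ii$post))
  # determinism
  expect_identical(edges,
                   sample_connectivity(cfg, n_e = 400, n_i = 100, seed = 1))
})

test_that("realized in-degrees stay inside central binomial bands", {
  cfg <- connectivity_config()
  n_e <- 400; n_i <- 100
  band <- qbinom(c(5e-4, 1 - 5e-4), n_e, cfg$p_ei)   # central 99.9%
  frac_in <- vapply(1:10, function(sd) {
    edges <- sample_connectivity(cfg, n_e = n_e, n_i = n_i, seed = sd)
    indeg <- tabulate(edges$post[edges$class == "EI"], nbins = n_i)
    mean(indeg >= band[1] & indeg <= band[2])
  }, numeric(1))
  expect_gte(mean(frac_in), 0.99)
})

test_that("lognormal I-E weights have the right location and support", {
  w <- sample_ie_weights(10000, meanlog = log(2), sdlog = 0.5, seed = 3)
  expect_true(all(w > 0))
  expect_equal(median(w), 2, tolerance = 0.05)
  # degenerate sigma -> constant
  w0 <- sample_ie_weights(100, meanlog = log(2), sdlog = 1e-12, seed = 3)
  expect_equal(w0, rep(2, 100), tolerance = 1e-6)
})

test_that("theta drive is a raised cosine with the stated peak and mean", {
  expect_equal(theta_conductance(0, 7, 8), 0)
  expect_equal(theta_conductance(125, 7, 8), 0, tolerance = 1e-12)
  expect_equal(theta_conductance(62.5, 7, 8), 7)        # crest
  t <- seq(0, 125, length.out = 10001)[-10001]
  expect_equal(mean(theta_conductance(t, 7, 8)), 3.5, tolerance = 1e-3)
  expect_true(all(theta_conductance(t, 7, 8) >= 0))
})

test_that("OU drive noise is seeded with the stated stationary variance", {
  z0 <- make_drive_noise(0, 1, 0.025, 1000, seed = 1)
  expect_true(all(z0 == 0))

  z <- make_drive_noise(sd = 0.5, tau = 1, dt = 0.025, duration = 10000,
                        seed = 2, n = 4)
  expect_equal(dim(z), c(400001, 4))
  expect_equal(sd(as.vector(z)), 0.5, tolerance = 0.1)
  z2 <- make_drive_noise(sd = 0.5, tau = 1, dt = 0.025, duration = 10000,
                         seed = 2, n = 4)
  expect_identical(z, z2)
  # autocorrelation time approximately tau
  ac <- acf(z[, 1], lag.max = 80, plot = FALSE)$acf
  expect_equal(ac[41], exp(-1), tolerance = 0.1)  # lag = 1 ms = tau
})

test_that("assembled network has the canonical composition", {
  net <- assemble_network(seed = 1)
  expect_equal(sum(net$cells$population == "I"), 100)
  expect_equal(sum(net$cells$population == "E"), 400)
  expect_equal(sum(net$cells$is_readout), 10)
  expect_false(any(net$edges$class == "EE"))
  # no efferents from readouts
  readouts <- net$cells$cell[net$cells$is_readout]
  expect_false(any(net$edges$pre %in% readouts))
  # readouts do receive afferents
  expect_true(all(readouts %in% net$edges$post))

  net2 <- assemble_network(seed = 1)
  expect_identical(net$edges, net2$edges)
  net3 <- assemble_network(seed = 2)
  expect_false(identical(net$edges, net3$edges))
})

test_that("class conductance rescaling acts on one class only", {
  net <- assemble_network(seed = 4)
  net0 <- set_class_conductance(net, "EI", 0)
  expect_true(all(net0$edges$weight_nS[net0$edges$class == "EI"] == 0))
  expect_identical(net0$edges$weight_nS[net0$edges$class != "EI"],
                   net$edges$weight_nS[net$edges$class != "EI"])
  expect_error(set_class_conductance(net, "EE", 1), "unknown")

  # total semantics: expected per-target sum
  net2 <- set_class_conductance(net, "EI", 8, semantics = "total")
  s <- class_conductance_summary(net2)
  expect_equal(s$mean_total_per_target_nS[s$class == "EI"], 8,
               tolerance = 0.05)
  # per-edge semantics
  net3 <- set_class_conductance(net, "EI", 8, semantics = "per_edge")
  expect_true(all(net3$edges$weight_nS[net3$edges$class == "EI"] == 8))
})

test_that("distributed GABA reversal assigns per-interneuron values", {
  net <- assemble_network(egaba_ii = "distributed", seed = 5)
  is_i <- net$cells$population %in% c("I", "I_readout")
  er <- net$cells$gaba_e_rev[is_i]
  expect_true(all(er >= -75 & er <= -55))
  expect_gt(length(unique(er)), 50)
  # E cells keep the I->E reversal
  expect_true(all(net$cells$gaba_e_rev[!is_i] == -65))
})

test_that("network configuration round-trips through YAML", {
  net <- assemble_network(seed = 11)
  path <- tempfile(fileext = ".yaml")
  write_network_config(net, path)
  net2 <- read_network_config(path)
  expect_identical(net$edges, net2$edges)
  expect_equal(net$cells$g_na, net2$cells$g_na)
  unlink(path)
})
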