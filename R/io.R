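# Configuration serialization (YAML) and result export (CSV + JSON).

#' Write a network configuration to YAML
#'
#' Serializes everything needed to rebuild a network deterministically:
#' population sizes and base cell parameters, connectivity probabilities
#' and weight distributions, synapse kinetics, drive, readouts, reversal
#' variants and the seed.
#'
#' @param network An `mec_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_config <- function(network, path) {
  stopifnot(inherits(network, "mec_network"))
  syn <- lapply(network$synapses, function(s) unclass(s))
  cfg <- list(
    n_i = network$n_i, n_e = network$n_e,
    n_readouts = network$n_readouts, v_hold = network$v_hold,
    seed = network$seed,
    egaba_ii = network$egaba_ii,
    connectivity = unclass(network$conn),
    drive = unclass(network$drive),
    synapses = syn,
    fs_base = unclass(fs_base_of(network)),
    stellate_base = unclass(stellate_base_of(network)),
    jitter_cv = attr(network, "jitter_cv") %||% 0.1
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

fs_base_of <- function(network) {
  attr(network, "fs_base") %||% fs_params()
}
stellate_base_of <- function(network) {
  attr(network, "stellate_base") %||% stellate_params()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild a network from a YAML configuration
#'
#' @param path YAML file written by [write_network_config()].
#' @return An `mec_network` (identical to the original for matching
#'   package versions, since construction is deterministic in the seed).
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  conn <- do.call(connectivity_config, cfg$connectivity)
  drive <- do.call(theta_drive_spec,
                   cfg$drive[c("f_theta", "g_peak_i", "g_peak_e", "e_rev",
                               "noise_sd", "noise_tau")])
  syn <- lapply(cfg$synapses, function(s) {
    synapse_spec(kind = s$kind,
                 tau_rise = if (is.null(s$tau_rise)) NA else s$tau_rise,
                 tau_decay = s$tau_decay, e_rev = s$e_rev,
                 g_max = s$g_max %||% 1, delay = s$delay %||% 0)
  })
  fsb <- do.call(fs_params, cfg$fs_base[c("c_m", "g_na", "g_k", "g_l",
                                          "e_na", "e_k", "e_l", "phi")])
  stb <- do.call(stellate_params,
                 cfg$stellate_base[c("c_m", "g_na", "g_k", "g_l", "g_nap",
                                     "g_hf", "g_hs", "e_na", "e_k", "e_l",
                                     "e_h", "phi")])
  assemble_network(n_i = cfg$n_i, n_e = cfg$n_e, conn = conn,
                   drive = drive, synapses = syn,
                   egaba_ii = cfg$egaba_ii, fs_base = fsb,
                   stellate_base = stb, jitter_cv = cfg$jitter_cv,
                   n_readouts = cfg$n_readouts, v_hold = cfg$v_hold,
                   seed = cfg$seed)
}

#' Export network adjacency as an edge-list CSV
#'
#' Columns: `pre_id`, `post_id`, `class`, `weight_nS`, `E_rev_mV`,
#' `tau_rise_ms`, `tau_decay_ms`.
#'
#' @param network An `mec_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "mec_network"))
  syn <- network$synapses
  e <- network$edges
  kin <- list(EI = syn$ei, IE = syn$ie, II = syn$ii)
  e_rev <- vapply(e$class, function(cl) kin[[cl]]$e_rev, numeric(1))
  ii_sel <- e$class == "II"
  e_rev[ii_sel] <- network$cells$gaba_e_rev[e$post[ii_sel]]
  out <- data.frame(
    pre_id = e$pre, post_id = e$post, class = e$class,
    weight_nS = e$weight_nS, E_rev_mV = e_rev,
    tau_rise_ms = vapply(e$class, function(cl) kin[[cl]]$tau_rise,
                         numeric(1)),
    tau_decay_ms = vapply(e$class, function(cl) kin[[cl]]$tau_decay,
                          numeric(1)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export simulation results
#'
#' Writes spikes to `<prefix>_spikes.csv` (`cell_id`, `population`,
#' `t_ms`), clamp currents to `<prefix>_clamp.csv` (wide, one column per
#' readout), and run metadata to `<prefix>_meta.json`.
#'
#' @param sim An `mec_sim`.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_sim_result <- function(sim, prefix) {
  stopifnot(inherits(sim, "mec_sim"))
  p1 <- paste0(prefix, "_spikes.csv")
  p2 <- paste0(prefix, "_clamp.csv")
  p3 <- paste0(prefix, "_meta.json")
  utils::write.csv(data.frame(cell_id = sim$spikes$cell,
                              population = sim$spikes$population,
                              t_ms = sim$spikes$t_ms),
                   p1, row.names = FALSE)
  clamp <- data.frame(time_ms = sim$time_ms, sim$clamp, check.names = FALSE)
  names(clamp)[-1] <- paste0("cell_", sim$clamp_cells$cell)
  utils::write.csv(clamp, p2, row.names = FALSE)
  meta <- list(f_theta = sim$f_theta, n_theta_cycles = sim$n_theta_cycles,
               dt = sim$config$dt, record_dt = sim$config$record_dt,
               network_seed = sim$network_seed,
               n_i = sim$n_i, n_e = sim$n_e,
               package_version = as.character(utils::packageVersion("mecgamma")))
  jsonlite::write_json(meta, p3, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
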