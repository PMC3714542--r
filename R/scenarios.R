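#' Spike-triggered force on the agent
#'
#' Every spike acts as an instantaneous attractor: the force is
#' `a_F * sum_f (x_j - x_a)` over the spikes observed in the step, pulling
#' the agent toward the spiking cells' field centers.
#'
#' @param spike_ids neuron ids spiking this step
#' @param map a `wn_map`
#' @param env_index environment index
#' @param agent_pos agent position (metres)
#' @param a_F force gain
#' @return force vector (2)
#' @export
spike_force <- function(spike_ids, map, env_index, agent_pos, a_F = 2) {
  if (length(spike_ids) == 0) return(c(0, 0))
  ctr <- map$centers[[env_index]][spike_ids, , drop = FALSE]
  unname(a_F * c(sum(ctr[, 1] - agent_pos[1]), sum(ctr[, 2] - agent_pos[2])))
}

#' The dual-map operating point
#'
#' Configuration used when two environments are stored in one network.
#' Cross-map synapses act as long-range projections that can relay activity
#' non-locally, so the wavefront phase runs with a higher coincidence
#' requirement (weaker per-volley gain `a_syn`), a 5 ms synaptic transmission
#' delay that caps the front speed, a shorter activity window and a larger
#' adaptation increment than the single-map defaults.
#'
#' @param ... further overrides passed to [wn_config()]
#' @return a `wn_config`
#' @export
dual_env_config <- function(...) {
  base <- list(
    synapse = list(a_syn = 3.4),
    neuron = list(dI_ca = 80, eps_active = 0.5, syn_delay = 0.005),
    exploration = list(m = 16))
  over <- list(...)
  for (grp in names(over)) base[[grp]] <- utils::modifyList(base[[grp]] %||% list(),
                                                           over[[grp]])
  do.call(wn_config, base)
}

#' Run a preset experiment scenario
#'
#' Presets (sizes chosen for a desk-scale run of minutes on one CPU):
#'
#' * `calibration`: open arena; wavefront; measures propagation speed.
#' * `fig2_tmaze`: wavefront propagation and adaptation map in the "T" maze.
#' * `fig3_navigation`: "T"-maze planning, vector field and a navigation run.
#' * `fig4_multitarget`: three equal targets in an open arena, basin
#'   partition and three navigation runs.
#' * `fig5_noise`: spurious-front incidence under injected spike noise,
#'   supralinear vs linear summation.
#' * `fig6_dualenv`: two maps in one network; field diagnostics in both
#'   coordinate frames.
#' * `fig7_dualnav`: navigation in each of the two stored maps.
#'
#' @param name scenario name
#' @param config optional `wn_config` overrides (a list of group overrides)
#' @param seed master seed
#' @param out_dir optional directory for CSV/JSON artifacts
#' @param n_cells override the scenario's network size
#' @return scenario result list (invisibly if `out_dir` given)
#' @export
run_scenario <- function(name = c("calibration", "fig2_tmaze",
                                  "fig3_navigation", "fig4_multitarget",
                                  "fig5_noise", "fig6_dualenv",
                                  "fig7_dualnav"),
                         config = NULL, seed = 1, out_dir = NULL,
                         n_cells = NULL) {
  name <- match.arg(name)
  res <- switch(name,
    calibration = scenario_calibration(config, seed, n_cells %||% 900),
    fig2_tmaze = scenario_tmaze(config, seed, n_cells %||% 2000),
    fig3_navigation = scenario_navigation(config, seed, n_cells %||% 2000),
    fig4_multitarget = scenario_multitarget(config, seed, n_cells %||% 1600),
    fig5_noise = scenario_noise(config, seed, n_cells %||% 900),
    fig6_dualenv = scenario_dualenv(config, seed, n_cells %||% 1800, navigate = FALSE),
    fig7_dualnav = scenario_dualenv(config, seed, n_cells %||% 1800, navigate = TRUE))
  res$scenario <- name
  res$seed <- seed
  res$config_hash <- config_hash(res$config %||% wn_config())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scenario(res, out_dir)
    return(invisible(res))
  }
  res
}

base_cfg <- function(config) {
  if (is.null(config)) return(wn_config())
  if (inherits(config, "wn_config")) return(validate_config(config))
  do.call(wn_config, config)
}

scenario_calibration <- function(config, seed, n) {
  cfg <- base_cfg(config)
  env <- make_environment("open")
  map <- assign_place_fields(env, n_cells = n, seed = seed,
                             footprint = cfg$placefields$footprint,
                             amplitude = cfg$placefields$amplitude)
  w <- nearest_neighbour_connectivity(map, 1, m = cfg$exploration$m,
                                      w0 = cfg$exploration$w0)
  net <- make_network(map, w, cfg)
  tgt <- target_set(rbind(c(0.5, 0.5)))
  fr <- run_planning(net, tgt, seed = seed)
  orc <- geodesic_distances(w, map, 1, rbind(c(0.5, 0.5)))
  sp <- measure_front_speed(fr, orc$dist)
  list(config = cfg, map = map, front = fr, speed = sp,
       report = c(planning_report(fr), sp))
}

scenario_tmaze <- function(config, seed, n) {
  cfg <- base_cfg(config)
  env <- make_environment("T")
  map <- assign_place_fields(env, n_cells = n, seed = seed,
                             footprint = cfg$placefields$footprint,
                             amplitude = cfg$placefields$amplitude)
  w <- nearest_neighbour_connectivity(map, 1, m = cfg$exploration$m,
                                      w0 = cfg$exploration$w0)
  net <- make_network(map, w, cfg)
  tgt_loc <- c(0.08, 0.85)
  fr <- run_planning(net, target_set(rbind(tgt_loc)), seed = seed)
  orc <- geodesic_distances(w, map, 1, rbind(tgt_loc))
  sp <- measure_front_speed(fr, orc$dist)
  # adaptation map after passage (Fig 2C-D analogue): i_Ca per cell
  list(config = cfg, map = map, front = fr, speed = sp,
       adaptation = fr$network$state$ica,
       report = c(planning_report(fr), sp))
}

scenario_navigation <- function(config, seed, n) {
  cfg <- base_cfg(config)
  env <- make_environment("T")
  map <- assign_place_fields(env, n_cells = n, seed = seed,
                             footprint = cfg$placefields$footprint,
                             amplitude = cfg$placefields$amplitude)
  w <- nearest_neighbour_connectivity(map, 1, m = cfg$exploration$m,
                                      w0 = cfg$exploration$w0)
  net <- make_network(map, w, cfg)
  S <- c(0.5, 0.08); T_loc <- c(0.08, 0.85)
  fr <- run_planning(net, target_set(rbind(T_loc)), seed = seed)
  field <- compute_svf(fr$network$weights, map, 1)
  orc <- geodesic_distances(w, map, 1, rbind(T_loc))
  diag <- svf_diagnostics(field, orc, map)
  traj <- navigate(fr$network, S, T_loc, seed = derive_seed(seed, "nav"))
  orcS <- geodesic_distances(w, map, 1, rbind(S))
  ctr <- map$centers[[1]]
  iT <- which.min((ctr[, 1] - T_loc[1])^2 + (ctr[, 2] - T_loc[2])^2)
  list(config = cfg, map = map, front = fr, field = field, diag = diag,
       traj = traj,
       report = list(alignment = diag$alignment,
                     attractor = diag$attractor_pos,
                     outcome = attr(traj, "outcome"),
                     path_length = attr(traj, "path_length"),
                     oracle_length = orcS$dist[iT],
                     ratio = attr(traj, "path_length") / orcS$dist[iT]))
}

scenario_multitarget <- function(config, seed, n) {
  cfg <- base_cfg(config)
  env <- make_environment("open")
  map <- assign_place_fields(env, n_cells = n, seed = seed,
                             footprint = cfg$placefields$footprint,
                             amplitude = cfg$placefields$amplitude)
  w <- nearest_neighbour_connectivity(map, 1, m = cfg$exploration$m,
                                      w0 = cfg$exploration$w0)
  net <- make_network(map, w, cfg)
  locs <- rbind(c(0.2, 0.75), c(0.75, 0.8), c(0.6, 0.2))
  tg <- target_set(locs)
  fr <- run_planning(net, tg, seed = seed)
  orc <- geodesic_distances(w, map, 1, locs)
  vor <- geodesic_voronoi(orc)
  starts <- rbind(c(0.12, 0.95), c(0.95, 0.6), c(0.3, 0.1))
  mt <- multi_target_navigate(fr$network, starts, tg,
                              seed = derive_seed(seed, "mt"))
  list(config = cfg, map = map, front = fr, voronoi = vor, nav = mt,
       report = c(planning_report(fr),
                  list(voronoi_agreement = mean(fr$source_label == vor$label),
                       nav = mt)))
}

scenario_noise <- function(config, seed, n, rate = 2, n_seeds = 5) {
  cfg <- base_cfg(config)
  env <- make_environment("open")
  map <- assign_place_fields(env, n_cells = n, seed = seed,
                             footprint = cfg$placefields$footprint,
                             amplitude = cfg$placefields$amplitude)
  w <- nearest_neighbour_connectivity(map, 1, m = cfg$exploration$m,
                                      w0 = cfg$exploration$w0)
  runs <- expand.grid(seed = seq_len(n_seeds), supra = c(TRUE, FALSE))
  runs$spurious <- NA_real_
  for (r in seq_len(nrow(runs))) {
    cfg_r <- cfg
    cfg_r$synapse$supralinear <- runs$supra[r]
    net <- make_network(map, w, cfg_r)
    fr <- run_planning(net, target_set(rbind(c(0.5, 0.5))), noise_rate = rate,
                       t_max = 0.4, seed = derive_seed(seed, paste0("noise", runs$seed[r])))
    runs$spurious[r] <- mean(fr$source_label == 0)
  }
  list(config = cfg, runs = runs,
       report = list(rate = rate,
                     spurious_supra = mean(runs$spurious[runs$supra]),
                     spurious_linear = mean(runs$spurious[!runs$supra])))
}

scenario_dualenv <- function(config, seed, n, navigate = FALSE) {
  cfg <- if (is.null(config)) dual_env_config() else base_cfg(config)
  envs <- list(make_environment("A"), make_environment("inf", side = 0.5))
  map <- assign_place_fields(envs, n_cells = n, seed = seed,
                             footprint = cfg$placefields$footprint,
                             amplitude = cfg$placefields$amplitude)
  w <- nearest_neighbour_connectivity(map, env_index = 1:2,
                                      m = cfg$exploration$m,
                                      w0 = cfg$exploration$w0)
  tgts <- list(c(0.5, 0.85), c(0.5, 0.25))
  starts <- list(c(0.47, 0.73), c(0.58, 0.3))
  out <- list(config = cfg, map = map, per_env = list())
  for (ei in 1:2) {
    net <- make_network(map, w, cfg)
    fr <- run_planning(net, target_set(rbind(tgts[[ei]])), env_index = ei,
                       t_max = 4, seed = seed)
    orc <- geodesic_distances(w, map, ei, rbind(tgts[[ei]]))
    fS <- compute_svf(fr$network$weights, map, ei)
    fO <- compute_svf(fr$network$weights, map, 3 - ei)
    dS <- svf_diagnostics(fS, orc, map)
    nul <- svf_coherence_null(fO, map, n_perm = 49,
                              seed = derive_seed(seed, paste0("null", ei)))
    rec <- list(target = tgts[[ei]], coverage = fr$coverage,
                alignment = dS$alignment,
                foreign_local_mrl = svf_local_mrl(fO, map),
                foreign_null95 = unname(stats::quantile(nul, 0.95)),
                front = fr, field = fS)
    if (navigate) {
      outs <- vapply(1:3, function(s)
        attr(navigate(fr$network, starts[[ei]], tgts[[ei]], env_index = ei,
                      seed = derive_seed(seed, paste0("nav", ei, "_", s))),
             "outcome"), "")
      rec$nav_success <- mean(outs == "reached")
      rec$nav_outcome <- if (rec$nav_success >= 0.5) "reached" else outs[1]
    }
    out$per_env[[ei]] <- rec
  }
  out$report <- lapply(out$per_env, function(r)
    r[c("target", "coverage", "alignment", "foreign_local_mrl",
        "foreign_null95", if (navigate) "nav_outcome")])
  out
}

write_scenario <- function(res, out_dir) {
  pick <- function(x) !is.null(x)
  if (pick(res$front)) {
    utils::write.csv(res$front$spikes, file.path(out_dir, "spikes.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(neuron_id = seq_along(res$front$first_spike),
                 t_first = res$front$first_spike,
                 source_label = res$front$source_label),
      file.path(out_dir, "first_spikes.csv"), row.names = FALSE)
  }
  if (pick(res$field)) write_svf(res$field, file.path(out_dir, "svf.csv"))
  if (pick(res$traj)) utils::write.csv(as.data.frame(res$traj),
                                       file.path(out_dir, "trajectory.csv"),
                                       row.names = FALSE)
  manifest <- list(scenario = res$scenario, seed = res$seed,
                   config_hash = res$config_hash, report = res$report)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(res)
}
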