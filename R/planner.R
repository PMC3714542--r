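#' Target set for planning
#'
#' @param locations `k x 2` matrix of target positions (metres)
#' @param rewards per-target rewards `R_k` (> 0); default all equal
#' @param cost_rate travel cost `C` per metre of path
#' @return a `wn_targets`
#' @export
target_set <- function(locations, rewards = NULL, cost_rate = 1) {
  locations <- matrix(as.double(locations), ncol = 2)
  rewards <- rewards %||% rep(1, nrow(locations))
  stopifnot(length(rewards) == nrow(locations), all(rewards > 0),
            cost_rate > 0)
  structure(list(locations = locations, rewards = rewards,
                 cost_rate = cost_rate), class = "wn_targets")
}

#' Reward-dependent wavefront initiation delays
#'
#' With equal-speed fronts, a reward difference is equivalent to a head start:
#' the highest-reward target fires its exciter first and target `k` follows
#' after `(max R - R_k) / (C v)`, where `C` is the cost per metre and `v` the
#' measured front speed. The delays shift the basin boundaries toward the
#' lower-reward targets.
#'
#' @param targets a [target_set()]
#' @param v wavefront speed (m/s), measured by [measure_front_speed()]
#' @return per-target delay (s)
#' @export
reward_to_delays <- function(targets, v) {
  if (v <= 0) stop("wavefront speed must be positive")
  (max(targets$rewards) - targets$rewards) / (targets$cost_rate * v)
}

#' Build exciter pulses that seed a wavefront at each target
#'
#' The cells whose field centers lie within `radius` of a target location
#' receive a brief suprathreshold current pulse at that target's start time,
#' producing a cluster of near-synchronous spikes.
#'
#' @param network a `wn_network`
#' @param targets a [target_set()] (or `k x 2` matrix)
#' @param env_index environment index
#' @param delays per-target start times (s); default from rewards (zero when
#'   equal) via [reward_to_delays()] if `v` is given, else all zero
#' @param v measured front speed, needed only for reward-derived delays
#' @param radius seeding radius (m); default the receptive-field sigma
#' @return pulse list consumed by [run_planning()]
#' @export
seed_wavefront <- function(network, targets, env_index = 1, delays = NULL,
                           v = NULL, radius = NULL) {
  if (!inherits(targets, "wn_targets")) targets <- target_set(targets)
  cfg <- network$config$planner
  radius <- radius %||% cfg$seed_radius %||% network$map$sigma[env_index]
  k <- nrow(targets$locations)
  if (is.null(delays)) {
    delays <- if (!is.null(v)) reward_to_delays(targets, v) else rep(0, k)
  }
  env <- network$map$envs[[env_index]]
  members <- vector("list", k)
  for (i in seq_len(k)) {
    loc <- targets$locations[i, ]
    if (!env_contains(env, rbind(loc))) stop("target outside environment")
    mem <- cells_near(network$map, env_index, loc, radius)
    if (length(mem) < cfg$min_seed_cells)
      stop(sprintf("target %d footprint holds %d cells (< %d): too few to trigger propagation",
                   i, length(mem), cfg$min_seed_cells))
    members[[i]] <- as.integer(mem - 1L)
  }
  list(t0 = delays, dur = rep(cfg$seed_dur, k),
       amp = rep(cfg$seed_amp, k), label = seq_len(k),
       members = members, targets = targets)
}

#' Generate a stream of random forced spikes (noise injection)
#'
#' Poisson-timed spike currents delivered to uniformly random neurons: each
#' event forces a full spike (threshold crossing, refractory period,
#' adaptation increment). Events carry source label 0 so spurious,
#' noise-descended activity can be audited by label propagation.
#'
#' @param n number of neurons
#' @param rate spikes per neuron per second
#' @param t_max duration covered (s)
#' @param dt integration step (s)
#' @param seed integer seed
#' @return data.frame `(step, id, label)`
#' @export
inject_noise_spikes <- function(n, rate, t_max, dt = 2e-4, seed = 1) {
  set.seed(derive_seed(seed, "noise_spikes"))
  count <- stats::rpois(1, rate * n * t_max)
  if (count == 0)
    return(data.frame(step = integer(0), id = integer(0), label = integer(0)))
  data.frame(step = sort(sample.int(round(t_max / dt), count, replace = TRUE)) - 1L,
             id = sample.int(n, count, replace = TRUE),
             label = 0L)
}

#' Run the planning phase: propagate wavefront(s) and write the SVF
#'
#' Seeds a wavefront at each target (with reward-dependent delays), runs the
#' spiking core with the inhibition gate off and anti-STDP (`d = -1`), and
#' terminates either when the front reaches the agent's place cells
#' (`agent_pos` given) or after a quiescence window with no spikes (whole-map
#' mode, used to chart the complete vector field).
#'
#' @param network a `wn_network` in post-exploration or post-reset state
#' @param targets a [target_set()] or `k x 2` matrix
#' @param env_index environment index
#' @param agent_pos optional agent position: planning halts when a cell within
#'   one sigma of it fires
#' @param noise_rate forced-spike noise rate (spikes/neuron/s)
#' @param delays,v passed to [seed_wavefront()]
#' @param t_max hard time limit (s)
#' @param seed integer seed (noise and membrane noise)
#' @return a `wn_front` result: the updated network, spike record with source
#'   labels, per-neuron first spike times, coverage diagnostics
#' @export
run_planning <- function(network, targets, env_index = 1, agent_pos = NULL,
                         noise_rate = 0, delays = NULL, v = NULL,
                         t_max = NULL, seed = 1) {
  cfg <- network$config
  t_max <- t_max %||% cfg$planner$t_max
  network <- set_phase(network, "plan")
  pulses <- seed_wavefront(network, targets, env_index, delays = delays, v = v)
  forced <- NULL
  if (noise_rate > 0)
    forced <- inject_noise_spikes(network$map$n, noise_rate, t_max,
                                  cfg$neuron$dt, seed)
  set.seed(derive_seed(seed, "planning"))
  term <- if (is.null(agent_pos)) 1L else 2L
  res <- run_core(network, env_index, t_max = t_max, mode = "none",
                  term_mode = term, quiet_window = cfg$planner$quiet_window,
                  stop_pos = agent_pos %||% c(0, 0),
                  stop_radius = network$map$sigma[env_index],
                  pulses = pulses, forced = forced,
                  noise_sd = cfg$planner$noise_sd)
  if (res$outcome == 5)
    stop("runaway activity during planning (population guard tripped)")
  network <- absorb_result(network, res)

  n <- network$map$n
  reachable <- n   # built environments are connected
  spikes <- data.frame(id = res$spike_id, t = res$spike_t,
                       label = res$spike_label)
  structure(
    list(network = network, spikes = spikes,
         first_spike = res$first_spike, n_spikes = res$n_spikes,
         source_label = res$label,
         coverage = mean(res$n_spikes > 0),
         multi_fire = sum(res$n_spikes > 1),
         fired_once = mean(res$n_spikes == 1),
         outcome = c("t_max", "quiescent", "agent_reached", "", "", "runaway")[res$outcome + 1],
         t_end = res$t_end, targets = pulses$targets, delays = pulses$t0,
         env_index = env_index),
    class = "wn_front")
}

#' @export
print.wn_front <- function(x, ...) {
  cat(sprintf("<wn_front: %d targets, %.1f%% cells fired (%.1f%% exactly once), %d multi-fire, end %s at %.3f s>\n",
              nrow(x$targets$locations), 100 * x$coverage,
              100 * x$fired_once, x$multi_fire, x$outcome, x$t_end))
  invisible(x)
}

#' Measure the wavefront propagation speed
#'
#' Affine fit of first-spike time against graph-geodesic distance from the
#' seed; the slope inverse is the speed `v` used for reward-delay conversion.
#'
#' @param front a [run_planning()] result
#' @param distances per-neuron geodesic distance from the seed
#'   ([geodesic_distances()])
#' @return list with `v` (m/s), `r` (Pearson correlation) and `r2` of the fit
#' @export
measure_front_speed <- function(front, distances) {
  ok <- is.finite(front$first_spike) & is.finite(distances)
  fit <- stats::lm(front$first_spike[ok] ~ distances[ok])
  list(v = 1 / unname(stats::coef(fit)[2]),
       r = stats::cor(distances[ok], front$first_spike[ok]),
       r2 = summary(fit)$r.squared)
}

#' Re-seed a wavefront after a recovery gap
#'
#' A second wavefront cannot be initiated in a region the first has traversed
#' until the spike-frequency adaptation has decayed; coverage of the re-seeded
#' front grows monotonically with the gap.
#'
#' @param network network returned inside a completed [run_planning()] result
#' @param targets the target(s) to re-seed
#' @param gap waiting time before re-seeding (s)
#' @param env_index environment index
#' @param seed integer seed
#' @return the re-seeded `wn_front`
#' @export
second_front <- function(network, targets, gap, env_index = 1, seed = 1) {
  network <- decay_state(network, gap)
  network$weights <- reset_synapses(network$weights)  # probe excitability only
  run_planning(network, targets, env_index = env_index, seed = seed)
}

#' Planning report
#'
#' JSON-ready summary of a planning run: targets, delays, coverage, multi-fire
#' count, and per-basin cell counts.
#'
#' @param front a `wn_front`
#' @return list
#' @export
planning_report <- function(front) {
  basins <- table(factor(front$source_label,
                         levels = c(0, seq_len(nrow(front$targets$locations)))))
  list(n_targets = nrow(front$targets$locations),
       delays = front$delays,
       coverage = front$coverage, fired_once = front$fired_once,
       multi_fire = front$multi_fire,
       basin_cells = as.list(stats::setNames(
         as.integer(basins), c("noise", paste0("T", seq_len(nrow(front$targets$locations)))))),
       outcome = front$outcome, t_end = front$t_end)
}
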