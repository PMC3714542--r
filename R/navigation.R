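#' Navigate the agent along the synaptic vector field
#'
#' The movement-execution phase: plasticity is off (`d = 0`), weak global
#' activity-dependent inhibition is on, and the place cells around the
#' agent's current position receive tonic excitation. Every spike in the
#' network acts as an instantaneous attractor, delivering a force impulse
#' `a_F (x_j - x_a)` that kicks the point-mass agent toward the spiking
#' cell's field center; the anti-STDP weight asymmetry makes cells on the
#' target side of the activity bump fire preferentially, so the agent drifts
#' along the vector field. Wall collisions are resolved by removing the
#' normal velocity component (slide).
#'
#' @param network a `wn_network` carrying SVF-bearing weights (post-planning,
#'   not reset)
#' @param start agent start position (metres)
#' @param target target position; the run stops when the agent comes within
#'   the capture radius (default 2 sigma)
#' @param env_index environment index
#' @param max_time simulated time limit (s)
#' @param seed integer seed (background membrane noise)
#' @return a `wn_navtraj`: data.frame `(t, x, y, n_spikes)` with outcome,
#'   path length and attributes
#' @export
navigate <- function(network, start, target, env_index = 1, max_time = NULL,
                     seed = 1) {
  cfg <- network$config
  max_time <- max_time %||% cfg$agent$max_time
  capture <- cfg$agent$capture_radius %||% (2 * network$map$sigma[env_index])
  env <- network$map$envs[[env_index]]
  if (!env_contains(env, rbind(start))) stop("start outside environment")
  network <- set_phase(network, "navigate")
  set.seed(derive_seed(seed, "navigate"))
  w_before <- network$weights$W@x

  agent <- list(x0 = as.double(start), v0 = c(0, 0),
                mass = cfg$agent$mass, damping = cfg$agent$damping,
                a_F = cfg$agent$a_F, target = as.double(target),
                capture_radius = capture,
                record_every = as.integer(cfg$agent$record_every))
  res <- run_core(network, env_index, t_max = max_time, mode = "agent",
                  term_mode = 0L, quiet_window = cfg$agent$stall_window,
                  agent = agent, noise_sd = cfg$agent$noise_sd,
                  sens_amp = cfg$agent$tonic_amp,
                  record_spikes = FALSE)
  stopifnot(identical(res$Wx, w_before))  # d = 0: plasticity frozen

  traj <- data.frame(t = res$agent_traj[, 1], x = res$agent_traj[, 2],
                     y = res$agent_traj[, 3], n_spikes = res$agent_traj[, 4])
  out <- traj
  attr(out, "outcome") <- switch(as.character(res$outcome),
                                 "3" = "reached", "4" = "stalled", "timeout")
  attr(out, "path_length") <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  attr(out, "t_end") <- res$t_end
  attr(out, "start") <- as.double(start)
  attr(out, "target") <- as.double(target)
  attr(out, "final_pos") <- res$agent_pos
  attr(out, "seed") <- seed
  class(out) <- c("wn_navtraj", "data.frame")
  out
}

#' @export
print.wn_navtraj <- function(x, ...) {
  cat(sprintf("<wn_navtraj: %s after %.2f s, path %.3f m, final (%.3f, %.3f)>\n",
              attr(x, "outcome"), attr(x, "t_end"), attr(x, "path_length"),
              attr(x, "final_pos")[1], attr(x, "final_pos")[2]))
  invisible(x)
}

#' Navigate several starts against a multi-target field
#'
#' Runs [navigate()] from each start; a run counts as converged to the target
#' whose capture disc it enters first. Planning with the full target set must
#' have been done beforehand.
#'
#' @param network post-planning `wn_network`
#' @param starts `k x 2` matrix of start positions
#' @param targets the [target_set()] used for planning
#' @param env_index environment index
#' @param max_time per-run time limit (s)
#' @param seed integer seed (one stream per start)
#' @return data.frame: start index, reached target index (0 = none), time,
#'   path length
#' @export
multi_target_navigate <- function(network, starts, targets, env_index = 1,
                                  max_time = NULL, seed = 1) {
  starts <- matrix(as.double(starts), ncol = 2)
  k <- nrow(targets$locations)
  cfg <- network$config
  capture <- cfg$agent$capture_radius %||% (2 * network$map$sigma[env_index])
  out <- data.frame(start = integer(0), reached = integer(0),
                    t = numeric(0), path_length = numeric(0))
  for (s in seq_len(nrow(starts))) {
    # run against the nearest-capture rule: terminate on whichever target
    # disc is entered first by monitoring all of them
    traj <- navigate_any(network, starts[s, ], targets$locations, capture,
                         env_index, max_time, derive_seed(seed, paste0("mt", s)))
    out <- rbind(out, data.frame(start = s, reached = attr(traj, "which"),
                                 t = attr(traj, "t_end"),
                                 path_length = attr(traj, "path_length")))
  }
  out
}

# navigate until any of several target discs is entered
navigate_any <- function(network, start, locations, capture, env_index,
                         max_time, seed) {
  cfg <- network$config
  max_time <- max_time %||% cfg$agent$max_time
  # run with no capture (radius 0) and post-hoc detect the first disc entry
  network <- set_phase(network, "navigate")
  set.seed(derive_seed(seed, "navigate"))
  agent <- list(x0 = as.double(start), v0 = c(0, 0),
                mass = cfg$agent$mass, damping = cfg$agent$damping,
                a_F = cfg$agent$a_F, target = c(-1e6, -1e6),
                capture_radius = 0,
                record_every = as.integer(cfg$agent$record_every))
  res <- run_core(network, env_index, t_max = max_time, mode = "agent",
                  term_mode = 0L, quiet_window = cfg$agent$stall_window,
                  agent = agent, noise_sd = cfg$agent$noise_sd,
                  sens_amp = cfg$agent$tonic_amp, record_spikes = FALSE)
  traj <- res$agent_traj
  which_t <- 0L; t_hit <- res$t_end; row_hit <- nrow(traj)
  for (k in seq_len(nrow(locations))) {
    d <- sqrt((traj[, 2] - locations[k, 1])^2 + (traj[, 3] - locations[k, 2])^2)
    hit <- which(d <= capture)
    if (length(hit) && traj[hit[1], 1] < t_hit) {
      which_t <- k; t_hit <- traj[hit[1], 1]; row_hit <- hit[1]
    }
  }
  out <- data.frame(t = traj[, 1], x = traj[, 2], y = traj[, 3],
                    n_spikes = traj[, 4])
  attr(out, "which") <- which_t
  attr(out, "t_end") <- t_hit
  attr(out, "path_length") <- sum(sqrt(diff(traj[seq_len(row_hit), 2])^2 +
                                         diff(traj[seq_len(row_hit), 3])^2))
  class(out) <- c("wn_navtraj", "data.frame")
  out
}

#' Export a navigation trajectory with its run manifest
#'
#' Writes the trajectory CSV `(t, x, y, n_spikes_this_step)` and a JSON
#' manifest (seed, start, target, outcome, path length, and the oracle
#' geodesic length plus ratio when supplied).
#'
#' @param traj a [navigate()] result
#' @param path CSV output file; the manifest goes to `<path>.json`
#' @param oracle_length optional geodesic reference length
#' @export
write_navtraj <- function(traj, path, oracle_length = NULL) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  manifest <- list(seed = attr(traj, "seed"), start = attr(traj, "start"),
                   target = attr(traj, "target"),
                   outcome = attr(traj, "outcome"),
                   path_length = attr(traj, "path_length"))
  if (!is.null(oracle_length)) {
    manifest$oracle_length <- oracle_length
    manifest$ratio <- attr(traj, "path_length") / oracle_length
  }
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(traj)
}
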