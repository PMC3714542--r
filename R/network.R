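#' Place-cell network
#'
#' Bundles the place-field map, the synaptic weights, the model configuration
#' and the per-neuron dynamic state (membrane potential, adaptation current,
#' synaptic traces, inhibition current). The phase controller maps the three
#' behavioural phases onto the plasticity polarity `d` and the inhibition
#' gate:
#'
#' | phase      | d  | inhibition gate |
#' |------------|----|-----------------|
#' | `explore`  | +1 | on              |
#' | `plan`     | -1 | off             |
#' | `navigate` |  0 | on              |
#'
#' @param map a [assign_place_fields()] object
#' @param weights a `wn_weights`
#' @param config a [wn_config()]
#' @return a `wn_network`
#' @export
make_network <- function(map, weights, config = wn_config()) {
  stopifnot(inherits(map, "wn_map"), inherits(weights, "wn_weights"),
            map$n == weights$n)
  config <- validate_config(config)
  structure(
    list(map = map, weights = weights, config = config,
         state = fresh_state(map$n), phase = "plan",
         phase_log = data.frame(t = numeric(0), phase = character(0))),
    class = "wn_network")
}

fresh_state <- function(n) {
  list(u = numeric(n), ica = numeric(n), syn_trace = numeric(n), ie = 0)
}

#' Set the behavioural phase
#'
#' @param network a `wn_network`
#' @param phase `"explore"`, `"plan"` or `"navigate"`
#' @return the network with the phase (and thus STDP polarity and inhibition
#'   gate) switched; the transition is logged
#' @export
set_phase <- function(network, phase = c("plan", "explore", "navigate")) {
  phase <- match.arg(phase)
  network$phase <- phase
  network$phase_log <- rbind(network$phase_log,
                             data.frame(t = unclass(Sys.time()), phase = phase))
  network
}

phase_d <- function(phase) switch(phase, explore = 1L, plan = -1L, navigate = 0L)
phase_gate <- function(phase) switch(phase, explore = TRUE, plan = FALSE,
                                     navigate = TRUE)

#' Let the per-neuron state decay passively for a time gap
#'
#' Advances the network clock with no input: adaptation, synaptic traces and
#' the inhibition current decay by their exact exponentials. Used to study
#' when a region becomes excitable again after a wavefront passage.
#'
#' @param network a `wn_network`
#' @param gap time (s)
#' @export
decay_state <- function(network, gap) {
  cfg <- network$config
  st <- network$state
  st$ica <- st$ica * exp(-gap / cfg$neuron$tau_ca)
  st$syn_trace <- st$syn_trace * exp(-gap / cfg$neuron$tau_syn)
  st$ie <- st$ie * exp(-gap / cfg$inhibition$tau_e)
  st$u <- st$u * exp(-gap / (1e-3 * cfg$neuron$C_m * cfg$neuron$R_m))
  network$state <- st
  network
}

#' @export
print.wn_network <- function(x, ...) {
  cat(sprintf("<wn_network: %d cells, phase '%s', %d synapses>\n",
              x$map$n, x$phase, length(x$weights$W@x)))
  invisible(x)
}

# --- internal: marshal a network + options into the C++ integrator ---------
run_core <- function(network, env_index = 1, t_max,
                     mode = c("none", "agent", "path"),
                     term_mode = 0L, quiet_window = 0.05,
                     stop_pos = c(0, 0), stop_radius = 0,
                     pulses = NULL, forced = NULL,
                     agent = NULL, path = NULL, path_dt = 1,
                     noise_sd = NULL, sens_amp = 0, sens_sigma = NULL,
                     d = NULL, gate = NULL, record_spikes = TRUE) {
  mode <- match.arg(mode)
  cfg <- network$config
  map <- network$map
  w <- network$weights
  env <- map$envs[[env_index]]
  n <- map$n

  neuron <- cfg$neuron
  neuron$tau_m <- 1e-3 * neuron$C_m * neuron$R_m  # nF x MOhm = ms -> s
  if (!is.null(noise_sd)) neuron$noise_sd <- noise_sd

  d <- d %||% phase_d(network$phase)
  gate <- gate %||% phase_gate(network$phase)
  stdp <- cfg$stdp
  stdp$d <- as.integer(d)

  drive <- list(
    mode = switch(mode, none = 0L, agent = 1L, path = 2L),
    sens_amp = sens_amp, sens_sigma = sens_sigma %||% map$sigma[env_index],
    pulse_t0 = numeric(0), pulse_dur = numeric(0), pulse_amp = numeric(0),
    pulse_label = integer(0), pulse_members = list(),
    f_step = integer(0), f_id = integer(0), f_label = integer(0),
    path = matrix(0, 1, 2), path_dt = path_dt)
  if (!is.null(pulses)) {
    drive$pulse_t0 <- pulses$t0; drive$pulse_dur <- pulses$dur
    drive$pulse_amp <- pulses$amp; drive$pulse_label <- pulses$label
    drive$pulse_members <- pulses$members
  }
  if (!is.null(forced) && nrow(forced) > 0) {
    o <- order(forced$step)
    drive$f_step <- as.integer(forced$step[o])
    drive$f_id <- as.integer(forced$id[o]) - 1L
    drive$f_label <- as.integer(forced$label[o])
  }
  if (!is.null(path)) drive$path <- as.matrix(path)

  agentp <- agent %||% list(x0 = c(0, 0), v0 = c(0, 0), mass = 1, damping = 1,
                            a_F = 0, target = c(0, 0), capture_radius = 0,
                            record_every = 1L)

  ctrl <- list(t_max = t_max, term_mode = as.integer(term_mode),
               quiet_window = quiet_window, stop_pos = stop_pos,
               stop_radius = stop_radius,
               label_window = cfg$planner$label_window,
               runaway_limit = cfg$planner$runaway_factor * n,
               record_spikes = record_spikes)

  net <- list(n = n, Wi = w$W@i, Wp = w$W@p, Wx = w$W@x,
              Ti = w$Ti, Tp = w$Tp, Tmap = w$Tmap,
              cx = map$centers[[env_index]][, 1],
              cy = map$centers[[env_index]][, 2])

  res <- run_core_cpp(net, neuron, cfg$synapse, c(cfg$inhibition, gate = gate),
                      stdp, drive, agentp, ctrl, env$rings, network$state)

  # activity-independent decay a (< 0): applied over the epoch, toward the
  # baseline snapshot, only while plasticity is gated on (d != 0)
  if (d != 0 && cfg$stdp$a_decay < 0) {
    drift <- abs(cfg$stdp$a_decay) * res$t_end
    delta <- w$baseline - res$Wx
    res$Wx <- res$Wx + sign(delta) * pmin(abs(delta), drift)
  }
  res
}

# write the integrator result back into the network
absorb_result <- function(network, res) {
  network$weights$W@x <- res$Wx
  network$state <- list(u = res$u, ica = res$ica, syn_trace = res$syn_trace,
                        ie = res$ie)
  network
}
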