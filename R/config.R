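#' Model configuration
#'
#' Returns the full nested parameter set, with any element overridden by name.
#' Units: seconds, metres, nA, mV. The neuron defaults are the published
#' operating point of the model: membrane capacitance 1 nF, resistance
#' 20 MOhm (so tau_m = 20 ms), rest/reset 0 mV, threshold 10 mV, absolute
#' refractory period 2 ms, synaptic current decay 25 ms, Euler step 0.2 ms,
#' calcium-like adaptation time constant in the 1-5 s range, and background
#' current noise of standard deviation 5 nA (scenarios scale this down or off
#' for noiseless experiments).
#'
#' @param ... named overrides, e.g. `wn_config(neuron = list(tau_ca = 1))`
#' @return nested list of class `wn_config`
#' @export
wn_config <- function(...) {
  cfg <- list(
    neuron = list(
      dt = 2e-4, C_m = 1, R_m = 20, u_r = 0, threshold = 10,
      refractory = 2e-3, tau_ca = 2, dI_ca = 40, tau_syn = 25e-3,
      i_jump = 1, eps_active = 0.3, noise_sd = 5, syn_delay = 0),
    synapse = list(
      supralinear = TRUE, a_syn = 10, b_syn = 0.05,
      # linear-mode gain matched to the supralinear multiplier at the
      # typical front convergence (about half the in-degree active at once)
      lin_gain = 10 * tanh(0.05 * 4)),
    inhibition = list(tau_e = 0.1, a_e = 0.05, I_e0 = 0.2, gain = 0.5),
    stdp = list(
      A_ji = 1, A_ij = 0.5, tau_w = 0.02, eta = 0.4, a_decay = -0.001,
      w_min = 0, w_max = 2),
    exploration = list(
      speed = 0.5, persistence = NULL, duration = 2000, dt = 5e-3,
      tau_e = 0.1, window = 0.5, rate_max = 40, m = 12, w0 = 0.5,
      full_lif = FALSE),
    placefields = list(footprint = 35, jitter_frac = 0.15, amplitude = 1.2),
    planner = list(
      seed_radius = NULL, seed_amp = 30, seed_dur = 1e-3, min_seed_cells = 3,
      quiet_window = 0.05, label_window = 0.025, runaway_factor = 6,
      noise_sd = 0, t_max = 2),
    agent = list(
      mass = 1, damping = 5, a_F = 2, capture_radius = NULL,
      max_time = 30, record_every = 25, noise_sd = 0.25,
      tonic_amp = 1.6, stall_window = 12)
  )
  over <- list(...)
  for (grp in names(over)) {
    if (!grp %in% names(cfg)) stop("unknown config group: ", grp)
    for (nm in names(over[[grp]])) {
      if (!nm %in% names(cfg[[grp]]))
        stop("unknown config entry: ", grp, "$", nm)
      cfg[[grp]][[nm]] <- over[[grp]][[nm]]
    }
  }
  structure(cfg, class = "wn_config")
}

#' Validate and normalize a configuration
#'
#' Range-checks every parameter group, fills defaults for missing entries,
#' and returns the normalized configuration; all violations are reported
#' together.
#'
#' @param cfg a list or `wn_config`
#' @return validated `wn_config`
#' @export
validate_config <- function(cfg = list()) {
  cfg <- do.call(wn_config, unclass(cfg))
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  with(cfg$neuron, {
    chk(dt > 0, "neuron$dt must be > 0")
    chk(C_m > 0 && R_m > 0, "membrane constants must be > 0")
    chk(threshold > u_r, "threshold must exceed resting potential")
    chk(refractory >= 0, "refractory must be >= 0")
    chk(tau_ca > 0, "tau_ca must be > 0")
    chk(tau_syn > 0, "tau_syn must be > 0")
    chk(noise_sd >= 0, "noise_sd must be >= 0")
  })
  with(cfg$stdp, {
    chk(A_ji > A_ij && A_ij > 0, "STDP requires A_ji > A_ij > 0")
    chk(tau_w > 0, "tau_w must be > 0")
    chk(a_decay <= 0, "a_decay must be <= 0")
    chk(w_min <= w_max, "w_min must be <= w_max")
  })
  with(cfg$exploration, {
    chk(speed > 0, "exploration speed must be > 0")
    chk(m >= 4, "m must be >= 4 (2-D propagation needs convergent inputs)")
    chk(w0 > 0, "w0 must be > 0")
    chk(duration > 0, "exploration duration must be > 0")
  })
  with(cfg$inhibition, {
    chk(tau_e > 0 && a_e > 0, "inhibition constants must be > 0")
  })
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  cfg
}

#' @export
print.wn_config <- function(x, ...) {
  cat("<wn_config>\n")
  for (grp in names(x)) {
    vals <- vapply(x[[grp]], function(v)
      if (is.null(v)) "auto" else format(v, digits = 4), "")
    cat(sprintf("  %-12s %s\n", grp,
                paste(names(vals), vals, sep = "=", collapse = " ")))
  }
  invisible(x)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_along(utf8ToInt(as.character(s))) %% 97 + 1)) %% 4294967291)
}
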