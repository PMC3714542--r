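#' STDP pair kernel
#'
#' Unit weight change contributed by a single pre/post spike pair with signed
#' lag `s = t_pre - t_post`. The causal branch (`s <= 0`, presynaptic spike at
#' or before the postsynaptic one) returns `+A_ji * exp(s / tau_w)`; the
#' anti-causal branch (`s > 0`) returns `-A_ij * exp(-s / tau_w)`. The full
#' contribution to `dw_ji` is the polarity `d` times this value, so with
#' `d = -1` (anti-STDP, wavefront phase) causal synapses are weakened and
#' anti-causal ones strengthened: synapses pointing back toward the wavefront
#' source end up stronger, which is what makes the synaptic vector field point
#' at the source.
#'
#' @param s signed lag `t_pre - t_post` (s); the `s = 0` boundary belongs to
#'   the causal branch
#' @param cfg STDP config group (`A_ji`, `A_ij`, `tau_w`)
#' @return unit weight change (multiply by `d * eta` for the applied change)
#' @export
pair_kernel <- function(s, cfg = wn_config()$stdp) {
  ifelse(s <= 0, cfg$A_ji * exp(s / cfg$tau_w),
         -cfg$A_ij * exp(-s / cfg$tau_w))
}

#' Supralinear synaptic summation
#'
#' Total synaptic current
#' `i_syn = a_syn * tanh(b_syn * N) * sum_j w_j i_j`, where `N` counts inputs
#' with `i_j > 0`. Per-input efficacy grows with the number of simultaneously
#' active inputs until the tanh saturates, favouring cooperative wavefront
#' propagation over isolated (noise) spikes.
#'
#' @param i_j per-input synaptic currents (nA), non-negative
#' @param w_j synaptic weights
#' @param a_syn,b_syn positive constants
#' @return total current (nA)
#' @export
supralinear_sum <- function(i_j, w_j, a_syn = 10, b_syn = 0.05) {
  stopifnot(all(i_j >= 0))
  n_active <- sum(i_j > 0)
  a_syn * tanh(b_syn * n_active) * sum(w_j * i_j)
}

#' Single-neuron adaptive LIF reference integrator (pure R)
#'
#' A direct, scalar transliteration of the membrane and adaptation dynamics,
#' used as the fixed-point and closed-form oracle for the vectorized core.
#'
#' @param I_fun function of time returning the input current (nA)
#' @param t_max duration (s)
#' @param cfg neuron config group
#' @return data.frame `(t, u, ica)` plus spike times as attribute `spikes`
#' @export
lif_reference <- function(I_fun, t_max, cfg = wn_config()$neuron) {
  dt <- cfg$dt; tau_m <- 1e-3 * cfg$C_m * cfg$R_m  # nF x MOhm = ms -> s
  nstep <- round(t_max / dt)
  u <- 0; ica <- 0; refr <- 0
  us <- numeric(nstep); icas <- numeric(nstep); spikes <- numeric(0)
  for (s in seq_len(nstep)) {
    t <- (s - 1) * dt
    ica <- ica * exp(-dt / cfg$tau_ca)
    if (refr > 0) {
      refr <- refr - dt
      u <- cfg$u_r
    } else {
      u <- u + dt / tau_m * (-(u - cfg$u_r) + cfg$R_m * (I_fun(t) - ica))
      if (u >= cfg$threshold) {
        spikes <- c(spikes, t)
        u <- cfg$u_r; refr <- cfg$refractory; ica <- ica + cfg$dI_ca
      }
    }
    us[s] <- u; icas[s] <- ica
  }
  out <- data.frame(t = seq_len(nstep) * dt - dt, u = us, ica = icas)
  attr(out, "spikes") <- spikes
  out
}
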