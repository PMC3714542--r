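#' Simulate an exploratory trajectory
#'
#' A noisy straight line at constant speed whose heading decorrelates over
#' `persistence` metres of arc, with specular (mirror-law) bounces at walls.
#'
#' @param env a `wn_env`
#' @param cfg exploration config group (see [wn_config()]); `persistence =
#'   NULL` uses the largest dimension of the environment
#' @param seed integer seed
#' @param start starting position; default is the environment "centroid"
#'   (first interior grid point near the middle)
#' @return a `wn_traj`: data.frame `(t, x, y)` with attributes `seed`, `speed`
#' @export
explore_trajectory <- function(env, cfg = wn_config()$exploration, seed = 1,
                               start = NULL) {
  persistence <- cfg$persistence %||% max(env$bbox[2, ] - env$bbox[1, ])
  if (is.null(start)) start <- interior_point(env)
  if (!env_contains(env, rbind(start)))
    stop("starting point outside the environment")
  set.seed(derive_seed(seed, "explore_traj"))
  theta0 <- stats::runif(1, 0, 2 * pi)
  m <- explore_traj_cpp(env$rings, start[1], start[2], theta0,
                        cfg$speed, persistence, cfg$dt, cfg$duration)
  out <- data.frame(t = m[, 1], x = m[, 2], y = m[, 3])
  attr(out, "seed") <- seed
  attr(out, "speed") <- cfg$speed
  attr(out, "persistence") <- persistence
  class(out) <- c("wn_traj", "data.frame")
  out
}

interior_point <- function(env) {
  mid <- colMeans(env$bbox)
  if (env_contains(env, rbind(mid))) return(mid)
  g <- grid_points(env, min(env$bbox[2, ] - env$bbox[1, ]) / 25)
  g[which.min((g[, 1] - mid[1])^2 + (g[, 2] - mid[2])^2), ]
}

#' Place-cell spiking along a trajectory
#'
#' During exploration each cell emits Poisson spikes at a rate proportional to
#' its Gaussian sensory drive (`rate_max` at the field center). This
#' rate-proportional emitter is the default; `cfg$full_lif = TRUE` instead
#' drives the full integrate-and-fire population along the trajectory.
#'
#' @param traj a [explore_trajectory()] result
#' @param map a `wn_map`
#' @param env_index environment index
#' @param cfg exploration config group
#' @param seed integer seed
#' @return data.frame `(t, id)` of spike events, class `wn_spikes`
#' @export
exploration_spikes <- function(traj, map, env_index = 1,
                               cfg = wn_config()$exploration, seed = 1) {
  set.seed(derive_seed(seed, "explore_spikes"))
  ctr <- map$centers[[env_index]]
  sp <- explore_spikes_cpp(as.matrix(traj[, c("t", "x", "y")]),
                           ctr[, 1], ctr[, 2], map$sigma[env_index], cfg$rate_max)
  out <- data.frame(t = sp$t, id = sp$id)
  out <- out[order(out$t, out$id), ]
  rownames(out) <- NULL
  class(out) <- c("wn_spikes", "data.frame")
  out
}

#' Accumulate pairwise co-activation potential
#'
#' For every ordered cell pair, sums `exp(-|t_i - t_j| / tau_e)` over pre/post
#' spike pairs closer than `window`. Causal pairs (pre first) carry unit
#' amplitude and anti-causal pairs amplitude `rho`, the exploration-phase
#' (d = +1, net potentiation) reading of the plasticity rule; with extensive,
#' direction-agnostic exploration the matrix is symmetric in expectation.
#'
#' @param spikes a [exploration_spikes()] data.frame
#' @param n number of neurons
#' @param tau_e pair-weighting time constant (s); this is the exploration
#'   constant, distinct from the inhibition current constant
#' @param window maximum pair lag considered (s)
#' @param rho anti-causal relative amplitude
#' @return `n x n` matrix `P[i, j]` = potential of synapse i (pre) -> j (post)
#' @export
accumulate_pairs <- function(spikes, n, tau_e = 0.1, window = 0.5, rho = 0.5) {
  if (nrow(spikes) == 0) stop("no spikes recorded during exploration")
  o <- order(spikes$t)
  accumulate_pairs_cpp(spikes$t[o], as.integer(spikes$id[o]) - 1L,
                       as.integer(n), tau_e, window, rho)
}

#' Select the learned connectivity
#'
#' Every candidate synapse exists with weight zero ("fully connected,
#' initially silent"); this activates, for each postsynaptic cell, incoming
#' synapses of identical strength `w0` from the `m` presynaptic partners with
#' the largest accumulated potential. Rank ties are broken by neuron index.
#'
#' @param P pair potential from [accumulate_pairs()]
#' @param m in-degree kept per neuron
#' @param w0 baseline weight
#' @return a `wn_weights` object (sparse post x pre matrix plus the baseline
#'   snapshot used by [reset_synapses()])
#' @export
build_connectivity <- function(P, m, w0 = 0.5) {
  n <- nrow(P)
  pre <- integer(n * m); post <- integer(n * m)
  for (j in seq_len(n)) {
    inc <- P[, j]
    inc[j] <- -Inf
    top <- order(-inc, seq_len(n))[seq_len(m)]   # ties -> lower index
    pre[((j - 1) * m + 1):(j * m)] <- top
    post[((j - 1) * m + 1):(j * m)] <- j
  }
  make_weights(pre, post, w0, n)
}

#' Geometric m-nearest-neighbour connectivity
#'
#' The oracle-style constructor: each cell receives synapses from its `m`
#' nearest cells by Euclidean distance whose connecting segment does not cross
#' a wall. The exploration pipeline converges to (approximately) this matrix;
#' scenario presets use it directly for the planning and navigation phases.
#'
#' @param map a `wn_map`
#' @param env_index environment(s) whose geometry defines neighbourhoods; with
#'   several indices the per-environment matrices are summed (a neuron keeps
#'   `m` incoming partners per environment)
#' @param m in-degree per environment
#' @param w0 baseline weight
#' @return a `wn_weights`
#' @export
nearest_neighbour_connectivity <- function(map, env_index = 1, m = 12,
                                           w0 = 0.5) {
  n <- map$n
  Wsum <- NULL
  for (e in env_index) {
    ctr <- map$centers[[e]]
    env <- map$envs[[e]]
    pre <- integer(0); post <- integer(0)
    cand_k <- min(n - 1, 4 * m)
    for (j in seq_len(n)) {
      d2 <- (ctr[, 1] - ctr[j, 1])^2 + (ctr[, 2] - ctr[j, 2])^2
      d2[j] <- Inf
      cand <- order(d2, seq_len(n))[seq_len(cand_k)]
      segs <- cbind(ctr[cand, 1], ctr[cand, 2],
                    ctr[j, 1], ctr[j, 2])
      ok <- cand[!seg_cross_cpp(segs, env$rings)]
      take <- ok[seq_len(min(m, length(ok)))]
      pre <- c(pre, take); post <- c(post, rep(j, length(take)))
    }
    W <- Matrix::sparseMatrix(i = post, j = pre, x = w0, dims = c(n, n))
    Wsum <- if (is.null(Wsum)) W else Wsum + W
  }
  weights_from_matrix(Wsum)
}

#' Export a trajectory as CSV (t, x, y)
#' @param traj a `wn_traj`
#' @param path output file
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "x", "y")], path,
                   row.names = FALSE)
  invisible(traj)
}
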