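#' Graph-geodesic oracle
#'
#' Independent brute-force reference for the emergent behaviour of the
#' simulator: Dijkstra shortest paths on the place-cell connectivity graph,
#' with nodes at the field centers and edge lengths equal to the Euclidean
#' distance between connected centers (the baseline network has uniform
#' weights, so hop costs are purely geometric and a constant-speed front
#' should arrive in order of these distances).
#'
#' @param weights a `wn_weights` (edges taken from the symmetrized nonzero
#'   pattern)
#' @param map a `wn_map`
#' @param env_index environment index
#' @param sources source cell ids, or a `k x 2` matrix of points (each mapped
#'   to its nearest cell)
#' @return list with `dist` (per-neuron distance to the nearest source, using
#'   the per-source minimum), `dist_each` (`n x k`), `descent` (`n x 2` unit
#'   step direction toward the nearest source along the graph), `sources`
#' @export
geodesic_distances <- function(weights, map, env_index = 1, sources,
                               local_radius = NULL) {
  ctr <- map$centers[[env_index]]
  n <- map$n
  if (is.matrix(sources) || (is.numeric(sources) && length(sources) == 2 && any(sources %% 1 != 0))) {
    pts <- matrix(sources, ncol = 2)
    sources <- apply(pts, 1, function(p)
      which.min((ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2))
  }
  # edges longer than the local radius in these coordinates belong to another
  # stored map (cross-map shortcuts) and do not carry the front here
  local_radius <- local_radius %||% (3 * map$sigma[env_index])
  g <- connectivity_graph(weights, ctr, local_radius)
  dm <- igraph::distances(g, v = sources, algorithm = "dijkstra")
  dist_each <- t(dm)
  dist <- apply(dist_each, 1, min)

  # descent direction: toward the graph neighbour with the smallest distance
  adj <- igraph::as_adj_list(g, mode = "all")
  descent <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    nb <- as.integer(adj[[i]])
    if (!length(nb) || !is.finite(dist[i]) || dist[i] == 0) next
    b <- nb[which.min(dist[nb])]
    if (dist[b] < dist[i]) {
      d <- ctr[b, ] - ctr[i, ]
      descent[i, ] <- d / sqrt(sum(d^2))
    }
  }
  list(dist = dist, dist_each = dist_each, descent = descent,
       sources = sources, unreachable = which(!is.finite(dist)))
}

connectivity_graph <- function(weights, ctr, local_radius = Inf) {
  W <- weights$W
  S <- W + Matrix::t(W)
  S <- methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix")
  pre <- rep(seq_len(nrow(S)), diff(S@p))
  post <- S@i + 1L
  keep <- pre < post & S@x > 0
  e <- cbind(pre[keep], post[keep])
  len <- sqrt((ctr[e[, 1], 1] - ctr[e[, 2], 1])^2 +
                (ctr[e[, 1], 2] - ctr[e[, 2], 2])^2)
  e <- e[len <= local_radius, , drop = FALSE]
  len <- len[len <= local_radius]
  g <- igraph::make_empty_graph(n = nrow(S), directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  igraph::E(g)$weight <- len
  g
}

#' Geodesic Voronoi partition over targets
#'
#' Labels every cell with the target reaching it first:
#' `argmin_k (dist_k + offset_k)`; ties are broken to the lowest `k` and
#' flagged. Offsets convert reward-derived initiation delays into distance
#' head starts (`offset_k = v * delay_k`).
#'
#' @param oracle a [geodesic_distances()] result computed with one source per
#'   target
#' @param offsets per-target distance offsets (default none)
#' @return list with integer `label` per cell and `ties`
#' @export
geodesic_voronoi <- function(oracle, offsets = NULL) {
  k <- ncol(oracle$dist_each)
  offsets <- offsets %||% rep(0, k)
  eff <- sweep(oracle$dist_each, 2, offsets, `+`)
  label <- apply(eff, 1, which.min)
  sorted <- t(apply(eff, 1, sort))
  ties <- which(k > 1 & abs(sorted[, 1] - sorted[, 2]) < 1e-12)
  list(label = as.integer(label), ties = ties)
}

#' All-pairs evaluation of the STDP rule
#'
#' Exact double-sum evaluation of the pair-based plasticity over a (small)
#' spike record: for every synapse and every pre/post spike pair, adds
#' `d * eta * pair_kernel(t_pre - t_post)`. Used as the independent oracle
#' for the online trace implementation, which must agree to floating-point
#' accuracy for exponential kernels.
#'
#' @param spikes data.frame `(t, id)`
#' @param synapses data.frame `(pre, post)` of synapses to evaluate
#' @param cfg STDP config group
#' @param d polarity
#' @param eta learning-rate scale
#' @return per-synapse weight change (same order as `synapses`)
#' @export
allpairs_stdp <- function(spikes, synapses, cfg = wn_config()$stdp,
                          d = -1, eta = cfg$eta) {
  if (nrow(spikes) > 1e4) stop("all-pairs oracle is for small records")
  byid <- split(spikes$t, spikes$id)
  vapply(seq_len(nrow(synapses)), function(r) {
    tp <- byid[[as.character(synapses$pre[r])]]
    tq <- byid[[as.character(synapses$post[r])]]
    if (is.null(tp) || is.null(tq)) return(0)
    s <- outer(tp, tq, `-`)        # t_pre - t_post
    sum(d * eta * pair_kernel(s, cfg))
  }, 0)
}
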