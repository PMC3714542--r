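# Shared fixtures, built lazily and memoised for the test session.

.fix <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# small open-arena network with a completed wavefront from (0.8, 0.8)
open_front <- function() fixture("open_front", function() {
  env <- make_environment("open")
  map <- assign_place_fields(env, n_cells = 900, seed = 2)
  w <- nearest_neighbour_connectivity(map, 1)
  net <- make_network(map, w)
  tgt <- c(0.8, 0.8)
  fr <- run_planning(net, target_set(rbind(tgt)), seed = 1)
  orc <- geodesic_distances(w, map, 1, rbind(tgt))
  list(env = env, map = map, w = w, net = net, tgt = tgt, fr = fr, orc = orc)
})

# small T-maze network with a completed wavefront in the left arm
tmaze_front <- function() fixture("tmaze_front", function() {
  env <- make_environment("T")
  map <- assign_place_fields(env, n_cells = 900, seed = 2)
  w <- nearest_neighbour_connectivity(map, 1)
  net <- make_network(map, w)
  tgt <- c(0.15, 0.85)
  fr <- run_planning(net, target_set(rbind(tgt)), seed = 1)
  orc <- geodesic_distances(w, map, 1, rbind(tgt))
  list(env = env, map = map, w = w, net = net, tgt = tgt, fr = fr, orc = orc)
})

# tiny network with scripted (forced) spikes and no synaptic drive, for
# plasticity-oracle comparisons
scripted_net <- function(n = 30, seed = 7) {
  set.seed(seed)
  env <- make_environment("open")
  map <- suppressWarnings(assign_place_fields(env, n_cells = n, seed = seed))
  pairs <- expand.grid(pre = seq_len(n), post = seq_len(n))
  pairs <- pairs[pairs$pre != pairs$post, ]
  pairs <- pairs[sample.int(nrow(pairs), 4 * n), ]
  w <- wavenav:::make_weights(pairs$pre, pairs$post, 0.5, n)
  cfg <- wn_config(synapse = list(a_syn = 0),   # no endogenous spiking
                   stdp = list(eta = 0.01, a_decay = 0),
                   neuron = list(noise_sd = 0))
  net <- make_network(map, w, cfg)
  list(net = net, map = map, w = w, pairs = pairs)
}

jaccard_sets <- function(a, b)
  mapply(function(x, y) length(intersect(x, y)) / length(union(x, y)), a, b)
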