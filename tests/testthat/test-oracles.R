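test_that("Dijkstra distances match exhaustive path enumeration on a toy graph", {
  # 5 nodes placed so edge lengths are the printed values
  ctr <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(2, 0.5))
  pre <-  c(1, 2, 2, 3, 4, 3)
  post <- c(2, 3, 5, 5, 1, 4)
  w <- wavenav:::make_weights(c(pre, post), c(post, pre), 1, 5)
  map <- structure(list(centers = list(ctr), sigma = Inf, amplitude = 1,
                        pitch = 1, n = 5, n_envs = 1,
                        envs = list(make_environment("open", 2)), seed = 1),
                   class = "wn_map")
  orc <- geodesic_distances(w, map, 1, sources = 1L, local_radius = Inf)
  # brute force: enumerate all simple paths from node 1
  len <- function(p) sum(sqrt(rowSums((ctr[p[-1], , drop = FALSE] -
                                         ctr[p[-length(p)], , drop = FALSE])^2)))
  edges <- cbind(c(pre, post), c(post, pre))
  best <- rep(Inf, 5); best[1] <- 0
  stack <- list(1L)
  while (length(stack)) {
    p <- stack[[1]]; stack <- stack[-1]
    for (nb in edges[edges[, 1] == p[length(p)], 2]) {
      if (nb %in% p) next
      q <- c(p, nb)
      best[nb] <- min(best[nb], len(q))
      stack <- c(stack, list(q))
    }
  }
  expect_equal(orc$dist, best, tolerance = 1e-12)
})

test_that("corridor geodesics are Euclidean; cross-arm routes pass the junction", {
  f <- tmaze_front()
  ctr <- f$map$centers[[1]]
  stem <- which(ctr[, 2] < 0.6 & abs(ctr[, 1] - 0.5) < 0.1)
  src <- stem[which.max(ctr[stem, 2])]
  orc <- geodesic_distances(f$w, f$map, 1, sources = src)
  euc <- sqrt(rowSums((ctr[stem, ] - matrix(ctr[src, ], length(stem), 2,
                                            byrow = TRUE))^2))
  expect_lt(stats::median(abs(orc$dist[stem] - euc)), 1.5 * f$map$pitch[1])

  # left-arm to right-arm distance includes the junction detour
  left <- which(ctr[, 1] < 0.1 & ctr[, 2] > 0.8)[1]
  right <- which(ctr[, 1] > 0.9 & ctr[, 2] > 0.8)[1]
  orcL <- geodesic_distances(f$w, f$map, 1, sources = left)
  expect_gt(orcL$dist[right],
            sqrt(sum((ctr[left, ] - ctr[right, ])^2)) - 1e-9)
})

test_that("geodesic Voronoi labels nearest targets and reacts to offsets", {
  f <- open_front()
  locs <- rbind(c(0.25, 0.5), c(0.75, 0.5))
  orc <- geodesic_distances(f$w, f$map, 1, locs)
  vor <- geodesic_voronoi(orc)
  ctr <- f$map$centers[[1]]
  # single target: trivial labelling
  one <- geodesic_voronoi(geodesic_distances(f$w, f$map, 1, locs[1, , drop = FALSE]))
  expect_true(all(one$label == 1L))
  # equal targets: the boundary tracks the perpendicular bisector
  away <- abs(ctr[, 1] - 0.5) > 2 * f$map$pitch[1]
  expect_true(all((vor$label == 1L)[away] == (ctr[away, 1] < 0.5)))
  # a head start for target 2 moves the boundary toward target 1
  vor2 <- geodesic_voronoi(orc, offsets = c(0, -0.2))
  expect_gt(sum(vor2$label == 2L), sum(vor$label == 2L))
  expect_true(all(vor2$label[vor$label == 2L] == 2L))
})

test_that("the all-pairs plasticity oracle handles edge cases exactly", {
  cfg <- wn_config()$stdp
  syn <- data.frame(pre = 1L, post = 2L)
  one <- data.frame(t = c(0.010, 0.013), id = c(1L, 2L))   # causal pair
  expect_equal(allpairs_stdp(one, syn, cfg, d = -1, eta = 1),
               -1 * pair_kernel(-0.003, cfg))
  none <- data.frame(t = numeric(0), id = integer(0))
  expect_equal(allpairs_stdp(none, syn, cfg), 0)
})
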