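make_cfg <- function(...) wn_config(exploration = list(...))$exploration

test_that("trajectory stays inside, keeps constant speed, reflects specularly", {
  env <- make_environment("open")
  cfg <- make_cfg(duration = 120)
  traj <- explore_trajectory(env, cfg, seed = 3)
  expect_true(all(env_contains(env, as.matrix(traj[, c("x", "y")]))))
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  expect_lt(max(abs(step - cfg$speed * cfg$dt)), 1e-9)

  # zero heading noise: specular bounces on an axis-aligned box only flip
  # velocity-component signs, so |vx| and |vy| are conserved throughout
  cfg0 <- make_cfg(duration = 60, persistence = 1e12)
  tr0 <- explore_trajectory(env, cfg0, seed = 5)
  vx <- abs(diff(tr0$x)); vy <- abs(diff(tr0$y))
  expect_lt(diff(range(vx)), 1e-6)
  expect_lt(diff(range(vy)), 1e-6)
  # and at least one bounce happened (sign changes)
  expect_gt(sum(abs(diff(sign(diff(tr0$x))))), 0)
})

test_that("a long run covers all three arms of the T maze", {
  env <- make_environment("T")
  traj <- explore_trajectory(env, make_cfg(duration = 400), seed = 1)
  pts <- as.matrix(traj[, c("x", "y")])
  arms <- list(left = pts[, 1] < 0.2 & pts[, 2] > 0.7,
               right = pts[, 1] > 0.8 & pts[, 2] > 0.7,
               stem = pts[, 2] < 0.2)
  expect_true(all(vapply(arms, any, TRUE)))
})

test_that("heading direction decorrelates over about one persistence length", {
  env <- make_environment("open", side = 50)   # large box: few bounces
  cfg <- make_cfg(duration = 2000, persistence = 2)
  traj <- explore_trajectory(env, cfg, seed = 8)
  th <- atan2(diff(traj$y), diff(traj$x))
  arc_lag <- round(cfg$persistence / (cfg$speed * cfg$dt))
  n <- length(th) - arc_lag
  ac <- mean(cos(th[seq_len(n) + arc_lag] - th[seq_len(n)]))
  expect_gt(ac, exp(-1) - 0.12)
  expect_lt(ac, exp(-1) + 0.12)
})

test_that("pair accumulation weights lags exponentially and needs spikes", {
  sp <- data.frame(t = c(0.1, 0.1, 0.25), id = c(1L, 2L, 3L))
  P <- accumulate_pairs(sp, n = 3, tau_e = 0.1, window = 0.5, rho = 0.5)
  expect_equal(P[1, 2], 1)               # simultaneous pair: weight exp(0)
  expect_equal(P[2, 1], 1)
  expect_equal(P[1, 3], exp(-0.15 / 0.1))           # causal branch
  expect_equal(P[3, 1], 0.5 * exp(-0.15 / 0.1))     # anti-causal, rho
  far <- data.frame(t = c(0, 10), id = c(1L, 2L))
  expect_equal(max(accumulate_pairs(far, 2, 0.1, 0.5)), 0)
  expect_error(accumulate_pairs(sp[0, ], 3), "no spikes")
})

test_that("co-activation statistics are near-symmetric after long exploration", {
  env <- make_environment("open")
  map <- assign_place_fields(env, n_cells = 400, seed = 2)
  cfg <- make_cfg(duration = 400)
  traj <- explore_trajectory(env, cfg, seed = 2)
  sp <- exploration_spikes(traj, map, 1, cfg, seed = 3)
  P <- accumulate_pairs(sp, map$n, cfg$tau_e, cfg$window)
  tot <- P + t(P)
  strong <- tot > stats::quantile(tot[tot > 0], 0.5)
  asym <- abs(P - t(P)) / tot
  expect_lt(stats::median(asym[strong]), 0.2)
})

test_that("top-m selection gives uniform in-degree with index tie-breaks", {
  # 1-D chain co-activation: m = 1 connects each cell to a nearest neighbour
  x <- seq(0, 1, length.out = 11)
  P <- outer(x, x, function(a, b) exp(-abs(a - b) * 20))
  diag(P) <- 0
  w <- build_connectivity(P, m = 1, w0 = 0.5)
  inc <- incoming_sets(w)
  expect_true(all(lengths(inc) == 1))
  for (j in 2:10) expect_true(inc[[j]] %in% c(j - 1, j + 1))
  # exact ties resolve to the lower neuron index
  Pt <- matrix(1, 3, 3); diag(Pt) <- 0
  wt <- build_connectivity(Pt, m = 1, w0 = 1)
  expect_equal(unlist(incoming_sets(wt)[2:3], use.names = FALSE), c(1L, 1L))
})

test_that("halving the pair time constant barely changes the selected sets", {
  env <- make_environment("open")
  map <- assign_place_fields(env, n_cells = 400, seed = 2)
  cfg <- make_cfg(duration = 600)
  traj <- explore_trajectory(env, cfg, seed = 4)
  sp <- exploration_spikes(traj, map, 1, cfg, seed = 5)
  w1 <- build_connectivity(accumulate_pairs(sp, map$n, 0.1, 0.5), m = 12)
  w2 <- build_connectivity(accumulate_pairs(sp, map$n, 0.05, 0.5), m = 12)
  jac <- mean(jaccard_sets(incoming_sets(w1), incoming_sets(w2)))
  expect_gt(jac, 0.9)   # insensitive to the weighting details
})

test_that("learned synapses do not link cells across walls", {
  env <- make_environment("T")
  map <- assign_place_fields(env, n_cells = 500, seed = 2)
  cfg <- make_cfg(duration = 600)
  traj <- explore_trajectory(env, cfg, seed = 6)
  sp <- exploration_spikes(traj, map, 1, cfg, seed = 7)
  w <- build_connectivity(accumulate_pairs(sp, map$n, cfg$tau_e, cfg$window),
                          m = cfg$m)
  ctr <- map$centers[[1]]
  W <- w$W
  pre <- rep(seq_len(map$n), diff(W@p)); post <- W@i + 1L
  # cells joined by a synapse must be geodesically close: Euclidean-close
  # pairs on opposite sides of the bar/stem walls are excluded
  orc_graph <- nearest_neighbour_connectivity(map, 1, m = 16)
  blocked <- env_blocked(env, cbind(ctr[pre, ], ctr[post, ]))
  euc <- sqrt(rowSums((ctr[pre, ] - ctr[post, ])^2))
  # any wall-crossing synapse must hug a corner (short detour), never span
  # a genuine barrier
  expect_true(all(euc[blocked] < 4 * map$sigma[1]))
  expect_lt(mean(blocked), 0.01)
})
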