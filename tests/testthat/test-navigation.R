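test_that("spike forces are sums of instantaneous attractions", {
  f <- open_front()
  expect_equal(spike_force(integer(0), f$map, 1, c(0.5, 0.5)), c(0, 0))
  ctr <- f$map$centers[[1]]
  north <- which.max(ctr[, 2] * (abs(ctr[, 1] - 0.5) < 0.05))
  F1 <- spike_force(north, f$map, 1, c(ctr[north, 1], 0.2), a_F = 2)
  expect_equal(F1[1], 0, tolerance = 1e-12)
  expect_equal(F1[2], as.numeric(2 * (ctr[north, 2] - 0.2)))
  # two spikes symmetric about the agent cancel
  mapS <- f$map
  mapS$centers[[1]][1, ] <- c(0.4, 0.5)
  mapS$centers[[1]][2, ] <- c(0.6, 0.5)
  expect_equal(spike_force(c(1, 2), mapS, 1, c(0.5, 0.5)), c(0, 0))
})

test_that("with no spikes the agent coasts with exponential velocity decay", {
  f <- open_front()
  cfg <- f$net$config
  net <- set_phase(f$net, "navigate")
  agent <- list(x0 = c(0.2, 0.5), v0 = c(0.3, 0), mass = cfg$agent$mass,
                damping = cfg$agent$damping, a_F = 0, target = c(2, 2),
                capture_radius = 0, record_every = 25L)
  res <- wavenav:::run_core(net, 1, t_max = 0.5, mode = "agent",
                            term_mode = 0L, quiet_window = 10,
                            agent = agent, noise_sd = 0, sens_amp = 0)
  tr <- res$agent_traj
  tau <- cfg$agent$mass / cfg$agent$damping
  # x(t) = x0 + v0 * tau * (1 - exp(-t/tau))
  expected <- 0.2 + 0.3 * tau * (1 - exp(-tr[, 1] / tau))
  expect_equal(tr[, 2], expected, tolerance = 0.01)
  expect_equal(tr[, 3], rep(0.5, nrow(tr)), tolerance = 1e-9)
})

test_that("navigation follows the field to the target and freezes weights", {
  f <- tmaze_front()
  w_before <- f$fr$network$weights$W@x
  tr <- navigate(f$fr$network, start = c(0.5, 0.1), target = f$tgt, seed = 2)
  expect_identical(f$fr$network$weights$W@x, w_before)
  expect_equal(attr(tr, "outcome"), "reached")
  # the whole trajectory stays inside the maze
  expect_true(all(env_contains(f$env, as.matrix(tr[, c("x", "y")]))))
  # macroscopically near-shortest (single stochastic run; the distribution
  # of the ratio over many runs is checked in the acceptance suite)
  ctr <- f$map$centers[[1]]
  iT <- which.min((ctr[, 1] - f$tgt[1])^2 + (ctr[, 2] - f$tgt[2])^2)
  orcS <- geodesic_distances(f$w, f$map, 1, rbind(c(0.5, 0.1)))
  expect_lt(attr(tr, "path_length") / orcS$dist[iT], 2)
})

test_that("distinct seeds give distinct paths but the same macroscopic route", {
  f <- tmaze_front()
  trs <- lapply(1:3, function(s)
    navigate(f$fr$network, c(0.5, 0.1), f$tgt, seed = s))
  expect_true(all(vapply(trs, function(t) attr(t, "outcome"), "") == "reached"))
  # paths differ in detail
  expect_false(identical(trs[[1]]$x, trs[[2]]$x))
  # but none wanders into the right arm (wrong macroscopic branch)
  for (t in trs) expect_lt(max(t$x), 0.75)
})

test_that("an agent started at the target stays near it", {
  f <- open_front()
  ok <- vapply(1:5, function(s) {
    tr <- navigate(f$fr$network, f$tgt, f$tgt, max_time = 5, seed = s)
    d <- sqrt((tr$x - f$tgt[1])^2 + (tr$y - f$tgt[2])^2)
    max(d) < 4 * f$map$sigma[1]
  }, TRUE)
  expect_gte(mean(ok), 0.8)
})

test_that("a mid-run displacement still ends at the same target", {
  f <- tmaze_front()
  # displace the start laterally by 2 sigma relative to the stem route
  shift <- 2 * f$map$sigma[1]
  ok <- vapply(1:5, function(s) {
    tr <- navigate(f$fr$network, c(0.5 + shift, 0.25), f$tgt, seed = s)
    attr(tr, "outcome") == "reached"
  }, TRUE)
  expect_gte(mean(ok), 0.8)
})
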