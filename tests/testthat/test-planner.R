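cells_near_pos <- function(map, pos, radius) {
  ctr <- map$centers[[1]]
  which((ctr[, 1] - pos[1])^2 + (ctr[, 2] - pos[2])^2 <= radius^2)
}

test_that("exciter seeding recruits a small cluster that fires promptly", {
  f <- open_front()
  ps <- seed_wavefront(f$net, target_set(rbind(c(0.5, 0.5))))
  expect_gte(length(ps$members[[1]]), 5)
  expect_lte(length(ps$members[[1]]), 15)

  # seeded cells fire within 2 ms of the pulse onset
  sp <- f$fr$spikes
  seeded <- seed_wavefront(f$net, target_set(rbind(f$tgt)))$members[[1]] + 1L
  t_first <- vapply(seeded, function(i) min(sp$t[sp$id == i]), 0)
  expect_true(all(t_first <= 0.002))

  # a too-small footprint is rejected before simulation
  expect_error(seed_wavefront(f$net, target_set(rbind(c(0.5, 0.5))),
                              radius = 1e-4), "too few")
})

test_that("a single isolated spike does not launch a wavefront", {
  f <- open_front()
  net <- set_phase(f$net, "plan")
  mid <- which.min(rowSums((f$map$centers[[1]] -
                              matrix(0.5, f$map$n, 2))^2))
  forced <- data.frame(step = 10L, id = mid, label = 1L)
  res <- wavenav:::run_core(net, 1, t_max = 0.3, mode = "none",
                            term_mode = 1L, forced = forced, noise_sd = 0)
  expect_lt(res$total_spikes, 5)   # below the cooperative threshold
})

test_that("reward differentials convert to initiation delays", {
  tg <- target_set(rbind(c(0.2, 0.2), c(0.8, 0.8)), rewards = c(2, 1),
                   cost_rate = 1)
  expect_equal(reward_to_delays(tg, v = 1), c(0, 1))
  tg_eq <- target_set(rbind(c(0.2, 0.2), c(0.8, 0.8)))
  expect_equal(reward_to_delays(tg_eq, v = 3), c(0, 0))
  expect_error(reward_to_delays(tg, v = 0), "positive")
  expect_error(target_set(rbind(c(0, 0)), rewards = -1))
})

test_that("noise injection is a seeded Poisson stream of labelled events", {
  s1 <- inject_noise_spikes(200, rate = 3, t_max = 2, seed = 4)
  s2 <- inject_noise_spikes(200, rate = 3, t_max = 2, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1$label == 0L))
  expect_lt(abs(nrow(s1) - 3 * 200 * 2), 4 * sqrt(3 * 200 * 2))
  expect_equal(nrow(inject_noise_spikes(200, 0, 2)), 0)
})

test_that("planning without noise is reproducible and label-complete", {
  f <- open_front()
  fr <- f$fr
  expect_equal(fr$coverage, 1, tolerance = 0.01)
  expect_equal(fr$multi_fire, 0)
  # every fired cell carries the seed's source label
  fired <- fr$n_spikes > 0
  expect_true(all(fr$source_label[fired] == 1L))
  # deterministic re-run
  fr2 <- run_planning(f$net, target_set(rbind(f$tgt)), seed = 1)
  expect_identical(fr2$spikes, fr$spikes)
})

test_that("planning halts when the front reaches the agent's place cells", {
  f <- open_front()
  agent_pos <- c(0.15, 0.15)
  fr <- run_planning(f$net, target_set(rbind(f$tgt)), agent_pos = agent_pos,
                     seed = 1)
  expect_equal(fr$outcome, "agent_reached")
  expect_lt(fr$coverage, 1)     # distal cells beyond the agent never fired
  # cells near the agent fired just before termination
  near <- cells_near_pos(f$map, agent_pos, f$map$sigma[1])
  expect_true(any(is.finite(fr$first_spike[near])))
})

test_that("runaway activity triggers the population guard", {
  f <- open_front()
  cfg <- f$net$config
  cfg$neuron$dI_ca <- 0    # no adaptation: the front re-ignites forever
  net <- make_network(f$map, f$w, cfg)
  expect_error(run_planning(net, target_set(rbind(c(0.5, 0.5))), seed = 1),
               "runaway")
})

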