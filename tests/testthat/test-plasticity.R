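test_that("the pair kernel has the stated branches and boundary", {
  cfg <- wn_config()$stdp
  expect_equal(pair_kernel(0, cfg), cfg$A_ji)            # s = 0 is causal
  expect_equal(pair_kernel(-cfg$tau_w, cfg), cfg$A_ji / exp(1))
  expect_equal(pair_kernel(cfg$tau_w, cfg), -cfg$A_ij / exp(1))
  # with d = -1 a causal pair weakens and an anti-causal pair strengthens
  expect_lt(-1 * pair_kernel(-0.005, cfg), 0)
  expect_gt(-1 * pair_kernel(+0.005, cfg), 0)
})

test_that("online trace plasticity equals the all-pairs evaluation", {
  sn <- scripted_net(n = 30, seed = 7)
  net <- set_phase(sn$net, "plan")
  # scripted random spikes, no endogenous drive
  set.seed(11)
  nf <- 120
  forced <- data.frame(step = sort(sample.int(1000, nf)),
                       id = sample.int(30, nf, replace = TRUE), label = 1L)
  res <- wavenav:::run_core(net, 1, t_max = 0.25, mode = "none",
                            term_mode = 0L, forced = forced, noise_sd = 0)
  rec <- data.frame(t = res$spike_t, id = res$spike_id)
  expect_gt(nrow(rec), 80)
  oracle <- allpairs_stdp(rec, sn$pairs, net$config$stdp, d = -1,
                          eta = net$config$stdp$eta)
  got <- res$Wx - net$weights$W@x
  # align oracle (pre, post) order with the sparse storage order
  W <- net$weights$W
  key_store <- paste(rep(seq_len(30), diff(W@p)), W@i + 1L)
  key_oracle <- paste(sn$pairs$pre, sn$pairs$post)
  oracle_aligned <- oracle[match(key_store, key_oracle)]
  expect_lt(max(abs(got - oracle_aligned)) / max(abs(oracle_aligned)), 1e-9)
})

test_that("plasticity is off during movement execution (d = 0)", {
  sn <- scripted_net(n = 20, seed = 3)
  net <- set_phase(sn$net, "navigate")
  forced <- data.frame(step = seq(10, 400, by = 10),
                       id = rep(1:20, 2), label = 1L)
  res <- wavenav:::run_core(net, 1, t_max = 0.1, mode = "none",
                            term_mode = 0L, forced = forced, noise_sd = 0)
  expect_identical(res$Wx, net$weights$W@x)
})

test_that("a passing 1-D wavefront under anti-STDP strengthens toward-source synapses", {
  run_chain <- function(rightward) {
    n <- 20
    env <- make_environment("open")
    map <- suppressWarnings(assign_place_fields(env, n_cells = n, seed = 2))
    map$centers[[1]] <- cbind(seq(0.05, 0.95, length.out = n), 0.5)
    pre <- c(seq_len(n - 1), seq(2, n))
    post <- c(seq(2, n), seq_len(n - 1))
    w <- wavenav:::make_weights(pre, post, 0.5, n)
    cfg <- wn_config(synapse = list(a_syn = 0), stdp = list(a_decay = 0),
                     neuron = list(noise_sd = 0))
    net <- set_phase(make_network(map, w, cfg), "plan")
    ids <- if (rightward) seq_len(n) else rev(seq_len(n))
    forced <- data.frame(step = seq(0, by = 15, length.out = n),  # 3 ms hops
                         id = ids, label = 1L)
    res <- wavenav:::run_core(net, 1, t_max = 0.12, mode = "none",
                              term_mode = 0L, forced = forced, noise_sd = 0)
    W2 <- net$weights$W
    W2@x <- res$Wx
    W2
  }
  WR <- run_chain(TRUE)
  for (k in 2:19) {
    # rightward-moving front: leftward (toward-source) synapse k -> k-1
    # ends stronger than its rightward partner k-1 -> k
    expect_gt(WR[k - 1, k], WR[k, k - 1])
  }
  # mirrored front mirrors the asymmetry on every pair
  WL <- run_chain(FALSE)
  asymR <- as.matrix(WR - Matrix::t(WR))
  asymL <- as.matrix(WL - Matrix::t(WL))
  expect_equal(asymR[upper.tri(asymR)], -asymL[upper.tri(asymL)],
               tolerance = 1e-10)
})

test_that("without spikes, weights drift toward baseline at rate |a_decay|", {
  sn <- scripted_net(n = 20, seed = 5)
  cfg <- sn$net$config
  cfg$stdp$a_decay <- -0.01
  net <- make_network(sn$map, sn$w, cfg)
  # displace weights above baseline, then run an empty plan epoch
  net$weights$W@x <- net$weights$W@x + 0.005
  net <- set_phase(net, "plan")
  res <- wavenav:::run_core(net, 1, t_max = 0.2, mode = "none",
                            term_mode = 0L, noise_sd = 0)
  drift <- 0.01 * res$t_end
  expect_equal(res$Wx, net$weights$baseline + 0.005 - drift, tolerance = 1e-9)
})

test_that("resetting synapses restores the baseline and zeroes the field", {
  f <- open_front()
  w_after <- f$fr$network$weights
  expect_gt(max(abs(w_after$W@x - w_after$baseline)), 0.01)
  w_reset <- reset_synapses(w_after)
  expect_identical(w_reset$W@x, w_reset$baseline)
  field <- compute_svf(w_reset, f$map, 1)
  expect_equal(max(abs(c(field$dx, field$dy))), 0)
})

test_that("clipping stays inactive in the standard wavefront regime", {
  f <- open_front()
  cfg <- f$net$config$stdp
  x <- f$fr$network$weights$W@x
  expect_gt(min(x), cfg$w_min)
  expect_lt(max(x), cfg$w_max)
})
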