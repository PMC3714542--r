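test_that("supralinear summation matches its closed form and favours crowds", {
  expect_equal(supralinear_sum(numeric(0), numeric(0)), 0)
  expect_equal(supralinear_sum(1, 1, a_syn = 10, b_syn = 0.05),
               10 * tanh(0.05), tolerance = 1e-12)
  expect_equal(supralinear_sum(rep(1, 20), rep(1, 20), 10, 0.05),
               10 * tanh(1) * 20, tolerance = 1e-12)
  # per-input efficacy strictly increases with the number of active inputs
  eff <- vapply(1:30, function(k)
    supralinear_sum(rep(1, k), rep(1, k), 10, 0.05) / k, 0)
  expect_true(all(diff(eff) > 0))
})

test_that("subthreshold drive settles at u = u_r + R_m * I without spiking", {
  ref <- lif_reference(function(t) 0.4, t_max = 0.3)   # R_m * I = 8 mV
  expect_length(attr(ref, "spikes"), 0)
  expect_equal(utils::tail(ref$u, 1), 8, tolerance = 1e-3)
})

test_that("adaptation current follows its single-spike exponential decay", {
  cfg <- wn_config(neuron = list(noise_sd = 0))$neuron
  ref <- lif_reference(function(t) if (t < 0.005) 30 else 0, t_max = 1, cfg)
  sp <- attr(ref, "spikes")
  expect_length(sp, 1)
  after <- ref$t > sp[1] + 0.01
  expected <- cfg$dI_ca * exp(-(ref$t[after] - sp[1]) / cfg$tau_ca)
  expect_equal(ref$ica[after], expected, tolerance = 1e-6)
})

test_that("sustained drive shows spike-frequency adaptation", {
  cfg <- wn_config(neuron = list(noise_sd = 0, dI_ca = 0.3, tau_ca = 2))$neuron
  ref <- lif_reference(function(t) 1.5, t_max = 8, cfg)
  sp <- attr(ref, "spikes")
  expect_gt(length(sp), 10)
  isi <- diff(sp)
  expect_gt(utils::tail(isi, 1), utils::head(isi, 1))   # rate slows down
  expect_true(all(isi >= cfg$refractory - 1e-12))       # refractory contract
})

test_that("the vectorized core is silent without input and respects refractoriness", {
  f <- open_front()
  net <- f$net
  res <- wavenav:::run_core(net, 1, t_max = 0.2, mode = "none",
                            term_mode = 0L, noise_sd = 0, d = 0L)
  expect_equal(res$total_spikes, 0)

  # in the wavefront fixture no cell ever fires twice within 2 ms
  sp <- f$fr$spikes
  gaps <- tapply(sp$t, sp$id, function(t) if (length(t) > 1) min(diff(t)) else Inf)
  expect_true(all(gaps >= 0.002 - 1e-12))
})

test_that("halving the Euler step leaves first-spike times nearly unchanged", {
  env <- make_environment("open", side = 0.5)
  map <- suppressWarnings(assign_place_fields(env, n_cells = 300, seed = 6))
  w <- nearest_neighbour_connectivity(map, 1)
  first <- lapply(c(2e-4, 1e-4), function(dt) {
    net <- make_network(map, w, wn_config(neuron = list(dt = dt)))
    fr <- run_planning(net, target_set(rbind(c(0.25, 0.25))), seed = 1)
    fr$first_spike
  })
  ok <- is.finite(first[[1]]) & is.finite(first[[2]])
  expect_gt(mean(ok), 0.98)
  expect_lt(stats::median(abs(first[[1]][ok] - first[[2]][ok])), 5e-4 + 1e-9)
})

test_that("gated global inhibition lowers the population rate under drive", {
  env <- make_environment("open")
  map <- assign_place_fields(env, n_cells = 400, seed = 3)
  w <- nearest_neighbour_connectivity(map, 1)
  net <- make_network(map, w)
  spikes_with_gate <- function(gate) {
    set.seed(1)
    res <- wavenav:::run_core(net, 1, t_max = 1, mode = "path",
                              path = matrix(c(0.5, 0.5), 1), path_dt = 10,
                              term_mode = 0L, quiet_window = 10,
                              sens_amp = 1.2, noise_sd = 0.25,
                              d = 0L, gate = gate)
    res$total_spikes
  }
  expect_lt(spikes_with_gate(TRUE), spikes_with_gate(FALSE))
})
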