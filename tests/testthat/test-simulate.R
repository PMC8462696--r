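test_that("a network at leak equilibrium with no input stays silent", {
  net <- single_pop_net(cell_params(), n = 3L)
  sim <- simulate_network(net, NULL, duration = 50, dt = 0.05,
                          record = "X")
  expect_equal(nrow(sim$spikes$X), 0)
  expect_true(all(abs(sim$voltages$X + 70) < 1e-9))
})

test_that("subthreshold step response matches the analytic RC solution", {
  net <- single_pop_net(cell_params(i_app = 1))   # settles at -60 mV
  sim <- simulate_network(net, NULL, duration = 100, dt = 0.01,
                          record = "X", v_stride = 1L)
  t <- seq(0.01, 100, by = 0.01)
  V_ref <- -70 + 10 * (1 - exp(-t / 10))
  V <- sim$voltages$X[1, -1]
  expect_lt(max(abs(V - V_ref) / abs(V_ref)), 0.01)
})

test_that("tonic firing rate matches the analytic inter-spike interval", {
  p <- cell_params(i_app = 3)
  net <- single_pop_net(p)
  sim <- simulate_network(net, NULL, duration = 1000, dt = 0.01)
  isi <- diff(sim$spikes$X$time)
  expect_equal(mean(isi), analytic_isi(p), tolerance = 0.01)
})

test_that("the compiled core matches the explicit event-sum oracle", {
  # feed-forward pair, a handful of presynaptic spikes, both synapse types
  for (syn in list(excitatory_synapse(0.4), inhibitory_synapse(1))) {
    pre <- c(3, 4.1, 9, 9.6, 15)
    ff <- feedforward_pair(syn, pre)
    dt <- 0.05
    sim <- simulate_network(ff$net, ff$input, duration = 40, dt = dt,
                            record = "E", v_stride = 1L)
    ref <- oracle_lif(pre, syn, cell_params(), duration = 40, dt = dt)
    expect_equal(as.numeric(sim$voltages$E[1, -1]), ref$V,
                 tolerance = 1e-10)
    expect_equal(sim$spikes$E$time, ref$spikes, tolerance = 1e-10)
  }
})

test_that("membrane potential stays within the synaptic reversal span", {
  # spiking disabled by an unreachable threshold; hammer the cell with
  # dense spike trains through each synapse type
  p <- cell_params(V_thresh = 500, V_spike = 600)
  set.seed(9)
  pre <- sort(runif(200, 0, 50))
  for (cfg in list(list(syn = inhibitory_synapse(5), lo = -80, hi = -70),
                   list(syn = excitatory_synapse(5), lo = -70, hi = 0))) {
    ff <- feedforward_pair(cfg$syn, pre, post_params = p)
    sim <- simulate_network(ff$net, ff$input, duration = 60, dt = 0.05,
                            record = "E", v_stride = 1L)
    V <- sim$voltages$E
    expect_gte(min(V), cfg$lo - 1e-9)
    expect_lte(max(V), cfg$hi + 1e-9)
  }
})

test_that("identical seeds give byte-identical rasters", {
  p <- cell_params(i_app = 1.4, noise = 6)     # noise-driven firing
  net <- single_pop_net(p, n = 5L)
  s1 <- simulate_network(net, NULL, duration = 200, dt = 0.05, seed = 42)
  s2 <- simulate_network(net, NULL, duration = 200, dt = 0.05, seed = 42)
  s3 <- simulate_network(net, NULL, duration = 200, dt = 0.05, seed = 43)
  expect_gt(nrow(s1$spikes$X), 0)
  expect_identical(s1$spikes, s2$spikes)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("halving dt shifts spike timing by less than dt", {
  # the first-spike latency and every inter-spike interval move by less
  # than dt; absolute times of late spikes accumulate the per-interval
  # discretisation bias linearly, so locality is the meaningful check
  p <- cell_params(i_app = 3)
  net <- single_pop_net(p)
  dt <- 0.02
  a <- simulate_network(net, NULL, duration = 300, dt = dt)$spikes$X$time
  b <- simulate_network(net, NULL, duration = 300,
                        dt = dt / 2)$spikes$X$time
  n <- min(length(a), length(b))
  expect_gt(n, 20)
  expect_lt(abs(a[1] - b[1]), dt)
  expect_lt(max(abs(diff(a[1:n]) - diff(b[1:n]))), dt)
})

test_that("unstable time steps and mismatched inputs are rejected", {
  ff <- feedforward_pair(excitatory_synapse(1), 5)
  expect_error(simulate_network(ff$net, ff$input, 10, dt = 0.5),
               "unstable")
  grid <- channel_grid("azimuth", seq(-90, 90, by = 45))
  net <- build_spatial_network(grid, aim_table2("lee"))
  bad <- poisson_ic(100, 7, 50, seed = 1)       # 7 channels into a 5-grid
  expect_error(simulate_network(net, bad, 50, dt = 0.05),
               "channel-count mismatch")
})

test_that("spike rasters and voltage traces round-trip through text", {
  p <- cell_params(i_app = 3)
  net <- single_pop_net(p, n = 2L)
  sim <- simulate_network(net, NULL, duration = 60, dt = 0.05,
                          record = "X")
  f <- withr::local_tempfile(fileext = ".csv")
  write_spikes(sim, f)
  df <- read_spikes(f)
  expect_equal(nrow(df), nrow(sim$spikes$X))
  expect_equal(df$spike_time_ms, round(sim$spikes$X$time, 3))
  expect_true(all(df$population_id == "X"))
  expect_equal(df$channel_index, sim$channel_map$X[sim$spikes$X$neuron])
  fv <- withr::local_tempfile(fileext = ".csv")
  write_voltages(sim, "X", fv)
  vv <- utils::read.csv(fv)
  expect_equal(ncol(vv), 3)
  expect_equal(nrow(vv), ncol(sim$voltages$X))
})

test_that("relay and silencing calibration behaves as designed", {
  # with the inhibitory populations silenced, input drives E and C;
  # with I tonically active, E is silenced after the settling period
  grid <- channel_grid("azimuth", seq(-90, 90, by = 10))
  net <- build_spatial_network(grid, aim_table2("lee"))
  inp <- poisson_ic(200, 19, 200, seed = 7)
  relay <- net
  relay$pops$I$i_app[] <- 0
  relay$pops$I2$i_app[] <- 0
  relay$conns[[aimnet:::find_conn(relay, "E->I")]]$syn$g_syn <- 0
  s <- simulate_network(relay, inp, 200, dt = 0.05)
  expect_gt(nrow(s$spikes$E), nrow(inp$spikes))   # relay amplifies
  expect_gt(nrow(s$spikes$C), 0)
  expect_equal(nrow(s$spikes$I), 0)

  tonic <- net
  tonic$pops$I2$i_app[] <- 0      # I2 off: I runs on its tonic current
  s2 <- simulate_network(tonic, inp, 200, dt = 0.05)
  expect_gt(nrow(s2$spikes$I), 0)
  expect_equal(sum(s2$spikes$E$time > 20), 0)     # E silenced when settled
})
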