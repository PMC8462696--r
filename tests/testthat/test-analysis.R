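test_that("moving-window rate counts spikes per window", {
  mr0 <- moving_rate(numeric(0), 100)
  expect_true(all(mr0$rate == 0))

  # regular 100 Hz train: steady-state rate 100 spikes/s
  mr <- moving_rate(seq(5, 995, by = 10), 1000)
  expect_equal(mean(mr$rate[mr$time > 50 & mr$time < 950]), 100,
               tolerance = 0.02)

  # one spike, 5 ms window: rate 200 spikes/s over exactly one window
  mr1 <- moving_rate(10, 50, window = 5, step = 1)
  expect_equal(max(mr1$rate), 200)
  expect_equal(sum(mr1$rate == 200), 5)

  # mean rate times duration returns the spike count (one-window slack)
  set.seed(3)
  spk <- sort(runif(87, 0, 500))
  mr2 <- moving_rate(spk, 500, window = 5, step = 1)
  expect_equal(mean(mr2$rate) * 0.5, 87, tolerance = 5 / 500 * 87 + 2)
})

test_that("tuning surfaces stack per-probe PSTHs and expose marginals", {
  p <- cell_params(i_app = 3)
  net <- single_pop_net(p)
  sims <- lapply(1:3, function(i)
    simulate_network(net, NULL, duration = 100, dt = 0.05))
  surf <- tuning_surface(sims, c(-10, 0, 10), pop = "X")
  expect_equal(dim(surf$rate), c(3L, 101L))
  expect_equal(length(probe_marginal(surf)), 3)

  silent <- single_pop_net(cell_params())
  s0 <- lapply(1:2, function(i) simulate_network(silent, NULL, 50,
                                                 dt = 0.05))
  surf0 <- tuning_surface(s0, c(0, 1), pop = "X")
  expect_true(all(surf0$rate == 0))
})

test_that("frequency collapse preserves per-channel expected counts", {
  set.seed(11)
  spikes <- do.call(rbind, lapply(1:3, function(s)
    data.frame(spatial = s, freq = sample(1:8, 60 * s, TRUE),
               time = sort(runif(60 * s, 0, 200)))))
  ic <- structure(list(spikes = spikes, n_spatial = 3L, n_freq = 8L,
                       azimuths = c(-45, 0, 45), freqs = 1:8,
                       duration = 200), class = "aim_ic_input")
  one <- collapse_frequency_poisson(ic, seed = 1)
  expect_equal(one$n_freq, 1L)
  expect_true(all(one$spikes$freq == 1L))
  expect_true(all(one$spikes$time >= 0 & one$spikes$time <= 200))

  # expected collapsed count equals the input count per spatial channel
  means <- rowMeans(vapply(1:20, function(sd)
    ic_counts_by_spatial(collapse_frequency_poisson(ic, seed = sd)),
    numeric(3)))
  expect_equal(means, c(60, 120, 180), tolerance = 0.1)

  empty <- ic
  empty$spikes <- empty$spikes[0, ]
  expect_equal(nrow(collapse_frequency_poisson(empty, seed = 1)$spikes), 0)
})

test_that("the 2-D correlation is a Pearson coefficient over entries", {
  set.seed(4)
  A <- matrix(rnorm(300), 10)
  expect_equal(corr2d(A, A), 1)
  expect_equal(corr2d(A, -A), -1)
  expect_equal(corr2d(A, 3 * A + 7), 1)       # affine invariance
  B <- matrix(sample(A), 10)                  # permutation oracle
  expect_lt(abs(corr2d(A, B)), 0.15)
  expect_warning(r <- corr2d(matrix(1, 4, 4), A[1:4, 1:4]),
                 "zero-variance")
  expect_true(is.na(r))
  # time axes of different lengths are resampled, not rejected: a smooth
  # rate pattern sampled at half the rate still correlates near 1
  S <- outer(1:10, seq(0, 2 * pi, length.out = 60),
             function(i, t) sin(t * i / 3) + i)
  S2 <- S[, seq(1, 60, by = 2)]
  expect_gt(corr2d(S, S2), 0.95)
  expect_error(corr2d(A, A[1:5, ]), "row-count")
})

test_that("half-maximum width matches constructed marginals", {
  # rectangular marginal spanning 40 degrees on a fine grid
  x <- seq(-60, 60, by = 1)
  m <- as.numeric(abs(x) <= 20)
  expect_equal(tuning_width(list(marginal = m, probe_values = x)), 40,
               tolerance = 2)
  # Gaussian with sigma = 10: FWHM = 2 sqrt(2 log 2) * 10
  g <- exp(-x^2 / 200)
  expect_equal(tuning_width(list(marginal = g, probe_values = x)),
               2 * sqrt(2 * log(2)) * 10, tolerance = 0.5)
  # single active probe: width bounded by the probe spacing
  x2 <- seq(-80, 80, by = 10)
  m2 <- as.numeric(x2 == 30)
  expect_lte(tuning_width(list(marginal = m2, probe_values = x2)), 10)
  expect_error(tuning_width(list(marginal = numeric(17),
                                 probe_values = x2)), "all-zero")
})

test_that("autocorrelation pitch estimation recovers fundamentals and
           rejects noise", {
  tok <- gen_stimulus("token", 300, f0 = 120, seed = 6)
  expect_equal(estimate_f0(tok), 120, tolerance = 2 / 120)
  tone <- gen_stimulus("tone", 200, frequency = 300)
  expect_equal(estimate_f0(tone), 300, tolerance = 2 / 300)
  nz <- gen_stimulus("noise", 300, seed = 6)
  expect_true(is.na(estimate_f0(nz)))
})

test_that("percent spike-count change compares matched channels", {
  p <- cell_params(i_app = 3)
  net <- single_pop_net(p, n = 2L)
  sim <- simulate_network(net, NULL, 200, dt = 0.05)
  expect_equal(spike_count_change(sim, sim, 1, pop = "X"), 0)
  doubled <- sim
  doubled$spikes$X <- rbind(sim$spikes$X,
                            transform(sim$spikes$X,
                                      time = time + 0.025))
  expect_equal(spike_count_change(doubled, sim, 1, pop = "X"), 100)
  silent <- simulate_network(single_pop_net(cell_params(), n = 2L),
                             NULL, 200, dt = 0.05)
  expect_error(spike_count_change(sim, silent, 1, pop = "X"),
               "zero passive")
})

test_that("rate matrices round-trip through delimited text", {
  set.seed(5)
  rate <- matrix(rpois(60, 40), 6)
  tm <- seq(0, 9)
  probes <- seq(100, 600, by = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rate_matrix(rate, tm, probes, f)
  back <- read_rate_matrix(f)
  expect_equal(back$time, tm)
  expect_equal(back$probe_values, probes)
  expect_equal(unname(back$rate), unname(rate))
})
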