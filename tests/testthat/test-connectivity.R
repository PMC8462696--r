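erb_grid <- channel_grid("frequency", erb_centers())

test_that("excitatory convergence kernel is a peak-normalised Gaussian", {
  g <- channel_grid("azimuth", seq(-90, 90, by = 10))
  w <- gaussian_excitatory_kernel(g, 0, sigma_EC = 20, g_EC = 0.8)
  expect_equal(w[g$values == 0], 0.8)
  expect_equal(w[g$values == 30], w[g$values == -30])
  expect_equal(w[g$values == 20], 0.8 * exp(-400 / 800))
  expect_error(gaussian_excitatory_kernel(g, 0, sigma_EC = 0), "sigma_EC")
})

test_that("lateral inhibition kernel has a 2-sigma dead zone and rises
           monotonically to its plateau", {
  s <- 500
  w <- lateral_inhibition_kernel(erb_grid, 1600, sigma_IE = s, g_IE = 1)
  d <- abs(erb_grid$values - 1600)
  expect_true(all(w[d <= 2 * s] == 0))
  expect_true(all(w[d > 2 * s] > 0))
  # non-decreasing with distance on each side (exhaustive on the grid)
  for (side in list(which(erb_grid$values > 1600),
                    rev(which(erb_grid$values < 1600))))
    expect_true(all(diff(w[side]) >= -1e-12))
  expect_gt(max(w), 0.99)            # plateau approached at the grid edge
  expect_error(lateral_inhibition_kernel(erb_grid, 1600, 0), "sigma_IE")
})

test_that("parameter columns carry the packaged conductances", {
  lee <- aim_table2("lee")
  expect_equal(lee$g[["IC_E"]], 2.5)
  expect_equal(lee$g[["I_E"]], 3)
  expect_equal(lee$g[["I2_E"]], 2.8)
  expect_equal(lee$i_app[["I2"]], 8)
  expect_equal(lee$i_app[["I"]], 3)
  fr <- aim_table2("fritz")
  expect_equal(fr$g[["E_E_attend"]], 5)
  expect_equal(fr$g[["E_E_passive"]], 3)
  expect_equal(fr$kernel$sigma_IE, 0.65)
  expect_equal(fr$kernel$sigma_EC, 0.32)
  expect_equal(aim_table2("atiani_b")$kernel$sigma_IE, 2)
  expect_equal(aim_table2("atiani_b")$kernel$sigma_EC, 0.35)
  expect_equal(aim_table2("freq_function")$kernel$sigma_IE, 0.01)
  expect_equal(aim_table2("spatial_function")$i_app[["I2"]], 3.5)
})

test_that("the spatial build realises the disinhibition motif", {
  grid <- channel_grid("azimuth", seq(-90, 90, by = 10))
  net <- build_spatial_network(grid, aim_table2("lee"))
  labs <- vapply(net$conns, `[[`, character(1), "label")
  expect_setequal(labs, c("IC->E", "E->C", "E->I", "I->E", "I2->I",
                          "I2->E"))
  W_ie <- as.matrix(net$conns[[aimnet:::find_conn(net, "I->E")]]$W)
  expect_true(all(diag(W_ie) == 0))           # no self-channel inhibition
  expect_true(all(W_ie[row(W_ie) != col(W_ie)] == 1))
  W_ec <- as.matrix(net$conns[[aimnet:::find_conn(net, "E->C")]]$W)
  expect_equal(dim(W_ec), c(19L, 1L))
  expect_true(all(W_ec == 1))                 # all-channel convergence
  expect_equal(net$pops$C$n, 1L)              # one cortical readout
  expect_true(all(net$pops$I2$i_app == 8))
  bad <- aim_table2("lee")
  bad$g <- bad$g[names(bad$g) != "I_E"]
  expect_error(build_spatial_network(grid, bad), "missing")
})

test_that("the spectral build centres convergence on the best frequency
           and bands inhibition", {
  net <- build_spectral_network(erb_grid, aim_table2("atiani_b"))
  f <- erb_grid$values
  w_ec <- as.numeric(net$conns[[aimnet:::find_conn(net, "E->C")]]$W)
  expect_equal(which.max(w_ec), nearest_channel(erb_grid, net$f_B))
  W_ie <- as.matrix(net$conns[[aimnet:::find_conn(net, "I->E")]]$W)
  # per-row zero band of half-width 2 sigma_IE (sigma in kHz)
  for (k in c(1, 20, 33, 50, 64)) {
    d <- abs(f - f[k])
    expect_true(all(W_ie[k, d <= 2 * 2000] == 0))
    expect_true(all(W_ie[k, d > 2 * 2000] > 0))
  }
  # per-channel readout variant: one C per channel, own Gaussian each
  net2 <- build_spectral_network(erb_grid, aim_table2("freq_function"),
                                 readout = "per_channel")
  expect_equal(net2$pops$C$n, 64L)
  W2 <- as.matrix(net2$conns[[aimnet:::find_conn(net2, "E->C")]]$W)
  expect_equal(unname(apply(W2, 2, which.max)), 1:64)
})

test_that("attention toggles I2 tonic currents and is restored by
           monitor mode", {
  grid <- channel_grid("azimuth", seq(-90, 90, by = 10))
  net <- build_spatial_network(grid, aim_table2("lee"))
  att <- set_attention(net, attention_state(30, "select"))
  idx <- nearest_channel(grid, 30)
  expect_equal(att$pops$I2$i_app[idx], 0)
  expect_true(all(att$pops$I2$i_app[-idx] == 8))
  back <- set_attention(att, attention_state())
  expect_identical(back$pops, net$pops)       # involution with monitor
  expect_equal(back$attention$mode, "monitor")
  expect_error(set_attention(net, attention_state(500)), "outside")
  expect_error(attention_state(numeric(0), "select"), "monitor")
})

test_that("cholinergic gains suppress off-target cortical drive and boost
           off-target thalamocortical drive", {
  grid <- channel_grid("azimuth", seq(-90, 90, by = 10))
  net <- build_spatial_network(grid, aim_table2("lee"))
  mod <- apply_cholinergic_gains(net, 30)
  idx <- nearest_channel(grid, 30)
  W_ec <- as.matrix(mod$conns[[aimnet:::find_conn(mod, "E->C")]]$W)
  W_ec0 <- as.matrix(net$conns[[aimnet:::find_conn(net, "E->C")]]$W)
  expect_identical(W_ec[idx, ], W_ec0[idx, ])  # target untouched
  expect_true(all(W_ec[-idx, ] == 0))
  rg <- mod$conns[[aimnet:::find_conn(mod, "IC->E")]]$row_gain
  expect_equal(rg[idx], 1)
  expect_true(all(rg[-idx] == 2.5))
  # masks stay normalised; the 2.5 gain lives outside the mask
  for (cn in mod$conns) {
    expect_true(all(cn$W@x >= 0 & cn$W@x <= 1))
  }
})

test_that("the gated intracortical connection is added, scaled by state,
           and removable", {
  net <- build_spectral_network(erb_grid, aim_table2("fritz"))
  fT <- net$f_B + 1200
  att <- add_ft_fb_connection(net, fT, state = "attend")
  pas <- add_ft_fb_connection(net, fT, state = "passive")
  ga <- att$conns[[aimnet:::find_conn(att, "E->E")]]$syn$g_syn
  gp <- pas$conns[[aimnet:::find_conn(pas, "E->E")]]$syn$g_syn
  expect_equal(ga, 5)
  expect_equal(gp, 3)
  W <- att$conns[[aimnet:::find_conn(att, "E->E")]]$W
  expect_equal(Matrix::nnzero(W), 1L)
  expect_equal(W[nearest_channel(erb_grid, fT),
                 nearest_channel(erb_grid, net$f_B)], 1)
  expect_error(add_ft_fb_connection(net, net$f_B), "same channel")
  reverted <- drop_connection(att, "E->E")
  expect_equal(length(reverted$conns), length(net$conns))
})

test_that("top-down mode switches between direct and feed-forward
           disinhibition", {
  net <- build_spectral_network(erb_grid, aim_table2("atiani_a"))
  ff <- set_topdown_mode(net, "feedforward")
  expect_equal(Matrix::nnzero(ff$conns[[aimnet:::find_conn(ff,
                                                           "I2->I")]]$W),
               0L)
  back <- set_topdown_mode(ff, "direct")
  expect_equal(as.matrix(back$conns[[aimnet:::find_conn(back,
                                                        "I2->I")]]$W),
               diag(64))
})

test_that("within-channel suppression adds an S population that can carve
           below-spontaneous responses, and gain 0 is inert", {
  g <- channel_grid("frequency", erb_centers(n = 8))
  params <- aim_table2("freq_function")
  base <- build_spectral_network(g, params, readout = "per_channel")
  att <- attention_state(g$values[4], "select")
  set.seed(21)
  ic <- structure(list(
    spikes = data.frame(spatial = 1L, freq = 4L,
                        time = sort(runif(150, 50, 250))),
    n_spatial = 1L, n_freq = 8L, azimuths = 0, freqs = g$values,
    duration = 300), class = "aim_ic_input")

  plain <- set_attention(base, att)
  withS0 <- set_attention(add_within_channel_suppression(base, g_s_e = 0),
                          att)
  withS <- set_attention(add_within_channel_suppression(base, g_s_e = 2),
                         att)
  s0 <- simulate_network(plain, ic, 300, dt = 0.05)
  s1 <- simulate_network(withS0, ic, 300, dt = 0.05)
  s2 <- simulate_network(withS, ic, 300, dt = 0.05)
  expect_identical(s1$spikes$E, s0$spikes$E)   # zero-gain S is inert
  # the disinhibited E fires tonically before the stimulus; driven S
  # suppresses it below that spontaneous rate during the stimulus
  spont <- sum(s2$spikes$E$neuron == 4 & s2$spikes$E$time < 50) / 0.05
  driven <- sum(s2$spikes$E$neuron == 4 & s2$spikes$E$time >= 50 &
                  s2$spikes$E$time < 250) / 0.2
  expect_gt(spont, 0)
  expect_lt(driven, spont)
})
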