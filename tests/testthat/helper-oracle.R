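# Shared fixtures and an independent reference simulator.
#
# The reference simulator re-computes a small network by explicit event
# summation: at every step it evaluates the double-exponential kernel for
# every (presynaptic spike, synapse) pair directly, instead of the
# compiled core's recursive decay traces, and advances the membrane with
# the same exponential-Euler rule. Agreement is therefore a genuine
# dual-route check on the synaptic superposition and integration order.

single_pop_net <- function(params, n = 1L, axis = "azimuth", value = 0) {
  pops <- list(X = aimnet:::new_population("X", n, params))
  # a zero-weight self-connection satisfies the network contract without
  # injecting current
  conn <- connection("X", "X", excitatory_synapse(0),
                     Matrix::Matrix(0, n, n), label = "X->X")
  aim_network(pops, list(conn), channel_grid(axis, value))
}

feedforward_pair <- function(syn, source_spikes, post_params = cell_params()) {
  pops <- list(IC = aimnet:::new_population("IC", 1L, cell_params(),
                                            source = TRUE),
               E = aimnet:::new_population("E", 1L, post_params))
  net <- aim_network(pops,
                     list(connection("IC", "E", syn, matrix(1, 1, 1),
                                     label = "IC->E")),
                     channel_grid("azimuth", 0))
  list(net = net,
       input = data.frame(neuron = 1L, time = source_spikes))
}

# explicit event-sum reference: one LIF neuron driven through one synapse
# by a fixed list of presynaptic spike times. Shares the simulator's
# discretisation conventions (a spike binned at step s seeds its kernel
# at step s+1, where the double exponential starts from zero) but sums
# the kernel over events directly instead of carrying recursive decay
# traces, so agreement checks the superposition itself.
oracle_lif <- function(pre_spikes, syn, params, duration, dt) {
  n_steps <- round(duration / dt)
  pre_step <- round(pre_spikes / dt)          # 0-based bin of each spike
  V <- params$E_leak
  Vtr <- numeric(n_steps)
  spikes <- numeric(0)
  for (step in 0:(n_steps - 1)) {
    age <- (step - pre_step - 1) * dt         # kernel age at this step
    g <- syn$g_syn * sum(conductance_kernel(age[age >= 0], syn))
    g_tot <- params$g_leak + g
    v_inf <- (params$g_leak * params$E_leak + g * syn$E_syn +
                params$i_app) / g_tot
    V <- v_inf + (V - v_inf) * exp(-g_tot * dt / params$C)
    if (V > params$V_thresh) {
      spikes <- c(spikes, (step + 1) * dt)
      V <- params$V_reset
    }
    Vtr[step + 1] <- V
  }
  list(V = Vtr, spikes = spikes)
}

poisson_ic <- function(rate_per_ch, n_ch, duration, seed,
                       n_freq = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_ch), function(ch) {
    n <- stats::rpois(1, rate_per_ch * duration / 1000)
    if (n == 0) return(NULL)
    data.frame(spatial = ch, freq = 1L,
               time = sort(stats::runif(n, 0, duration)))
  })
  spikes <- do.call(rbind, rows)
  if (is.null(spikes))
    spikes <- data.frame(spatial = integer(0), freq = integer(0),
                         time = numeric(0))
  structure(list(spikes = spikes, n_spatial = n_ch, n_freq = n_freq,
                 azimuths = seq_len(n_ch), freqs = NA_real_,
                 duration = duration),
            class = "aim_ic_input")
}

# analytic inter-spike interval of a LIF neuron under constant current
analytic_isi <- function(params) {
  v_inf <- params$E_leak + params$i_app / params$g_leak
  tau_m(params) * log((v_inf - params$V_reset) / (v_inf - params$V_thresh))
}
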