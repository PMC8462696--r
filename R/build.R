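#' Default cellular parameters
#'
#' The shared cellular defaults for every population: C = 1 nF, g_leak =
#' 0.1 uS, E_leak = -70 mV, V_thresh = -55 mV, V_spike = 50 mV, V_reset =
#' -75 mV, i_app = 0 nA, noise 0.
#' @param ... overrides passed to [cell_params()].
#' @return a [cell_params()] object.
#' @export
default_cell_params <- function(...) cell_params(...)

#' Per-simulation synaptic and applied-current parameter sets
#'
#' Returns the packaged parameter column for one of the six simulation
#' set-ups: synaptic conductances (uS) for IC->E, E->C, E->I, I2->I, I2->E,
#' I->E (plus the E->E pair for the receptive-field hotspot protocol),
#' tonic applied currents (nA) for the I, E and I2 populations, and, for
#' spectral columns, the convergence kernel parameters (g_EC, g_IE
#' dimensionless; sigma_EC, sigma_IE in kHz).
#'
#' @param column one of `"lee"`, `"fritz"`, `"atiani_a"`, `"atiani_b"`,
#'   `"spatial_function"`, `"freq_function"`.
#' @return a list with elements `g`, `i_app` and (spectral columns)
#'   `kernel`.
#' @export
aim_table2 <- function(column = c("lee", "fritz", "atiani_a", "atiani_b",
                                  "spatial_function", "freq_function")) {
  column <- match.arg(column)
  k <- function(s_ie, s_ec) list(g_EC = 1, g_IE = 1,
                                 sigma_IE = s_ie, sigma_EC = s_ec)
  tab <- list(
    lee = list(
      g = c(IC_E = 2.5, E_C = 2, E_I = 2.5, I2_I = 4, I2_E = 2.8, I_E = 3),
      i_app = c(I = 3, E = 1, I2 = 8), kernel = NULL),
    fritz = list(
      g = c(IC_E = 4, E_C = 1.25, E_I = 3, I2_I = 3, I2_E = 4, I_E = 4,
            E_E_attend = 5, E_E_passive = 3),
      i_app = c(I = 0, E = 3, I2 = 8), kernel = k(0.65, 0.32)),
    atiani_a = list(
      g = c(IC_E = 4, E_C = 1.25, E_I = 3, I2_I = 3, I2_E = 4, I_E = 4),
      i_app = c(I = 0, E = 3, I2 = 8), kernel = k(1.7, 1.15)),
    atiani_b = list(
      g = c(IC_E = 3, E_C = 3, E_I = 3, I2_I = 3, I2_E = 3, I_E = 4),
      i_app = c(I = 0, E = 3, I2 = 8), kernel = k(2, 0.35)),
    spatial_function = list(
      g = c(IC_E = 2, E_C = 2, E_I = 2, I2_I = 2.25, I2_E = 1.25, I_E = 3),
      i_app = c(I = 4, E = 0, I2 = 3.5), kernel = NULL),
    freq_function = list(
      g = c(IC_E = 4, E_C = 1.5, E_I = 3, I2_I = 3, I2_E = 3, I_E = 3.5),
      i_app = c(I = 0, E = 3, I2 = 8), kernel = k(0.01, 0.05)))
  c(tab[[column]], list(column = column))
}

#' Gaussian excitatory convergence kernel
#'
#' Weight of the connection from the channel at `x` onto a target centred
#' at `center`: `g_EC * exp(-(x - center)^2 / (2 sigma_EC^2))`, peaking at
#' `g_EC` at the centre.
#'
#' @param grid a [channel_grid()].
#' @param center centre value (same units as the grid).
#' @param sigma_EC convergence width (same units as the grid); > 0.
#' @param g_EC peak strength.
#' @return weight vector over grid channels.
#' @export
gaussian_excitatory_kernel <- function(grid, center, sigma_EC, g_EC = 1) {
  if (sigma_EC <= 0) stop("sigma_EC must be > 0")
  g_EC * exp(-(grid$values - center)^2 / (2 * sigma_EC^2))
}

#' Thresholded inverted-Gaussian lateral-inhibition kernel
#'
#' Cross-channel inhibitory weight as a function of distance from the
#' inhibiting channel: exactly zero within `2 * sigma_IE` of the centre
#' (the dead zone), and `g_IE * (1 - exp(-d^2 / (2 sigma_IE^2)))` beyond
#' it, rising monotonically towards the plateau `g_IE`.
#'
#' @param grid a [channel_grid()].
#' @param center centre value.
#' @param sigma_IE dead-zone half-width is `2 * sigma_IE`; > 0.
#' @param g_IE plateau strength.
#' @return weight vector over grid channels.
#' @export
lateral_inhibition_kernel <- function(grid, center, sigma_IE, g_IE = 1) {
  if (sigma_IE <= 0) stop("sigma_IE must be > 0")
  d <- abs(grid$values - center)
  w <- g_IE * (1 - exp(-d^2 / (2 * sigma_IE^2)))
  w[d <= 2 * sigma_IE] <- 0
  w
}

diag_mask <- function(n) Matrix::Diagonal(n, 1)

lane_kron <- function(n_lanes, W) {
  if (n_lanes == 1) return(W)
  Matrix::kronecker(Matrix::Diagonal(n_lanes, 1), W)
}

#' Build a spatial AIM network
#'
#' Per-channel chains IC->E->C with all-channel convergence onto one
#' cortical readout per lane, cross-channel lateral inhibition I->E
#' (zero diagonal: no self-channel inhibition), within-channel E->I, and
#' within-channel top-down modulation I2->I and I2->E. Tonic currents for
#' E, I and I2 come from the chosen parameter column.
#'
#' @param grid azimuthal [channel_grid()].
#' @param params a parameter set from [aim_table2()] (default the spatial
#'   tuning column `"lee"`).
#' @param n_lanes number of independent frequency lanes; each lane
#'   replicates the spatial circuit and has its own C readout (used by the
#'   cocktail-party protocols, where each filterbank channel is processed
#'   independently).
#' @return an [aim_network()].
#' @export
build_spatial_network <- function(grid, params = aim_table2("lee"),
                                  n_lanes = 1) {
  stopifnot(grid$axis == "azimuth")
  g <- params$g
  need <- c("IC_E", "E_C", "E_I", "I2_I", "I2_E", "I_E")
  if (any(is.na(g[need])) || !all(need %in% names(g)))
    stop("parameter set missing rows: ",
         paste(setdiff(need, names(g)), collapse = ", "))
  n_ch <- grid$n
  n <- n_ch * n_lanes
  ch_map <- rep(seq_len(n_ch), n_lanes)
  ia <- params$i_app
  pops <- list(
    IC = new_population("IC", n, cell_params(), ch_map, source = TRUE),
    E = new_population("E", n, cell_params(i_app = ia[["E"]]), ch_map),
    I = new_population("I", n, cell_params(i_app = ia[["I"]]), ch_map),
    I2 = new_population("I2", n, cell_params(i_app = ia[["I2"]]), ch_map),
    C = new_population("C", n_lanes, cell_params(), seq_len(n_lanes)))
  ec <- Matrix::sparseMatrix(
    i = seq_len(n), j = rep(seq_len(n_lanes), each = n_ch), x = 1,
    dims = c(n, n_lanes))
  cross <- Matrix::Matrix(1, n_ch, n_ch) - diag_mask(n_ch)
  conns <- list(
    connection("IC", "E", excitatory_synapse(g[["IC_E"]]), diag_mask(n),
               label = "IC->E"),
    connection("E", "C", excitatory_synapse(g[["E_C"]]), ec,
               label = "E->C"),
    connection("E", "I", excitatory_synapse(g[["E_I"]]), diag_mask(n),
               label = "E->I"),
    connection("I", "E", inhibitory_synapse(g[["I_E"]]),
               lane_kron(n_lanes, cross), label = "I->E"),
    connection("I2", "I", inhibitory_synapse(g[["I2_I"]]), diag_mask(n),
               label = "I2->I"),
    connection("I2", "E", inhibitory_synapse(g[["I2_E"]]), diag_mask(n),
               label = "I2->E"))
  aim_network(pops, conns, grid, n_lanes = n_lanes,
              attention = attention_state(), table2 = params$column,
              i2_i_app = ia[["I2"]], kernel = NULL, readout = "per_lane",
              topdown = "direct", f_B = NULL)
}

#' Build a spectral AIM network
#'
#' Tonotopic variant: excitatory convergence E->C follows a Gaussian kernel
#' centred on the best frequency `f_B`, and cross-channel inhibition I->E
#' follows a thresholded inverted Gaussian per presynaptic row (zero within
#' `2 sigma_IE`, rising to `g_IE` beyond). Within-channel IC->E, E->I,
#' I2->I and I2->E are as in the spatial build.
#'
#' @param grid frequency [channel_grid()] (Hz), typically 64 ERB-spaced
#'   channels from [erb_centers()].
#' @param params a spectral parameter set from [aim_table2()]; its
#'   `kernel` element supplies `sigma_EC`, `g_EC`, `sigma_IE`, `g_IE`
#'   (sigmas in kHz).
#' @param kernel optional kernel override (same structure).
#' @param f_B best frequency (Hz); default the middle grid channel. The
#'   E->C weight is maximal at the channel nearest `f_B`.
#' @param readout `"single"` (one cortical neuron at `f_B`; receptive-field
#'   protocols) or `"per_channel"` (one cortical neuron per frequency
#'   channel, each with its own Gaussian convergence; functional
#'   frequency-domain protocols).
#' @return an [aim_network()].
#' @export
build_spectral_network <- function(grid, params = aim_table2("atiani_a"),
                                   kernel = NULL, f_B = NULL,
                                   readout = c("single", "per_channel")) {
  stopifnot(grid$axis == "frequency")
  readout <- match.arg(readout)
  kernel <- kernel %||% params$kernel
  if (is.null(kernel)) stop("parameter set has no convergence kernel")
  g <- params$g
  n <- grid$n
  f <- grid$values
  if (is.null(f_B)) f_B <- f[ceiling(n / 2)]
  s_ec <- kernel$sigma_EC * 1000
  s_ie <- kernel$sigma_IE * 1000
  if (2 * s_ie >= diff(range(f)))
    warning("inhibitory dead-zone half-width (2*sigma_IE) covers the ",
            "whole grid span; I->E is all-zero")
  ia <- params$i_app
  n_C <- if (readout == "single") 1L else n
  c_map <- if (readout == "single") nearest_channel(grid, f_B) else seq_len(n)
  pops <- list(
    IC = new_population("IC", n, cell_params(), seq_len(n), source = TRUE),
    E = new_population("E", n, cell_params(i_app = ia[["E"]]), seq_len(n)),
    I = new_population("I", n, cell_params(i_app = ia[["I"]]), seq_len(n)),
    I2 = new_population("I2", n, cell_params(i_app = ia[["I2"]]),
                        seq_len(n)),
    C = new_population("C", n_C, cell_params(), c_map))
  ec <- if (readout == "single") {
    Matrix::Matrix(gaussian_excitatory_kernel(grid, f_B, s_ec,
                                              kernel$g_EC), ncol = 1)
  } else {
    Matrix::Matrix(vapply(f, function(fc)
      gaussian_excitatory_kernel(grid, fc, s_ec, kernel$g_EC),
      numeric(n)))  # rows = presynaptic E channel, cols = C centred at fc
  }
  ie <- t(vapply(f, function(fc)
    lateral_inhibition_kernel(grid, fc, s_ie, kernel$g_IE), numeric(n)))
  conns <- list(
    connection("IC", "E", excitatory_synapse(g[["IC_E"]]), diag_mask(n),
               label = "IC->E"),
    connection("E", "C", excitatory_synapse(g[["E_C"]]), ec,
               label = "E->C"),
    connection("E", "I", excitatory_synapse(g[["E_I"]]), diag_mask(n),
               label = "E->I"),
    connection("I", "E", inhibitory_synapse(g[["I_E"]]), ie,
               label = "I->E"),
    connection("I2", "I", inhibitory_synapse(g[["I2_I"]]), diag_mask(n),
               label = "I2->I"),
    connection("I2", "E", inhibitory_synapse(g[["I2_E"]]), diag_mask(n),
               label = "I2->E"))
  aim_network(pops, conns, grid, n_lanes = 1,
              attention = attention_state(), table2 = params$column,
              i2_i_app = ia[["I2"]], kernel = kernel, readout = readout,
              topdown = "direct", f_B = f_B)
}

#' Attention state
#'
#' @param channels grid values (degrees or Hz) of the attended channels;
#'   empty for monitor mode.
#' @param mode optional label (`"monitor"`, `"select"`, `"switch"`);
#'   inferred from `channels` when missing.
#' @return an `attention_state` object.
#' @export
attention_state <- function(channels = numeric(0), mode = NULL) {
  mode <- mode %||% if (length(channels) == 0) "monitor" else "select"
  if (length(channels) == 0 && mode != "monitor")
    stop("monitor mode is exactly the empty attended set")
  structure(list(channels = channels, mode = mode),
            class = "attention_state")
}

#' Set the attention state of a network
#'
#' Attending to a channel inactivates its I2 neuron by zeroing the I2 tonic
#' current in that channel (the neuron falls silent, disinhibiting the
#' channel's I and E neurons). Monitor mode restores every I2 current to the
#' parameter-table value, so `set_attention(select(k))` followed by monitor
#' reproduces the original specification exactly.
#'
#' @param net an [aim_network()].
#' @param state an [attention_state()], or a numeric vector of attended
#'   channel values (empty = monitor).
#' @return the modified network.
#' @export
set_attention <- function(net, state = attention_state()) {
  if (!inherits(state, "attention_state")) state <- attention_state(state)
  idx <- vapply(state$channels, function(v) {
    i <- nearest_channel(net$grid, v)
    if (abs(net$grid$values[i] - v) > max(diff(net$grid$values)))
      stop("attended channel ", v, " is outside the grid")
    i
  }, integer(1))
  ia <- rep(net$i2_i_app, net$pops$I2$n)
  ia[net$pops$I2$channel %in% idx] <- 0
  net$pops$I2$i_app <- ia
  net$attention <- state
  net
}

#' Apply global cholinergic gains (behaving state)
#'
#' Models neuromodulation during task engagement: off-target intracortical
#' drive E->C is suppressed (muscarinic, gain 0) and off-target
#' thalamocortical drive IC->E is enhanced (nicotinic, gain 2.5). The gain
#' 2.5 is applied as a per-row conductance gain rather than inside the
#' weight mask, keeping masks in `[0, 1]`. Target-channel weights are
#' untouched.
#'
#' @param net a spatial [aim_network()].
#' @param target_channel azimuth (deg) of the target channel.
#' @return the modified network.
#' @export
apply_cholinergic_gains <- function(net, target_channel) {
  idx <- nearest_channel(net$grid, target_channel)
  off <- net$pops$E$channel != idx
  iec <- find_conn(net, "E->C")
  W <- net$conns[[iec]]$W
  W[off, ] <- 0
  net$conns[[iec]]$W <- methods::as(W, "CsparseMatrix")
  iic <- find_conn(net, "IC->E")
  rg <- rep(1, net$pops$IC$n)
  rg[net$pops$IC$channel != idx] <- 2.5
  net$conns[[iic]]$row_gain <- rg
  net$cholinergic <- list(on = TRUE, target = target_channel)
  net
}

#' Add the target-to-best-frequency intracortical connection
#'
#' Adds one excitatory E(f_T) -> E(f_B) synapse whose strength depends on
#' the attentional state (attend 5 uS, passive 3 uS by default, the
#' receptive-field hotspot parameter rows). Remove it again with
#' [drop_connection()].
#'
#' @param net a spectral [aim_network()].
#' @param f_T target frequency (Hz).
#' @param f_B best frequency (Hz); defaults to the network's `f_B`.
#' @param state `"attend"` or `"passive"`.
#' @param g_attend,g_passive conductances (uS).
#' @return the modified network.
#' @export
add_ft_fb_connection <- function(net, f_T, f_B = net$f_B,
                                 state = c("passive", "attend"),
                                 g_attend = 5, g_passive = 3) {
  state <- match.arg(state)
  if (net$grid$axis != "frequency") stop("requires a spectral network")
  it <- nearest_channel(net$grid, f_T)
  ib <- nearest_channel(net$grid, f_B)
  if (it == ib) stop("f_T and f_B fall on the same channel")
  n <- net$pops$E$n
  W <- Matrix::sparseMatrix(i = it, j = ib, x = 1, dims = c(n, n))
  g <- if (state == "attend") g_attend else g_passive
  net$conns <- c(net$conns,
                 list(connection("E", "E", excitatory_synapse(g), W,
                                 label = "E->E")))
  net$ft_fb <- list(f_T = f_T, f_B = f_B, state = state)
  net
}

#' Remove a labelled connection
#' @param net an [aim_network()].
#' @param label connection label, e.g. `"E->E"`.
#' @return the modified network.
#' @export
drop_connection <- function(net, label) {
  net$conns <- net$conns[!vapply(net$conns, function(cn) cn$label == label,
                                 logical(1))]
  net$ft_fb <- NULL
  net
}

#' Add within-channel suppression (S population)
#'
#' Adds one S interneuron per channel that is driven by the channel's
#' bottom-up input and inhibits the channel's E neuron, carving
#' below-spontaneous (inhibitory) regions into frequency-dependent PSTHs.
#' S neurons are themselves inhibited by the channel's I2 neuron, so the
#' same top-down disinhibition logic that gates I also gates S.
#'
#' @param net a spectral [aim_network()].
#' @param g_ic_s,g_s_e,g_i2_s conductances (uS) of IC->S, S->E and I2->S;
#'   `g_s_e = 0` reduces exactly to the plain network.
#' @param i_app_s tonic current of S (nA).
#' @return the modified network.
#' @export
add_within_channel_suppression <- function(net, g_ic_s = 3, g_s_e = 2,
                                           g_i2_s = 3, i_app_s = 0) {
  if (net$grid$axis != "frequency") stop("requires a spectral network")
  n <- net$grid$n
  net$pops$S <- new_population("S", n, cell_params(i_app = i_app_s),
                               seq_len(n))
  net$conns <- c(net$conns, list(
    connection("IC", "S", excitatory_synapse(g_ic_s), diag_mask(n),
               label = "IC->S"),
    connection("S", "E", inhibitory_synapse(g_s_e), diag_mask(n),
               label = "S->E"),
    connection("I2", "S", inhibitory_synapse(g_i2_s), diag_mask(n),
               label = "I2->S")))
  net
}

#' Choose how top-down disinhibition reaches the I neurons
#'
#' `"direct"` (default): I2 inhibits I directly, so inactivating I2
#' releases I immediately. `"feedforward"`: the I2->I mask is zeroed and
#' attention acts only through I2->E disinhibition, with the released E
#' neuron recruiting lateral inhibition via E->I. Both modes sharpen the
#' attended channel's tuning.
#'
#' @param net an [aim_network()].
#' @param mode `"direct"` or `"feedforward"`.
#' @return the modified network.
#' @export
set_topdown_mode <- function(net, mode = c("direct", "feedforward")) {
  mode <- match.arg(mode)
  i <- find_conn(net, "I2->I")
  n <- net$pops$I2$n
  net$conns[[i]]$W <- if (mode == "feedforward")
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, net$pops$I$n))
  else diag_mask(n)
  net$topdown <- mode
  net
}
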