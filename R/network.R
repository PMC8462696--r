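#' Synaptic connection between two populations
#'
#' @param pre,post population names (character).
#' @param syn a [synapse_params()] object.
#' @param W weight mask, rows = presynaptic neurons, columns = postsynaptic
#'   neurons, entries in `[0, 1]` scaling `g_syn`. Dense or `Matrix` sparse;
#'   stored sparse.
#' @param row_gain optional per-presynaptic-row gain vector multiplying
#'   `g_syn` for spikes from that row. Used for the nicotinic 2.5x gain on
#'   thalamocortical drive, which is deliberately kept out of the mask so
#'   that masks stay in `[0, 1]`.
#' @param label optional connection label (e.g. `"IC->E"`).
#' @return An object of class `aim_connection`.
#' @export
connection <- function(pre, post, syn, W, row_gain = NULL, label = NULL) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "dMatrix"),
                   "CsparseMatrix")
  if (any(W@x < 0) || any(W@x > 1))
    stop("weight-mask entries must lie in [0, 1]")
  if (!is.null(row_gain)) {
    stopifnot(length(row_gain) == nrow(W), all(row_gain >= 0))
  }
  structure(list(pre = pre, post = post, syn = syn, W = W,
                 row_gain = row_gain,
                 label = label %||% paste0(pre, "->", post)),
            class = "aim_connection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Channel grid of a network
#'
#' @param axis `"azimuth"` (degrees) or `"frequency"` (Hz).
#' @param values strictly monotone channel values.
#' @return An object of class `channel_grid`.
#' @export
channel_grid <- function(axis = c("azimuth", "frequency"), values) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 1, !is.unsorted(values, strictly = TRUE))
  structure(list(axis = axis, values = as.numeric(values),
                 n = length(values)), class = "channel_grid")
}

#' Index of the grid channel nearest a value
#' @param grid a [channel_grid()].
#' @param value target azimuth (deg) or frequency (Hz).
#' @return integer channel index.
#' @export
nearest_channel <- function(grid, value) which.min(abs(grid$values - value))

new_population <- function(name, n, params, channel = seq_len(n),
                           source = FALSE) {
  i_app <- rep(params$i_app, length.out = n)
  list(name = name, n = n, params = params, i_app = i_app,
       noise = params$noise, channel = channel, source = source)
}

#' Assemble a network specification
#'
#' Low-level constructor; most users should call [build_spatial_network()]
#' or [build_spectral_network()] instead.
#'
#' @param pops named list of populations (created internally).
#' @param conns list of [connection()] objects.
#' @param grid a [channel_grid()].
#' @param n_lanes number of independent frequency lanes replicating the
#'   channel structure (spatial networks processing multiple frequency
#'   bands); 1 for collapsed or spectral networks.
#' @param ... further metadata stored on the object.
#' @return An object of class `aim_network`.
#' @export
aim_network <- function(pops, conns, grid, n_lanes = 1, ...) {
  for (cn in conns) {
    if (!cn$pre %in% names(pops) || !cn$post %in% names(pops))
      stop("connection ", cn$label, " references unknown population")
    if (nrow(cn$W) != pops[[cn$pre]]$n || ncol(cn$W) != pops[[cn$post]]$n)
      stop("weight-mask shape mismatch for ", cn$label)
  }
  structure(c(list(pops = pops, conns = conns, grid = grid,
                   n_lanes = n_lanes), list(...)),
            class = "aim_network")
}

#' @export
print.aim_network <- function(x, ...) {
  cat("AIM network (", x$grid$axis, " axis, ", x$grid$n, " channels, ",
      x$n_lanes, " lane(s))\n", sep = "")
  for (p in x$pops)
    cat(sprintf("  %-3s n=%-4d i_app=[%s] nA%s\n", p$name, p$n,
                paste(format(range(p$i_app), trim = TRUE), collapse = ", "),
                if (p$source) " (spike source)" else ""))
  for (cn in x$conns)
    cat(sprintf("  %-8s g=%.3g uS E=%g mV\n", cn$label, cn$syn$g_syn,
                cn$syn$E_syn))
  invisible(x)
}

find_conn <- function(net, label) {
  idx <- which(vapply(net$conns, function(cn) cn$label == label, logical(1)))
  if (length(idx) == 0) stop("no connection labelled ", label)
  idx
}

#' Simulate a network
#'
#' Advances all populations jointly with a fixed-step loop (compiled core).
#' The membrane equation is integrated with exponential Euler, holding the
#' synaptic conductances constant within each step: this is unconditionally
#' stable under the very large summed conductances that saturated
#' presynaptic populations produce, is exact for constant drive, and keeps
#' the potential inside the span of the reversal potentials. Synaptic
#' gating traces decay exactly on the step grid. Spikes generated at step n
#' affect synaptic currents from step n+1 onward; given a seed the result
#' is fully deterministic (the random stream is consumed only by membrane
#' noise, when enabled).
#'
#' @param net an [aim_network()].
#' @param input external input spikes for the source (IC) population: an
#'   `aim_ic_input` (see [encode_ic()]) or a data frame with columns
#'   `neuron`, `time` (ms). `NULL` for no input.
#' @param duration simulated time (ms).
#' @param dt time step (ms); must be well below the fastest synaptic rise
#'   time (`dt >= min tau_R` is rejected as unstable).
#' @param seed optional integer seed.
#' @param record character vector of population names whose membrane
#'   potential should be recorded.
#' @param v_stride record every `v_stride`-th step of voltage.
#' @return An object of class `aim_sim` with elements `spikes` (named list
#'   of data frames `neuron`, `time`), `voltages`, `duration`, `dt`,
#'   `channel_map`.
#' @export
simulate_network <- function(net, input = NULL, duration, dt = 0.01,
                             seed = NULL, record = character(0),
                             v_stride = 10L) {
  stopifnot(inherits(net, "aim_network"), duration > 0, dt > 0)
  tau_R_min <- min(vapply(net$conns, function(cn) cn$syn$tau_R, numeric(1)))
  if (dt >= tau_R_min)
    stop("dt = ", dt, " ms >= fastest synaptic rise time (", tau_R_min,
         " ms): unstable")
  if (!is.null(seed)) set.seed(seed)

  pn <- names(net$pops)
  ext <- vector("list", length(pn))
  cpp_pops <- vector("list", length(pn))
  for (i in seq_along(pn)) {
    p <- net$pops[[i]]
    if (p$source) {
      df <- ic_as_events(net, input, p)
      if (any(df$neuron < 1 | df$neuron > p$n))
        stop("input neuron index outside source population ", p$name)
      ext[[i]] <- list(neuron = as.integer(df$neuron),
                       time = as.numeric(df$time))
      cpp_pops[[i]] <- list(n = p$n, source = TRUE)
    } else {
      ext[[i]] <- list(neuron = integer(0), time = numeric(0))
      cpp_pops[[i]] <- list(n = p$n, source = FALSE, C = p$params$C,
                            g_leak = p$params$g_leak,
                            E_leak = p$params$E_leak,
                            V_thresh = p$params$V_thresh,
                            V_reset = p$params$V_reset,
                            noise = p$noise, i_app = p$i_app,
                            V0 = rep(p$params$E_leak, p$n))
    }
  }
  cpp_conns <- lapply(net$conns, function(cn) {
    list(pre = match(cn$pre, pn), post = match(cn$post, pn),
         g_syn = cn$syn$g_syn, tau_R = cn$syn$tau_R, tau_D = cn$syn$tau_D,
         E_syn = cn$syn$E_syn, W = cn$W, row_gain = cn$row_gain)
  })
  rec <- pn %in% record
  out <- lif_simulate_cpp(cpp_pops, cpp_conns, ext, duration, dt, rec,
                          as.integer(v_stride))
  spikes <- out$spikes
  names(spikes) <- pn
  volts <- out$voltages
  names(volts) <- pn
  volts <- volts[!vapply(volts, is.null, logical(1))]
  structure(list(spikes = spikes, voltages = volts, duration = duration,
                 dt = dt,
                 channel_map = lapply(net$pops, `[[`, "channel"),
                 grid = net$grid, n_lanes = net$n_lanes),
            class = "aim_sim")
}

#' @export
print.aim_sim <- function(x, ...) {
  cat("AIM simulation:", x$duration, "ms at dt =", x$dt, "ms\n")
  for (nm in names(x$spikes))
    cat(sprintf("  %-3s %d spikes\n", nm, nrow(x$spikes[[nm]])))
  invisible(x)
}

# map external input onto IC neuron indices (lane-major layout)
ic_as_events <- function(net, input, pop) {
  if (is.null(input)) return(data.frame(neuron = integer(0),
                                        time = numeric(0)))
  if (is.data.frame(input)) return(input)
  if (!inherits(input, "aim_ic_input")) stop("unsupported input type")
  n_ch <- net$grid$n
  if (net$grid$axis == "azimuth") {
    if (input$n_spatial != n_ch || input$n_freq != net$n_lanes)
      stop("channel-count mismatch: input is ", input$n_spatial, " x ",
           input$n_freq, " (spatial x frequency), network expects ",
           n_ch, " x ", net$n_lanes)
    neuron <- (input$spikes$freq - 1L) * n_ch + input$spikes$spatial
  } else {
    if (input$n_spatial != 1L || input$n_freq != n_ch)
      stop("channel-count mismatch: spectral network expects 1 x ", n_ch,
           " input, got ", input$n_spatial, " x ", input$n_freq)
    neuron <- input$spikes$freq
  }
  data.frame(neuron = as.integer(neuron), time = input$spikes$time)
}

#' Population firing rate over an interval
#'
#' @param sim an `aim_sim`.
#' @param pop population name.
#' @param from,to interval (ms); defaults to the whole simulation.
#' @param per_neuron if `TRUE`, return one rate per neuron.
#' @return firing rate(s) in spikes/s.
#' @export
firing_rate <- function(sim, pop, from = 0, to = sim$duration,
                        per_neuron = FALSE) {
  sp <- sim$spikes[[pop]]
  sp <- sp[sp$time > from & sp$time <= to, ]
  dur_s <- (to - from) / 1000
  if (!per_neuron) return(nrow(sp) / dur_s)
  n <- length(sim$channel_map[[pop]])
  as.numeric(table(factor(sp$neuron, levels = seq_len(n)))) / dur_s
}

#' Write a spike raster to delimited text
#'
#' One row per spike, columns `population_id`, `channel_index`,
#' `neuron_index`, `spike_time_ms` (3 decimals), comma separated with a
#' header line.
#'
#' @param sim an `aim_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(sim, path) {
  rows <- lapply(names(sim$spikes), function(nm) {
    sp <- sim$spikes[[nm]]
    if (nrow(sp) == 0) return(NULL)
    data.frame(population_id = nm,
               channel_index = sim$channel_map[[nm]][sp$neuron],
               neuron_index = sp$neuron,
               spike_time_ms = sprintf("%.3f", sp$time))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(population_id = character(0),
                     channel_index = integer(0), neuron_index = integer(0),
                     spike_time_ms = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike raster written by [write_spikes()]
#' @param path file path.
#' @return data frame with numeric `spike_time_ms`.
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$spike_time_ms <- as.numeric(df$spike_time_ms)
  df
}

#' Write recorded voltage traces
#'
#' Matrix text dump of a recorded population's membrane potential: first
#' column time (ms), one column per neuron.
#'
#' @param sim an `aim_sim` run with `record = pop`.
#' @param pop population name.
#' @param path output file.
#' @param v_stride the stride used at simulation time (for the time axis).
#' @return `path`, invisibly.
#' @export
write_voltages <- function(sim, pop, path, v_stride = 10L) {
  V <- sim$voltages[[pop]]
  if (is.null(V)) stop("population ", pop, " was not recorded")
  t <- seq(0, by = sim$dt * v_stride, length.out = ncol(V))
  df <- data.frame(time_ms = t, t(V))
  names(df)[-1] <- paste0("n", seq_len(nrow(V)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
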