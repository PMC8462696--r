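#' Cellular parameters of a leaky integrate-and-fire population
#'
#' Bundles the membrane parameters of one population. Defaults are the
#' standard cellular parameters used throughout the model: C = 1 nF,
#' g_leak = 0.1 uS (membrane time constant 10 ms), leak reversal -70 mV,
#' spike threshold -55 mV, reset -75 mV, displayed spike value +50 mV,
#' no tonic current and no noise.
#'
#' @param C membrane capacitance (nF); must be > 0.
#' @param g_leak leak conductance (uS); must be > 0.
#' @param E_leak leak reversal potential (mV).
#' @param V_thresh spike threshold (mV).
#' @param V_spike displayed spike value (mV); cosmetic only, it is reported
#'   in voltage traces at spike instants and never enters the dynamics.
#' @param V_reset post-spike reset value (mV); must satisfy
#'   `V_reset < V_thresh < V_spike`.
#' @param i_app tonic applied current (nA).
#' @param noise standard deviation of zero-mean white current noise (nA),
#'   drawn independently per neuron and per step; 0 disables noise.
#'
#' @return An object of class `cell_params` (a named list).
#' @examples
#' cell_params()                 # defaults
#' cell_params(i_app = 3)       # tonically active cell (~118 spikes/s)
#' @export
cell_params <- function(C = 1, g_leak = 0.1, E_leak = -70, V_thresh = -55,
                        V_spike = 50, V_reset = -75, i_app = 0, noise = 0) {
  stopifnot(C > 0, g_leak > 0, noise >= 0)
  if (!(V_reset < V_thresh && V_thresh < V_spike))
    stop("require V_reset < V_thresh < V_spike")
  structure(list(C = C, g_leak = g_leak, E_leak = E_leak,
                 V_thresh = V_thresh, V_spike = V_spike, V_reset = V_reset,
                 i_app = i_app, noise = noise),
            class = "cell_params")
}

#' Membrane time constant of a cell
#'
#' tau_m = C / g_leak, in ms (nF / uS).
#' @param params a [cell_params()] object.
#' @return time constant in ms.
#' @export
tau_m <- function(params) params$C / params$g_leak

#' Double-exponential synapse parameters
#'
#' @param g_syn peak conductance scale (uS); multiplies the raw
#'   double-exponential kernel, which is not peak-normalised.
#' @param tau_R rise time constant (ms).
#' @param tau_D decay time constant (ms); must exceed `tau_R`.
#' @param E_syn synaptic reversal potential (mV).
#' @return An object of class `synapse_params`.
#' @seealso [excitatory_synapse()], [inhibitory_synapse()] for the two
#'   presets used by every connection in the model.
#' @export
synapse_params <- function(g_syn, tau_R, tau_D, E_syn) {
  stopifnot(g_syn >= 0, tau_R > 0, tau_D > tau_R)
  structure(list(g_syn = g_syn, tau_R = tau_R, tau_D = tau_D, E_syn = E_syn),
            class = "synapse_params")
}

#' @rdname synapse_params
#' @details The excitatory preset has tau_R = 0.4 ms, tau_D = 2 ms,
#'   E_syn = 0 mV; the inhibitory preset has tau_R = 1 ms, tau_D = 10 ms,
#'   E_syn = -80 mV.
#' @export
excitatory_synapse <- function(g_syn = 1)
  synapse_params(g_syn, tau_R = 0.4, tau_D = 2, E_syn = 0)

#' @rdname synapse_params
#' @export
inhibitory_synapse <- function(g_syn = 1)
  synapse_params(g_syn, tau_R = 1, tau_D = 10, E_syn = -80)

#' Double-exponential conductance kernel
#'
#' Dimensionless synaptic gating variable as a function of time since a
#' presynaptic spike: `exp(-t/tau_D) - exp(-t/tau_R)` for t >= 0 and 0 for
#' t < 0 (unit step). The kernel is not normalised; its peak is below 1 and
#' depends on the time constants.
#'
#' @param t_since_spike time since the presynaptic spike (ms); vectorised.
#' @param params a [synapse_params()] object.
#' @return gating values, same length as `t_since_spike`.
#' @examples
#' conductance_kernel(0.805, excitatory_synapse())  # near the kernel peak
#' @export
conductance_kernel <- function(t_since_spike, params) {
  ifelse(t_since_spike >= 0,
         exp(-t_since_spike / params$tau_D) - exp(-t_since_spike / params$tau_R),
         0)
}

#' Time at which the conductance kernel peaks
#'
#' Closed form `tau_D tau_R / (tau_D - tau_R) * log(tau_D / tau_R)` from
#' setting the kernel derivative to zero.
#' @param params a [synapse_params()] object.
#' @return peak time in ms.
#' @export
kernel_peak_time <- function(params) {
  with(params, tau_D * tau_R / (tau_D - tau_R) * log(tau_D / tau_R))
}

#' One forward-Euler membrane update (no threshold logic)
#'
#' Advances membrane potentials by
#' `dV = dt * (g_leak (E_leak - V) - i_syn + i_app + noise)/C`.
#' Threshold crossing and reset are handled separately by
#' [detect_and_reset()]; this split mirrors the integration loop and makes
#' the subthreshold dynamics testable against the closed-form RC solution.
#'
#' @param V membrane potentials (mV), one per neuron.
#' @param params [cell_params()] for the population.
#' @param i_syn synaptic current per neuron (nA); positive values are
#'   hyperpolarising under the sign convention `i_syn = g (V - E_syn)`.
#' @param dt time step (ms), > 0.
#' @return updated potentials.
#' @export
membrane_step <- function(V, params, i_syn = 0, dt = 0.01) {
  stopifnot(dt > 0, all(is.finite(V)), all(is.finite(i_syn)))
  noise <- if (params$noise > 0) stats::rnorm(length(V), 0, params$noise) else 0
  V2 <- V + dt * (params$g_leak * (params$E_leak - V) - i_syn +
                    params$i_app + noise) / params$C
  if (any(!is.finite(V2)))
    stop("non-finite membrane potential after update; check parameters/dt")
  V2
}

#' Spike detection and reset
#'
#' Neurons whose potential exceeds the threshold record a spike at time `t`
#' and are reset to `V_reset` for the next step. There is no refractory
#' period: a neuron driven above threshold on consecutive steps spikes on
#' each of them.
#'
#' @param V membrane potentials (mV).
#' @param params [cell_params()].
#' @param t current time (ms), attached to the recorded spikes.
#' @return list with `V` (post-reset potentials), `spiked` (logical per
#'   neuron) and `display` (potentials with `V_spike` substituted at spike
#'   instants, for plotting voltage traces).
#' @export
detect_and_reset <- function(V, params, t = 0) {
  stopifnot(all(is.finite(V)))
  spiked <- V > params$V_thresh
  display <- V
  display[spiked] <- params$V_spike
  V[spiked] <- params$V_reset
  list(V = V, spiked = spiked, display = display, t = t)
}

#' Synaptic current onto a postsynaptic population
#'
#' Linear superposition of spike-triggered double-exponential kernels:
#' `i_j = g_syn * sum_i W[i,j] * sum_k kernel(t - t_ik) * (V_j - E_syn)`.
#' With this sign convention excitatory current is negative (inward) for
#' `V_j < E_syn = 0`. This direct event-sum form is the reference
#' implementation; the network simulator evaluates the same quantity
#' recursively with per-connection decay traces.
#'
#' @param pre_spikes list of numeric vectors, spike times (ms) per
#'   presynaptic neuron; all times must be `<= t`.
#' @param conn a [connection()] object (supplies synapse and weight mask).
#' @param V_post postsynaptic potentials (mV).
#' @param t evaluation time (ms).
#' @return current per postsynaptic neuron (nA).
#' @export
synaptic_current <- function(pre_spikes, conn, V_post, t) {
  W <- conn$W
  if (length(pre_spikes) != nrow(W))
    stop("pre_spikes length does not match weight-mask rows")
  if (length(V_post) != ncol(W))
    stop("V_post length does not match weight-mask columns")
  syn <- conn$syn
  k <- vapply(pre_spikes, function(ts) {
    if (length(ts) == 0) return(0)
    if (any(ts > t)) stop("spike times must not exceed t")
    sum(conductance_kernel(t - ts, syn))
  }, numeric(1))
  if (!is.null(conn$row_gain)) k <- k * conn$row_gain
  gv <- as.numeric(Matrix::crossprod(W, k))
  syn$g_syn * gv * (V_post - syn$E_syn)
}
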