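#' Initial state of the postsynaptic neuron
#'
#' Membrane at rest, threshold at rest, all conductances zero.
#'
#' @param params [neuron_params()].
#' @return An object of class `neuron_state`: a named list with fields `V`,
#'   `theta`, `g_ampa`, `g_nmda`, `g_adapt`.
#' @export
neuron_state <- function(params = neuron_params()) {
  structure(list(V = params$V_rest, theta = params$theta_rest,
                 g_ampa = 0, g_nmda = 0, g_adapt = 0),
            class = "neuron_state")
}

#' Advance the neuron by one time step
#'
#' Update order within a step: the fast conductance jumps by the summed
#' synaptic increments of spikes arriving in this step and then decays; the
#' slow conductance low-passes the fast one; the adaptation conductance
#' decays; the membrane integrates the combined excitatory and adaptation
#' currents (with an exponential integrator, since synchronized volleys
#' drive the total conductance far beyond the stability bound of an explicit
#' step); the threshold relaxes toward rest; finally the spike condition
#' `V >= theta` is tested. On a spike the membrane is reset, the threshold is
#' set to its post-spike value (the sole source of refractoriness) and the
#' adaptation conductance increments by `g_spike`.
#'
#' This scalar-step function is the reference implementation; the experiment
#' runners use an equivalent compiled loop.
#'
#' @param state A `neuron_state`.
#' @param presyn_spike_weights Numeric vector of conductance increments, one
#'   per presynaptic spike arriving in this step (may be empty).
#' @param params [neuron_params()].
#' @param dt Time step (s), nominally 1e-4.
#' @return A list with elements `state` (the new `neuron_state`) and `spiked`
#'   (logical).
#' @examples
#' st <- neuron_state()
#' step_neuron(st, numeric(0), neuron_params(), 1e-4)$spiked
#' @export
step_neuron <- function(state, presyn_spike_weights, params = neuron_params(),
                        dt = 1e-4) {
  for (nm in c("V", "theta", "g_ampa", "g_nmda", "g_adapt")) {
    if (!is.finite(state[[nm]]))
      abort(paste0("numerical divergence in neuron state variable '", nm, "'"))
  }
  p <- params
  g_ampa <- state$g_ampa + sum(presyn_spike_weights)
  g_ampa <- g_ampa - g_ampa * dt / p$tau_ampa
  g_nmda <- state$g_nmda + (g_ampa - state$g_nmda) * dt / p$tau_nmda
  g_adapt <- state$g_adapt - state$g_adapt * dt / p$tau_adapt
  g_exc <- p$beta_ampa_frac * g_ampa + (1 - p$beta_ampa_frac) * g_nmda
  # exponential integrator for the membrane: exact for conductances held
  # constant over the step and stable at arbitrarily large total conductance
  g_tot <- 1 + g_exc + g_adapt
  V_eq <- (p$V_rest + g_exc * p$V_exc + g_adapt * p$V_adapt) / g_tot
  V <- V_eq + (state$V - V_eq) * exp(-g_tot * dt / p$tau_m)
  theta <- state$theta + dt / p$tau_thr * (p$theta_rest - state$theta)
  spiked <- V >= theta
  if (spiked) {
    V <- p$V_rest
    theta <- p$theta_spike
    g_adapt <- g_adapt + p$g_spike
  }
  list(state = structure(list(V = V, theta = theta, g_ampa = g_ampa,
                              g_nmda = g_nmda, g_adapt = g_adapt),
                         class = "neuron_state"),
       spiked = spiked)
}
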