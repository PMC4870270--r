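#' Initial triplet-trace state for a set of synapses
#'
#' Holds the per-synapse presynaptic trace `x_plus`, the shared postsynaptic
#' traces `y_minus` (fast) and `y_triplet` (slow), and the per-synapse
#' co-activity low-pass `I_A`. All start at zero.
#'
#' @param n_synapses Number of synapses.
#' @return An object of class `trace_state`.
#' @export
trace_state <- function(n_synapses) {
  structure(list(x_plus = rep(0, n_synapses), y_minus = 0, y_triplet = 0,
                 I_A = rep(0, n_synapses)),
            class = "trace_state")
}

#' Plasticity-induction signals of the minimal triplet rule
#'
#' Potentiation is induced at postsynaptic spikes as
#' `A+ * x_plus * y_triplet`, where the slow postsynaptic trace is read just
#' before its own increment; depression at presynaptic spikes as
#' `A- * y_minus`. Call with the traces as they stand *before* the current
#' step's increments (see [update_traces()]), which realizes the
#' pre-increment read: a first-ever pre-post pairing yields zero
#' potentiation.
#'
#' @param state A `trace_state` (pre-increment values).
#' @param pre_spikes Logical vector, one element per synapse.
#' @param post_spike Logical scalar.
#' @param params [triplet_params()].
#' @return List with per-synapse numeric vectors `I_plus`, `I_minus`.
#' @export
induction <- function(state, pre_spikes, post_spike,
                      params = triplet_params()) {
  n <- length(state$x_plus)
  I_plus <- if (isTRUE(post_spike))
    params$A_plus * state$x_plus * state$y_triplet else rep(0, n)
  I_minus <- params$A_minus * state$y_minus * as.numeric(pre_spikes)
  list(I_plus = I_plus, I_minus = I_minus)
}

#' Increment and decay the triplet traces for one step
#'
#' Each trace increments by 1 at its own spike (`x_plus` at presynaptic
#' spikes, `y_minus` and `y_triplet` at postsynaptic spikes) and then decays
#' over `dt` with its time constant. Between spikes the decay is the exact
#' exponential, which keeps the traces identical to the event-driven
#' closed form.
#'
#' @param state A `trace_state`.
#' @param pre_spikes Logical vector per synapse.
#' @param post_spike Logical scalar.
#' @param dt Time step (s).
#' @param params [triplet_params()].
#' @return The updated `trace_state`.
#' @export
update_traces <- function(state, pre_spikes, post_spike, dt,
                          params = triplet_params()) {
  x <- state$x_plus + as.numeric(pre_spikes)
  ym <- state$y_minus + as.numeric(isTRUE(post_spike))
  yt <- state$y_triplet + as.numeric(isTRUE(post_spike))
  state$x_plus <- x * exp(-dt / params$tau_x)
  state$y_minus <- ym * exp(-dt / params$tau_y)
  state$y_triplet <- yt * exp(-dt / params$tau_triplet)
  state
}

#' Drive for the weight variable from the triplet inductions
#'
#' `I_w = I+ (1 + [z - w]+)(1 - w) - I- (1 + [w - z]+)(1 + w)` with
#' `[x]+ = x H(x)`. Saturates by construction at `w = 1` (potentiation term)
#' and `w = -1` (depression term).
#'
#' @param I_plus,I_minus Per-synapse induction magnitudes.
#' @param w,z Per-synapse weight and scaffold variables.
#' @return Per-synapse drive `I_w`.
#' @examples
#' drive_weight(1e-4, 0, w = -1, z = 1) # 6e-4
#' @export
drive_weight <- function(I_plus, I_minus, w, z) {
  I_plus * (1 + pmax(z - w, 0)) * (1 - w) -
    I_minus * (1 + pmax(w - z, 0)) * (1 + w)
}

#' Drive for the gate accumulator from the triplet inductions
#'
#' `I_gamma = (I+ H(w - z) + I- H(z - w)) (1 - gamma)`, with the convention
#' `H(0) = 1`, so at `w = z` both inductions contribute.
#'
#' @param I_plus,I_minus Per-synapse induction magnitudes.
#' @param w,z,gamma Per-synapse state variables.
#' @return Per-synapse drive `I_gamma`.
#' @export
drive_gate <- function(I_plus, I_minus, w, z, gamma) {
  (I_plus * (w >= z) + I_minus * (z >= w)) * (1 - gamma)
}

#' Leaky integration of the per-synapse co-activity
#'
#' The co-activity `I_A` low-passes the summed triplet inductions with time
#' constant `tau_A`. Inductions enter as direct per-event increments (the
#' delta-impulse convention used throughout the synapse layer), so the
#' stationary level under periodic stimulation is
#' `per-pulse induction * rate * tau_A`.
#'
#' @param state A `trace_state`.
#' @param I_plus,I_minus Per-synapse inductions accumulated over the step.
#' @param dt Time step (s).
#' @param params [triplet_params()].
#' @return The updated `trace_state`.
#' @export
update_coactivity <- function(state, I_plus, I_minus, dt,
                              params = triplet_params()) {
  state$I_A <- state$I_A * exp(-dt / params$tau_A) + I_plus + I_minus
  state
}
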