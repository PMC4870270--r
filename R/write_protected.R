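#' Restoring force of the bistable double-well potential
#'
#' `f(x) = -x (x - 1)(x + 1) = x - x^3`, the negative gradient of the quartic
#' double-well `U(x) = x^4/4 - x^2/2` with stable fixed points at -1 and +1.
#'
#' @param x Numeric.
#' @return `f(x)`, same shape as `x`.
#' @examples
#' bistable_force(c(-1, 0, 0.5, 1)) # 0, 0, 0.375, 0
#' @export
bistable_force <- function(x) -x * (x - 1) * (x + 1)

#' Initialize a population of write-protected synapses
#'
#' A fraction of synapses starts in the big, consolidated state
#' `(w, T, z) = (1, 1, 1)` and bound to a stabilizing entity; the rest start
#' small `(-1, -1, -1)` and unbound. Gate accumulators start at zero.
#'
#' @param n Number of synapses.
#' @param frac_big Fraction initialized big (default one third).
#' @param seed Integer seed for the random assignment.
#' @return A tibble with one row per synapse and columns `w`, `T`, `z`,
#'   `gamma`, `b` (bound flag, 0/1), `big` (initial consolidation flag).
#' @examples
#' sum(init_synapses(200, seed = 1)$b) # 67
#' @export
init_synapses <- function(n, frac_big = 1 / 3, seed = 1) {
  stopifnot(n >= 1, frac_big >= 0, frac_big <= 1)
  n_big <- round(n * frac_big)
  big <- rep(FALSE, n)
  if (n_big > 0)
    with_seed(seed, big[sample.int(n, n_big)] <- TRUE)
  v <- ifelse(big, 1, -1)
  tibble::tibble(w = v, T = v, z = v, gamma = 0, b = as.integer(big),
                 big = big)
}

#' Map a weight variable to its synaptic conductance increment
#'
#' Affine map from `w` in `[-1, 1]` to `[g0 w_-, g0 w_+]` with
#' `w_+ = k_w w_-`: `dg = g0 (w_- + (w + 1)(w_+ - w_-)/2)`.
#'
#' @param w Weight variable(s).
#' @param params [wp_params()].
#' @return Conductance increment(s) per presynaptic spike.
#' @examples
#' conductance_from_weight(c(-1, 1), wp_params(g0 = 1)) # 0.05, 0.15
#' @export
conductance_from_weight <- function(w, params = wp_params()) {
  w_plus <- params$k_w * params$w_minus
  params$g0 * (params$w_minus + (w + 1) * (w_plus - params$w_minus) / 2)
}

#' Update the global plasticity-product gate
#'
#' `dp/dt = D k_up (1 - p) - k_down p`: the availability of plasticity
#' related products rises quickly while the dopamine signal `D` is on and
#' decays slowly (time constant `1/k_down`) when it is off.
#'
#' @param gate List with fields `p` (in `[0, 1]`) and `D` (0 or 1).
#' @param dt Time step (s).
#' @param params [wp_params()].
#' @return The updated gate list.
#' @export
update_p <- function(gate, dt, params = wp_params()) {
  stopifnot(gate$D %in% c(0, 1))
  gate$p <- gate$p + dt * (gate$D * params$k_up * (1 - gate$p) -
                             params$k_down * gate$p)
  gate
}

#' Euler-Maruyama step of the write-protected synapse variables
#'
#' Advances the coupled bistable weight `w`, tag `T` and scaffold `z` of each
#' synapse by one step, including the weight-tag gate `G = H(gamma -
#' theta_gamma)` (evaluated on the pre-update `gamma`), the plasticity-product
#' coupling `p`, and the binding-dependent destabilization `a_b/tau_z H(z)(b -
#' 1)` that pushes an unbound consolidated scaffold out of its well. Triplet
#' drives enter as per-step impulses: `I_w` adds directly to `w` and `kappa *
#' I_gamma` to `gamma`. Noise enters as `sigma * sqrt(dt) * N(0, 1)`; in the
#' `"activity_gated_noise"` variant the `w` and `T` noise terms are multiplied
#' by `H(I_A - theta_act)` while the `z` noise is never gated.
#'
#' @param state Tibble of synapse states as from [init_synapses()].
#' @param gate List with the plasticity-product availability `p` in `[0, 1]`.
#' @param drives List with per-synapse accumulated `I_plus`, `I_minus` and
#'   current `I_A`.
#' @param params [wp_params()].
#' @param noise Optional 3-column matrix of standard normal draws (columns
#'   for `w`, `T`, `z`); drawn internally when `NULL`.
#' @param dt Time step (s), nominally 0.1.
#' @param variant `"original"` or `"activity_gated_noise"`.
#' @return The updated synapse tibble.
#' @export
step_synapse <- function(state, gate, drives, params = wp_params(),
                         noise = NULL, dt = params$dt,
                         variant = c("original", "activity_gated_noise")) {
  variant <- match.arg(variant)
  n <- nrow(state)
  if (is.null(noise)) noise <- matrix(rnorm(3 * n), ncol = 3)
  p <- gate$p
  I_plus <- drives$I_plus
  I_minus <- drives$I_minus
  I_A <- drives$I_A %||% rep(0, n)
  w <- state$w; Tv <- state$T; z <- state$z; gam <- state$gamma
  b <- state$b
  I_g <- drive_gate(I_plus, I_minus, w, z, gam)
  G <- as.numeric(gam >= params$theta_gamma)
  ngate <- if (variant == "activity_gated_noise")
    as.numeric(I_A >= params$theta_act) else 1
  sq <- params$sigma * sqrt(dt)
  w_new <- w + dt * (bistable_force(w) / params$tau_w +
                       params$a_Tw / (4 * params$tau_w) * (1 - G) * (Tv - w)) +
    ngate * sq * noise[, 1]
  # impulse drives; large accumulated impulses are applied in saturating
  # sub-chunks so the weight cannot overshoot its well
  K <- pmax(1, ceiling((I_plus + I_minus) / 0.05))
  for (j in seq_along(w_new)) {
    if (I_plus[j] + I_minus[j] <= 0) next
    for (k in seq_len(K[j]))
      w_new[j] <- w_new[j] + drive_weight(I_plus[j] / K[j], I_minus[j] / K[j],
                                          w_new[j], z[j])
  }
  T_new <- Tv + dt * (bistable_force(Tv) / params$tau_T +
                        params$a_wT / (4 * params$tau_T) * G * (w - Tv) +
                        params$a_zT / (4 * params$tau_T) * (1 - p) * (z - Tv)) +
    ngate * sq * noise[, 2]
  z_new <- z + dt * (bistable_force(z) / params$tau_z +
                       params$a_Tz / (4 * params$tau_z) * p * (Tv - z) +
                       params$a_b / params$tau_z * (z >= 0) * (b - 1)) +
    sq * noise[, 3]
  gam_new <- pmin(pmax(gam + params$kappa * I_g - gam * dt / params$tau_gamma,
                       0), 1)
  bad <- which(!is.finite(w_new) | !is.finite(T_new) | !is.finite(z_new))
  if (length(bad))
    abort(paste0("numerical divergence in synapse ", bad[1]))
  state$w <- w_new; state$T <- T_new; state$z <- z_new; state$gamma <- gam_new
  state
}
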