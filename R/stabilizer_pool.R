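#' Initial state of the stabilizer pool
#'
#' The reservoir of immune entities starts empty; bound entities are counted
#' through `n_bound` and the susceptible pool holds the remainder of the
#' total.
#'
#' @param params [pool_params()].
#' @param n_bound Number of entities initially bound to synapses.
#' @return An object of class `pool_state` with integer fields `N_A`
#'   (free susceptible), `N_A_star` (free immune, the reservoir), `n_bound`,
#'   and logical `psi_active`.
#' @export
pool_state <- function(params = pool_params("wp"), n_bound = 0) {
  stopifnot(n_bound >= 0, n_bound <= params$N_A_tot)
  structure(list(N_A = params$N_A_tot - n_bound, N_A_star = 0,
                 n_bound = n_bound, psi_active = FALSE),
            class = "pool_state")
}

#' Activity-dependent unbinding rate of a bound stabilizer
#'
#' `k(I_A) = k0 + m / (1 + exp((I0 - I_A) / r))`: a logistic increase from
#' the minimal rate `k0` toward `k0 + m`, half-maximal at the co-activity
#' `I0` (which differs between unbinding into the susceptible pool, `k2`, and
#' into the immune reservoir, `k4`).
#'
#' @param I_A Co-activity value(s), >= 0.
#' @param which `"k2"` or `"k4"`.
#' @param params [pool_params()].
#' @return Unbinding rate(s) in s^-1.
#' @examples
#' p <- pool_params("wp")
#' unbinding_rate(p$I0_2, "k2", p) # k0 + m/2 = 1.5e-3
#' @export
unbinding_rate <- function(I_A, which = c("k2", "k4"),
                           params = pool_params("wp")) {
  which <- match.arg(which)
  I0 <- if (which == "k2") params$I0_2 else params$I0_4
  params$k0 + params$m / (1 + exp((I0 - I_A) / params$r))
}

#' One stochastic binding/unbinding sweep over all synapses
#'
#' Processes the synapses in a fresh uniformly random order. An unbound
#' consolidated synapse (`is_big`, the scaffold test `z >= 0`) binds with
#' probability `(k1 N_A + k3 N_A*) dt`, drawing from the susceptible pool
#' with probability `k1 N_A / (k1 N_A + k3 N_A*)` and from the reservoir
#' otherwise. A bound synapse unbinds with probability `(k2 + k4) dt`,
#' releasing into the susceptible pool with probability `k2 / (k2 + k4)`
#' (the entity is discarded if PSI is active) and into the reservoir
#' otherwise. First-order probabilities must stay below 1.
#'
#' This is the reference implementation; the experiment runners use an
#' equivalent compiled sweep.
#'
#' @param pool A `pool_state`.
#' @param synapses Tibble/data frame with per-synapse columns `is_big`
#'   (logical), `b` (0/1 bound flag) and `I_A` (co-activity). An optional
#'   `force_unbound` column keeps flagged synapses unbound.
#' @param params [pool_params()].
#' @param dt Time step (s).
#' @return List with the updated `pool` and the updated bound-flag vector
#'   `b`.
#' @export
step_pool <- function(pool, synapses, params = pool_params("wp"), dt = 0.1) {
  b <- as.integer(synapses$b)
  is_big <- as.logical(synapses$is_big)
  I_A <- synapses$I_A
  fu <- if ("force_unbound" %in% names(synapses))
    as.logical(synapses$force_unbound) else rep(FALSE, length(b))
  N_A <- pool$N_A; N_As <- pool$N_A_star
  for (j in sample.int(length(b))) {
    if (b[j] == 0L) {
      if (!is_big[j] || fu[j]) next
      r_on <- params$k1 * N_A + params$k3 * N_As
      p_bind <- r_on * dt
      if (p_bind > 1)
        abort("binding probability exceeds 1; use a smaller time step")
      if (r_on > 0 && runif(1) < p_bind) {
        b[j] <- 1L
        if (runif(1) < params$k1 * N_A / r_on) N_A <- N_A - 1
        else N_As <- N_As - 1
      }
    } else {
      k2 <- unbinding_rate(I_A[j], "k2", params)
      k4 <- unbinding_rate(I_A[j], "k4", params)
      p_unbind <- (k2 + k4) * dt
      if (p_unbind > 1)
        abort("unbinding probability exceeds 1; use a smaller time step")
      if (runif(1) < p_unbind) {
        b[j] <- 0L
        if (runif(1) < k2 / (k2 + k4)) {
          if (!pool$psi_active) N_A <- N_A + 1
        } else N_As <- N_As + 1
      }
    }
  }
  pool$N_A <- N_A; pool$N_A_star <- N_As; pool$n_bound <- sum(b)
  list(pool = pool, b = b)
}

#' Switch protein synthesis inhibition on or off
#'
#' Activation empties the susceptible pool (`N_A <- 0`); during PSI any
#' entity released into the susceptible pool degrades immediately.
#' Deactivation replenishes the susceptible pool to
#' `N_A_tot - N_A_star - n_bound`, restoring the total entity count (a
#' homeostatic assumption). Repeated activation is idempotent.
#'
#' @param pool A `pool_state`.
#' @param active Logical.
#' @param params [pool_params()].
#' @return The updated `pool_state`.
#' @examples
#' p <- set_psi(pool_state(), TRUE)
#' p$N_A # 0
#' @export
set_psi <- function(pool, active, params = pool_params("wp")) {
  if (active) {
    pool$N_A <- 0
    pool$psi_active <- TRUE
  } else {
    if (pool$psi_active)
      pool$N_A <- max(0, params$N_A_tot - pool$N_A_star - pool$n_bound)
    pool$psi_active <- FALSE
  }
  pool
}
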