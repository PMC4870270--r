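#' Population state of the seven-state synapse model
#'
#' @param params [sb_params()].
#' @return An object of class `sb_population`: integer counts `N` per state
#'   (1-7), a `pool_state`, and the HFS clock `t_hfs` (`NA` before
#'   induction).
#' @export
sb_population <- function(params = sb_params()) {
  N <- c(0, 0, params$n_weak0, params$n_strong0, 0, 0, 0)
  structure(list(N = N, pool = pool_state(params$pool, n_bound = 0),
                 t_hfs = NA_real_),
            class = "sb_population")
}

#' Relative field EPSP of the state-based population
#'
#' Weighted population strength: weak states (1-3) carry weight 1, strong
#' states (4-7) weight 2, normalized so that the initial 800 weak / 200
#' strong mixture reads 100%:
#' `fEPSP = (N1 + N2 + N3 + 2 (N4 + ... + N7)) / 1200 * 100`.
#'
#' @param counts Integer vector of length 7 (counts per state).
#' @return Percent fEPSP.
#' @examples
#' fepsp(c(0, 0, 800, 200, 0, 0, 0)) # 100
#' @export
fepsp <- function(counts) {
  stopifnot(length(counts) == 7, all(counts >= 0))
  (sum(counts[1:3]) + 2 * sum(counts[4:7])) / 1200 * 100
}

#' Time-dependent transition rates after LTP induction
#'
#' After HFS at `t0`, the strong-basal to intermediate rate follows
#' `p(t) = (t - t0)/50min * exp(1 - (t - t0)/10min)` per minute and the
#' intermediate to stable rate `c(t) = (t - t0)/30min * exp(1 - (t -
#' t0)/30min)` per minute; at the induction instant itself an alpha pulse
#' moves all weak-basal synapses to the strong-basal state.
#'
#' @param t_since_hfs Time since induction (s), >= 0.
#' @param params [sb_params()].
#' @return List with `p_rate` and `c_rate` (s^-1) and `alpha_pulse` (logical
#'   indicator of the instantaneous induction pulse at `t_since_hfs == 0`).
#' @examples
#' hfs_rates(600)$p_rate * 60 # 0.2 per minute at +10 min
#' @export
hfs_rates <- function(t_since_hfs, params = sb_params()) {
  stopifnot(all(t_since_hfs >= 0))
  p_rate <- t_since_hfs / params$p_denom *
    exp(1 - t_since_hfs / params$p_tau) * params$rate_unit
  c_rate <- t_since_hfs / params$c_denom *
    exp(1 - t_since_hfs / params$c_tau) * params$rate_unit
  list(p_rate = p_rate, c_rate = c_rate, alpha_pulse = t_since_hfs == 0)
}

#' Apply the instantaneous LTP-induction pulse
#'
#' Moves every weak-basal (state 3) synapse to the strong-basal state 4 and
#' starts the clocks of the time-dependent rates `p(t)` and `c(t)`;
#' thereafter the baseline weak-to-strong rate is `alpha_post_hfs`. Applying
#' HFS again restarts the clocks.
#'
#' @param pop An `sb_population`.
#' @param t0 Induction time (s).
#' @return The updated population.
#' @export
apply_hfs <- function(pop, t0) {
  pop$N[4] <- pop$N[4] + pop$N[3]
  pop$N[3] <- 0L
  pop$t_hfs <- t0
  pop
}

#' One stochastic step of the seven-state population
#'
#' Each synapse makes at most one transition per step. Because all rates are
#' global (the model has no per-synapse activity), synapses are exchangeable
#' and the per-synapse scheme is simulated exactly on the state counts with
#' sequential binomial draws. Stabilizer binding (6 to 7) and unbinding (7 to
#' 6) run on the finer `pool_dt` substep through the shared pool kinetics;
#' the decay of state 7 (rate `tau_r`, the slowest process) releases the
#' bound entity into the susceptible pool, where it degrades if PSI is
#' active. In the `"activity_gated_beta"` variant the strong-to-weak basal
#' rate `beta` is multiplied by `H(I_A - theta_act)`.
#'
#' This is the reference implementation; [run_state_based()] uses an
#' equivalent compiled loop.
#'
#' @param pop An `sb_population`.
#' @param t Current time (s).
#' @param I_A Global filtered activity (from the reduced model's filter).
#' @param psi_active Logical.
#' @param params [sb_params()].
#' @param dt State step (s).
#' @param variant `"original"` or `"activity_gated_beta"`.
#' @return The updated `sb_population`.
#' @export
step_population <- function(pop, t, I_A, psi_active, params = sb_params(),
                            dt = params$dt,
                            variant = c("original", "activity_gated_beta")) {
  variant <- match.arg(variant)
  N <- pop$N
  pool <- pop$pool
  if (psi_active && !pool$psi_active) pool <- set_psi(pool, TRUE, params$pool)
  if (!psi_active && pool$psi_active) {
    pool$n_bound <- N[7]
    pool <- set_psi(pool, FALSE, params$pool)
  }
  post <- !is.na(pop$t_hfs) && t >= pop$t_hfs
  alpha <- if (post) params$alpha_post_hfs else params$alpha
  rr <- if (post) hfs_rates(t - pop$t_hfs, params)
        else list(p_rate = 0, c_rate = 0)
  beta <- params$beta *
    if (variant == "activity_gated_beta") as.numeric(I_A >= params$theta_act)
    else 1
  draw <- function(n, p) if (n <= 0 || p <= 0) 0L else rbinom(1, n, min(p, 1))
  d13 <- draw(N[1], params$tau_l * dt)
  d23 <- draw(N[2], params$tau_e * dt)
  d34 <- draw(N[3], alpha * dt)
  d43 <- draw(N[4], beta * dt)
  d45 <- draw(N[4] - d43, rr$p_rate * dt / (1 - beta * dt))
  d54 <- draw(N[5], params$tau_e * dt)
  d56 <- draw(N[5] - d54, rr$c_rate * dt / (1 - params$tau_e * dt))
  d6x <- draw(N[6], params$tau_l * dt)
  d7x <- draw(N[7], params$tau_r * dt)
  N[1] <- N[1] - d13
  N[2] <- N[2] - d23
  N[3] <- N[3] + d13 + d23 - d34 + d43
  N[4] <- N[4] + d34 - d43 - d45 + d54
  N[5] <- N[5] + d45 - d54 - d56
  N[6] <- N[6] + d56 - d6x
  N[7] <- N[7] - d7x
  if (params$six_to_three) N[3] <- N[3] + d6x + d7x
  else N[4] <- N[4] + d6x + d7x
  if (!pool$psi_active) pool$N_A <- pool$N_A + d7x
  # stabilizer exchange between states 6 and 7 on the pool substep
  nsub <- max(1L, round(dt / params$pool_dt))
  dts <- dt / nsub
  pp <- params$pool
  k2 <- unbinding_rate(I_A, "k2", pp)
  k4 <- unbinding_rate(I_A, "k4", pp)
  for (s in seq_len(nsub)) {
    r_on <- pp$k1 * pool$N_A + pp$k3 * pool$N_A_star
    if (r_on * dts > 1 || (k2 + k4) * dts > 1)
      abort("pool transition probability exceeds 1; use a smaller pool_dt")
    binds <- draw(N[6], r_on * dts)
    unbinds <- draw(N[7], (k2 + k4) * dts)
    from_A <- if (binds > 0 && r_on > 0)
      draw(binds, pp$k1 * pool$N_A / r_on) else 0L
    from_A <- min(from_A, pool$N_A)
    from_As <- min(binds - from_A, pool$N_A_star)
    bound <- from_A + from_As
    N[6] <- N[6] - bound; N[7] <- N[7] + bound
    pool$N_A <- pool$N_A - from_A
    pool$N_A_star <- pool$N_A_star - from_As
    to_A <- draw(unbinds, k2 / (k2 + k4))
    N[7] <- N[7] - unbinds; N[6] <- N[6] + unbinds
    if (!pool$psi_active) pool$N_A <- pool$N_A + to_A
    pool$N_A_star <- pool$N_A_star + unbinds - to_A
  }
  pool$n_bound <- N[7]
  pop$N <- N
  pop$pool <- pool
  pop
}
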