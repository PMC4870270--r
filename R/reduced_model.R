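#' Initial state of the reduced reservoir model
#'
#' @param n_ASyn Mean number of bound synapses.
#' @param n_A_star Mean reservoir size (starts at 0 by default).
#' @param N_big Number of consolidated synapses.
#' @param I_A Filtered global activity.
#' @param params [reduced_params()] (sets the history-buffer span
#'   `phi`).
#' @return An object of class `reduced_state`; the history buffer is primed
#'   flat at `n_ASyn`.
#' @export
reduced_state <- function(n_ASyn = 0, n_A_star = 0, N_big = 0, I_A = 0,
                          params = reduced_params()) {
  stopifnot(n_ASyn >= 0, n_A_star >= 0, N_big >= 0, n_ASyn <= N_big + 1e-9)
  L <- round(params$phi / params$dt) + 1
  structure(list(n_ASyn = n_ASyn, n_A_star = n_A_star, N_big = N_big,
                 I_A = I_A, history = rep(n_ASyn, L)),
            class = "reduced_state")
}

#' Low-pass filter of the global stimulation activity
#'
#' `tau_A dI_A/dt = -I_A + omega * sum_k delta(t - t_k)`: exponential decay
#' with `tau_A`, plus a jump of `omega / tau_A` per stimulation pulse. Under
#' sustained periodic stimulation at rate `f` the mean settles at
#' `omega * f`.
#'
#' @param I_A Current filtered activity.
#' @param n_pulses Number of stimulation pulses falling in this step.
#' @param params [reduced_params()].
#' @param dt Time step (s).
#' @return The updated `I_A`.
#' @export
filter_activity <- function(I_A, n_pulses, params = reduced_params(),
                            dt = params$dt) {
  I_A * exp(-dt / params$tau_A) + n_pulses * params$omega / params$tau_A
}

#' Filtered-activity time series from pulse times
#'
#' Evaluates the activity filter on a regular grid given the nominal
#' stimulation pulse times; used to drive the reduced and state-based models.
#'
#' @param pulses Sorted pulse times (s).
#' @param duration Total duration (s).
#' @param dt Grid step (s).
#' @param params [reduced_params()].
#' @param I_A0 Initial value.
#' @return Numeric vector of `I_A` at times `0, dt, ..., duration`.
#' @export
filter_activity_series <- function(pulses, duration, dt,
                                   params = reduced_params(), I_A0 = 0) {
  n <- round(duration / dt)
  counts <- tabulate(pmin(pmax(ceiling(pulses / dt), 1), n), nbins = n)
  a <- exp(-dt / params$tau_A)
  jumps <- counts * params$omega / params$tau_A
  out <- stats::filter(jumps + c(I_A0 * a, rep(0, n - 1)), a,
                       method = "recursive")
  c(I_A0, as.numeric(out))
}

#' One Euler step of the reduced two-dimensional reservoir model
#'
#' Mean-field dynamics of the bound-synapse count and the immune reservoir:
#' \deqn{dn_{ASyn}/dt = -(\hat k_4 + \hat k_2) n_{ASyn} +
#'   (k_1 n_A + k_3 n_{A^*}) (N_{big} - n_{ASyn})}
#' \deqn{dn_{A^*}/dt = -k_3 n_{A^*} (N_{big} - n_{ASyn}) + \hat k_4 n_{ASyn}}
#' with `n_A = N_A_tot - n_ASyn - n_A*`, forced to zero while PSI is active,
#' and the unbinding rates evaluated at the current filtered activity. The
#' number of consolidated synapses then decays per [update_Nbig()].
#'
#' @param state A `reduced_state`.
#' @param psi_active Logical.
#' @param params [reduced_params()].
#' @param dt Time step (s).
#' @return The updated `reduced_state`.
#' @export
step_reduced <- function(state, psi_active, params = reduced_params(),
                         dt = params$dt) {
  pp <- params$pool
  n_A <- if (psi_active) 0 else
    max(0, pp$N_A_tot - state$n_ASyn - state$n_A_star)
  k2 <- unbinding_rate(state$I_A, "k2", pp)
  k4 <- unbinding_rate(state$I_A, "k4", pp)
  dnS <- -(k2 + k4) * state$n_ASyn +
    (pp$k1 * n_A + pp$k3 * state$n_A_star) * (state$N_big - state$n_ASyn)
  dnR <- -pp$k3 * state$n_A_star * (state$N_big - state$n_ASyn) +
    k4 * state$n_ASyn
  state$n_ASyn <- state$n_ASyn + dt * dnS
  state$n_A_star <- state$n_A_star + dt * dnR
  if (state$n_ASyn < 0 || state$n_A_star < 0) {
    warning("reduced model state clamped at 0", call. = FALSE)
    state$n_ASyn <- max(state$n_ASyn, 0)
    state$n_A_star <- max(state$n_A_star, 0)
  }
  state$history <- c(state$history[-1], state$n_ASyn)
  update_Nbig(state, params, dt)
}

#' Delayed-slope decay of the number of consolidated synapses
#'
#' The consolidated count follows the decay of the bound count with delay
#' `phi`: the slope of `n_ASyn`, measured as a finite difference over the
#' window `eta` and read `phi` seconds ago, is applied to `N_big` only when
#' it is steeper (more negative) than the threshold `theta_big`.
#'
#' @param state A `reduced_state` whose `history` field spans at least
#'   `phi` seconds (no-op during warm-up, i.e. states created with a flat
#'   history buffer are unaffected until genuine decay arrives).
#' @param params [reduced_params()].
#' @param dt Time step (s).
#' @return The updated `reduced_state`.
#' @export
update_Nbig <- function(state, params = reduced_params(), dt = params$dt) {
  L <- length(state$history)
  k_eta <- round(params$eta / params$dt)
  if (L < k_eta + 1) return(state)
  s <- (state$history[1 + k_eta] - state$history[1]) / params$eta
  if (s <= params$theta_big)
    state$N_big <- max(0, state$N_big + dt * s)
  state
}

#' Initialize the reduced model from a detailed-simulation snapshot
#'
#' The detailed write-protected model is run through the initiation phase
#' (background stimulation with LTP induction, then a pause); its state at
#' the end of that phase seeds the reduced model: consolidated count, bound
#' count, reservoir size and mean co-activity. The history buffer is primed
#' flat at the bound count.
#'
#' @param snapshot Named list with fields `N_big`, `n_bound`, `N_A_star`,
#'   `I_A` (as produced by [run_full()] with `snapshot_t`).
#' @param params [reduced_params()].
#' @return A `reduced_state`.
#' @export
handoff_from_full <- function(snapshot, params = reduced_params()) {
  need <- c("N_big", "n_bound", "N_A_star", "I_A")
  miss <- setdiff(need, names(snapshot))
  if (length(miss))
    abort(paste0("snapshot is missing fields: ", paste(miss, collapse = ", ")))
  reduced_state(n_ASyn = snapshot$n_bound, n_A_star = snapshot$N_A_star,
                N_big = snapshot$N_big, I_A = snapshot$I_A, params = params)
}

run_reduced_core <- function(state, duration, pulses, psi_window, params,
                             record_dt = 10) {
  res <- cpp_run_reduced(duration, params$dt, as.numeric(pulses),
                         as.numeric(psi_window %||% numeric(0)),
                         unclass(params$pool), params$phi, params$theta_big,
                         params$eta, params$omega, params$tau_A,
                         state$n_ASyn, state$n_A_star, state$N_big,
                         state$I_A, record_dt)
  list(series = tibble::tibble(t = res$t, n_ASyn = res$n_ASyn,
                               n_A_star = res$n_A_star, n_A = res$n_A,
                               N_big = res$N_big, I_A = res$I_A),
       final = res$final)
}

#' Map the boundary conditions of reconsolidation
#'
#' For each combination of stimulation duration and PSI duration (both
#' windows centered at the same time point), the reduced model is run from a
#' common post-initiation state and the remaining fraction of consolidated
#' synapses at the end of the protocol, relative to the consolidated count at
#' the start of the mapped phase, is recorded.
#'
#' @param stim_durations,psi_durations Numeric vectors of window durations
#'   (s); the default 26-point grids span 0 to 2.5 h.
#' @param init A `reduced_state` at the start of the mapped phase (e.g. from
#'   [handoff_from_full()]).
#' @param params [reduced_params()].
#' @param t_center Center of both windows (s after the start of `init`).
#' @param t_end End of the mapped phase (s).
#' @param lfs_rate Stimulation rate within the stimulation window (Hz).
#' @return A tibble with columns `stim_duration`, `psi_duration` and
#'   `remaining_fraction`, of class `sr_boundary_map`.
#' @seealso [autoplot.sr_boundary_map()]
#' @export
map_boundary <- function(stim_durations = seq(0, 9000, length.out = 26),
                         psi_durations = seq(0, 9000, length.out = 26),
                         init, params = reduced_params(),
                         t_center = 5400, t_end = 13200, lfs_rate = 0.1) {
  grid <- tidyr::expand_grid(stim_duration = stim_durations,
                             psi_duration = psi_durations)
  if (nrow(grid) == 0) {
    return(structure(tibble::tibble(stim_duration = numeric(0),
                                    psi_duration = numeric(0),
                                    remaining_fraction = numeric(0)),
                     class = c("sr_boundary_map", "tbl_df", "tbl", "data.frame")))
  }
  N0 <- init$N_big
  frac <- purrr::pmap_dbl(grid, function(stim_duration, psi_duration) {
    pulses <- if (stim_duration > 0)
      nominal_pulses(stim_block(t_center - stim_duration / 2,
                                t_center + stim_duration / 2, lfs_rate))
    else numeric(0)
    psi <- if (psi_duration > 0)
      c(t_center - psi_duration / 2, t_center + psi_duration / 2) else NULL
    res <- run_reduced_core(init, t_end, pulses, psi, params,
                            record_dt = t_end)
    res$final$N_big / N0
  })
  out <- dplyr::mutate(grid, remaining_fraction = frac)
  class(out) <- c("sr_boundary_map", class(out))
  out
}

#' Heat map of the reconsolidation boundary conditions
#'
#' @param object An `sr_boundary_map` from [map_boundary()].
#' @param ... Unused.
#' @return A ggplot: stimulation duration against PSI duration, filled by the
#'   remaining fraction of consolidated synapses.
#' @export
autoplot.sr_boundary_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$psi_duration / 3600,
                                       y = .data$stim_duration / 3600,
                                       fill = .data$remaining_fraction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "PSI duration (h)", y = "stimulation duration (h)",
                  fill = "remaining\nfraction") +
    ggplot2::theme_minimal()
}

#' Write a boundary map as a TSV matrix
#'
#' Rows are stimulation durations, columns PSI durations, both in seconds.
#'
#' @param map An `sr_boundary_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary_map <- function(map, path) {
  wide <- tidyr::pivot_wider(map, names_from = "psi_duration",
                             values_from = "remaining_fraction")
  readr::write_tsv(wide, path)
  invisible(path)
}
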