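#' Parameters of the postsynaptic leaky integrate-and-fire neuron
#'
#' Conductance-based LIF neuron with an adaptive threshold and spike-triggered
#' adaptation. All conductances are dimensionless multiples of the leak
#' conductance (the membrane equation has unit leak), so no capacitance
#' parameter exists. Times are in seconds, voltages in mV.
#'
#' @param tau_m Membrane time constant (s).
#' @param V_rest Resting (and reset) potential (mV).
#' @param V_exc Excitatory reversal potential (mV).
#' @param V_adapt Reversal potential of the adaptation conductance (mV). The
#'   adaptation current implements spike-triggered self-inhibition, so its
#'   reversal sits below rest.
#' @param tau_thr Relaxation time of the dynamic threshold (s).
#' @param theta_rest Resting threshold (mV).
#' @param theta_spike Threshold value imposed right after a spike (mV); its
#'   decay back to `theta_rest` is the only source of refractoriness.
#' @param tau_ampa Decay time of the fast (AMPA) conductance (s).
#' @param tau_nmda Time constant of the slow (NMDA) low-pass of the AMPA
#'   conductance (s).
#' @param beta_ampa_frac Relative contribution of the fast conductance to the
#'   combined excitatory conductance, in `[0, 1]`.
#' @param tau_adapt Decay time of the adaptation conductance (s).
#' @param g_spike Increment of the adaptation conductance per postsynaptic
#'   spike (dimensionless).
#'
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' neuron_params()
#' @export
neuron_params <- function(tau_m = 20e-3, V_rest = -70, V_exc = 0,
                          V_adapt = -80, tau_thr = 2e-3, theta_rest = -50,
                          theta_spike = 100, tau_ampa = 5e-3,
                          tau_nmda = 100e-3, beta_ampa_frac = 0.5,
                          tau_adapt = 250e-3, g_spike = 10) {
  stopifnot(tau_m > 0, tau_thr > 0, tau_ampa > 0, tau_nmda > 0, tau_adapt > 0,
            beta_ampa_frac >= 0, beta_ampa_frac <= 1)
  structure(list(tau_m = tau_m, V_rest = V_rest, V_exc = V_exc,
                 V_adapt = V_adapt, tau_thr = tau_thr, theta_rest = theta_rest,
                 theta_spike = theta_spike, tau_ampa = tau_ampa,
                 tau_nmda = tau_nmda, beta_ampa_frac = beta_ampa_frac,
                 tau_adapt = tau_adapt, g_spike = g_spike),
            class = "neuron_params")
}

#' Parameters of the minimal triplet STDP rule
#'
#' The minimal (reduced-parameter) triplet rule: a presynaptic trace `x+`, a
#' fast postsynaptic trace `y-`, and a slow postsynaptic trace `y_triplet`.
#' Potentiation is induced at postsynaptic spikes in proportion to
#' `x+ * y_triplet` (read just before its own increment), depression at
#' presynaptic spikes in proportion to `y-`.
#'
#' @param A_plus Potentiation amplitude (dimensionless).
#' @param A_minus Depression amplitude (dimensionless).
#' @param tau_x Decay time of the presynaptic trace (s).
#' @param tau_y Decay time of the fast postsynaptic trace (s).
#' @param tau_triplet Decay time of the slow postsynaptic trace (s).
#' @param tau_A Decay time of the per-synapse co-activity low-pass (s).
#'
#' @return An object of class `triplet_params`.
#' @export
triplet_params <- function(A_plus = 5e-4, A_minus = 2e-4, tau_x = 16.8e-3,
                           tau_y = 33.7e-3, tau_triplet = 114e-3,
                           tau_A = 150) {
  stopifnot(A_plus > 0, A_minus > 0, tau_x > 0, tau_y > 0, tau_triplet > 0,
            tau_A > 0)
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_x = tau_x,
                 tau_y = tau_y, tau_triplet = tau_triplet, tau_A = tau_A),
            class = "triplet_params")
}

#' Parameters of the write-protected synapse model
#'
#' Three coupled bistable variables per synapse (weight `w`, tag `T`, scaffold
#' `z`, each with stable states near -1 and +1), a gating accumulator `gamma`
#' coupling weight to tag, a global plasticity-product gate `p` driven by
#' dopamine, and a binding-dependent destabilization of the scaffold of
#' strength `a_b` that acts only while the synapse holds no stabilizing
#' entity.
#'
#' @param tau_w,tau_T,tau_z Relaxation times of weight, tag and scaffold (s).
#' @param a_wT,a_Tz Coupling strengths weight->tag and tag->scaffold (one
#'   shared printed value).
#' @param a_Tw Coupling tag->weight.
#' @param a_zT Coupling scaffold->tag.
#' @param a_b Destabilization strength acting on an unbound consolidated
#'   scaffold.
#' @param sigma Noise intensity (s^-1/2); enters Euler-Maruyama updates as
#'   `sigma * sqrt(dt) * N(0,1)`.
#' @param tau_gamma Decay time of the gate accumulator (s).
#' @param theta_gamma Gate threshold on `gamma`, in (0, 1).
#' @param kappa Unit-carrying constant (s) multiplying the gate drive.
#' @param k_up,k_down Rise and decay rates of the plasticity-product gate `p`
#'   (s^-1).
#' @param theta_act Activity threshold on the co-activity `I_A` used by the
#'   activity-gated-noise variant.
#' @param w_minus Conductance fraction of a fully depressed synapse.
#' @param k_w Ratio of the fully potentiated to fully depressed conductance.
#' @param g0 Synaptic conductance scale. The default was fixed once by
#'   [calibrate_g0()] so that a low-frequency stimulation volley elicits a
#'   small postsynaptic burst placing the per-synapse co-activity between the
#'   two unbinding half-activations; see the methods vignette.
#' @param dt Synapse-model time step (s).
#'
#' @return An object of class `wp_params`.
#' @seealso [step_synapse()], [init_synapses()], [calibrate_g0()]
#' @export
wp_params <- function(tau_w = 200, tau_T = 200, tau_z = 200, a_wT = 3.5,
                      a_Tz = 3.5, a_Tw = 1.3, a_zT = 0.95, a_b = 1,
                      sigma = 1e-2, tau_gamma = 600, theta_gamma = 0.37,
                      kappa = 1, k_up = 1, k_down = 1 / 2000,
                      theta_act = 0.01, w_minus = 0.05, k_w = 3, g0 = 20.4,
                      dt = 0.1) {
  stopifnot(tau_w > 0, tau_T > 0, tau_z > 0, sigma >= 0, tau_gamma > 0,
            theta_gamma > 0, theta_gamma < 1, k_up > 0, k_down > 0,
            w_minus > 0, k_w > 0, g0 > 0, dt > 0)
  structure(list(tau_w = tau_w, tau_T = tau_T, tau_z = tau_z, a_wT = a_wT,
                 a_Tz = a_Tz, a_Tw = a_Tw, a_zT = a_zT, a_b = a_b,
                 sigma = sigma, tau_gamma = tau_gamma,
                 theta_gamma = theta_gamma, kappa = kappa, k_up = k_up,
                 k_down = k_down, theta_act = theta_act, w_minus = w_minus,
                 k_w = k_w, g0 = g0, dt = dt),
            class = "wp_params")
}

#' Parameters of the stabilizer pool kinetics
#'
#' A finite pool of `N_A_tot` stabilizing entities shared by all synapses of
#' the postsynaptic neuron. Free entities are either susceptible to protein
#' synthesis inhibition (count `N_A`) or immune to it (the reservoir,
#' `N_A_star`). A consolidated (big-scaffold) synapse binds one entity at
#' rate `k1 * N_A + k3 * N_A_star` and, once bound, releases it at the
#' activity-dependent rates `k2(I_A)` (into the susceptible pool) plus
#' `k4(I_A)` (into the reservoir); both follow the same logistic law
#' `k0 + m / (1 + exp((I0 - I_A) / r))` with different half-activations.
#'
#' @param model `"wp"` for the write-protected column of rates, `"sb"` for the
#'   state-based column.
#' @param k1 Binding rate per susceptible entity (s^-1).
#' @param k3 Binding rate per immune entity (s^-1).
#' @param k0 Minimal unbinding rate (s^-1).
#' @param m Range of the unbinding rate; `k0 + m` is its maximum (s^-1).
#' @param r Slope of the logistic activity dependence.
#' @param I0_2 Half-activation of the unbinding into the susceptible pool.
#' @param I0_4 Half-activation of the unbinding into the reservoir.
#' @param N_A_tot Total number of stabilizing entities.
#'
#' @return An object of class `pool_params`.
#' @seealso [unbinding_rate()], [step_pool()], [set_psi()]
#' @export
pool_params <- function(model = c("wp", "sb"), k1 = NULL, k3 = NULL,
                        k0 = NULL, m = NULL, r = 3e-3, I0_2 = NULL,
                        I0_4 = 4.5e-2, N_A_tot = 2e4) {
  model <- match.arg(model)
  # the state-based rate column is tabulated per minute, like the rest of
  # the state-based model's rates; stored here in s^-1
  def <- if (model == "wp") {
    list(k1 = 1 / 10000, k3 = 1 / 1750, k0 = 5e-4, m = 2e-3, I0_2 = 5.7e-2)
  } else {
    list(k1 = 1 / 3000 / 60, k3 = (1 / 3000) * (10000 / 1750) / 60,
         k0 = 0.02 / 60, m = 0.25 / 60,
         I0_2 = 5.8e-2)
  }
  k1 <- k1 %||% def$k1
  k3 <- k3 %||% def$k3
  k0 <- k0 %||% def$k0
  m <- m %||% def$m
  I0_2 <- I0_2 %||% def$I0_2
  stopifnot(k1 >= 0, k3 >= 0, k0 >= 0, m >= 0, r > 0, N_A_tot >= 1)
  structure(list(model = model, k1 = k1, k3 = k3, k0 = k0, m = m, r = r,
                 I0_2 = I0_2, I0_4 = I0_4, N_A_tot = N_A_tot),
            class = "pool_params")
}

#' Parameters of the reduced two-dimensional reservoir model
#'
#' Mean-field description of the number of bound synapses and the reservoir of
#' immune stabilizers, driven by a low-pass filtered global activity and a
#' delayed-slope rule for the decay of the number of consolidated synapses.
#'
#' @param phi Delay between the decay of the bound count and the decay of the
#'   consolidated count (s).
#' @param theta_big Slope threshold (s^-1): the consolidated count decays only
#'   when the delayed slope of the bound count is steeper (more negative) than
#'   this value. The default (-80 per hour) separates the collapse of the
#'   bound count after reservoir depletion (about -0.2 per second) from
#'   ordinary cycling drift (about -0.002 per second); a per-second reading
#'   of the tabulated magnitude would exceed the fastest possible collapse
#'   and the rule would never fire.
#' @param eta Window of the finite-difference slope (s).
#' @param omega Increment parameter of the activity filter: each stimulation
#'   pulse raises the filtered activity by `omega / tau_A`, so sustained
#'   stimulation at rate `f` settles at `omega * f`. The default places the
#'   0.1 Hz steady state at 0.054, between the two unbinding half-activations
#'   (0.045 and 0.057) — the operating point at which stimulation
#'   strongly accelerates unbinding into the reservoir while only mildly
#'   accelerating unbinding into the susceptible pool, which is what lets
#'   the four slice paradigms separate; see the methods vignette.
#' @param tau_A Time constant of the activity filter (s).
#' @param dt Integration step (s).
#' @param pool [pool_params()] (write-protected column by default).
#'
#' @return An object of class `reduced_params`.
#' @seealso [run_reduced()], [map_boundary()]
#' @export
reduced_params <- function(phi = 72, theta_big = -80 / 3600, eta = 10,
                           omega = 0.54,
                           tau_A = 150, dt = 0.1, pool = pool_params("wp")) {
  stopifnot(phi >= 0, eta > 0, tau_A > 0, dt > 0, dt <= 1,
            inherits(pool, "pool_params"))
  structure(list(phi = phi, theta_big = theta_big, eta = eta, omega = omega,
                 tau_A = tau_A, dt = dt, pool = pool),
            class = "reduced_params")
}

#' Parameters of the seven-state Markov model of synaptic strength
#'
#' States 1-3 are weak (stable, intermediate, basal), states 4-6 strong
#' (basal, intermediate, stable); state 7 is the stabilizer-bound strong
#' state, entered from state 6 through binding and left through unbinding.
#' All rates are stored in s^-1 (Table values printed per minute are
#' converted).
#'
#' @param alpha Basal weak->strong rate (s^-1).
#' @param beta Basal strong->weak rate (s^-1).
#' @param tau_e Intermediate->basal decay rate (s^-1), both branches.
#' @param tau_l Stable->basal decay rate (s^-1). In the extension it also
#'   governs the decay of state 6, which is therefore much less stable than
#'   the new bound state 7.
#' @param tau_r Decay rate of the bound state 7 (s^-1), the slowest process.
#' @param alpha_post_hfs Baseline weak->strong rate after LTP induction
#'   (s^-1).
#' @param n_synapses Number of simulated synapses.
#' @param n_weak0,n_strong0 Initial counts in the weak and strong basal
#'   states.
#' @param six_to_three If `TRUE`, the fast decay of state 6 targets the weak
#'   basal state 3 directly; the default sends it to the strong basal state 4.
#' @param p_denom,p_tau Shape constants (s) of the time-dependent 4->5 rate
#'   after LTP induction, `p(t) = (t - t0)/p_denom * exp(1 - (t - t0)/p_tau)`
#'   in units of `rate_unit`.
#' @param c_denom,c_tau Shape constants (s) of the 5->6 rate, same form.
#' @param rate_unit Unit of the `p`/`c` rate shapes (s^-1); the printed
#'   shapes are per minute, so the default is `1/60`.
#' @param theta_act Activity threshold for the activity-gated `beta` variant.
#' @param dt State-model time step (s).
#' @param pool_dt Substep (s) on which the stabilizer binding/unbinding is
#'   integrated; the state-based rate column is too fast for first-order
#'   probabilities at the 1 s state step.
#' @param pool [pool_params()] with the state-based column.
#'
#' @return An object of class `sb_params`.
#' @seealso [run_state_based()], [step_population()], [fepsp()]
#' @export
sb_params <- function(alpha = 0.017 / 60, beta = 0.067 / 60,
                      tau_e = 0.017 / 60, tau_l = 0.01 / 60,
                      tau_r = 1e-4 / 60, alpha_post_hfs = 1 / 3600,
                      n_synapses = 1000, n_weak0 = 800, n_strong0 = 200,
                      six_to_three = FALSE, theta_act = 0.01,
                      p_denom = 3000, p_tau = 600, c_denom = 1800,
                      c_tau = 1800, rate_unit = 1 / 60, dt = 1,
                      pool_dt = 0.5, pool = pool_params("sb")) {
  stopifnot(alpha >= 0, beta >= 0, tau_e >= 0, tau_l >= 0, tau_r >= 0,
            n_weak0 + n_strong0 == n_synapses, dt > 0, pool_dt > 0,
            p_denom > 0, p_tau > 0, c_denom > 0, c_tau > 0,
            inherits(pool, "pool_params"))
  structure(list(alpha = alpha, beta = beta, tau_e = tau_e, tau_l = tau_l,
                 tau_r = tau_r, alpha_post_hfs = alpha_post_hfs,
                 n_synapses = n_synapses, n_weak0 = n_weak0,
                 n_strong0 = n_strong0, six_to_three = six_to_three,
                 theta_act = theta_act, p_denom = p_denom, p_tau = p_tau,
                 c_denom = c_denom, c_tau = c_tau, rate_unit = rate_unit,
                 dt = dt, pool_dt = pool_dt, pool = pool),
            class = "sb_params")
}

#' Compress the slow time scale of a model configuration
#'
#' Rescales the slow subsystem of a configuration by a factor `lambda < 1`
#' (durations multiplied by `lambda`, slow time constants by `lambda`, rates
#' by `1/lambda`, noise intensity by `1/sqrt(lambda)`), leaving the
#' millisecond-scale neuron and trace dynamics untouched. Stimulation rates
#' scale by `1/lambda` through [compress_time.sr_protocol()], so the filtered
#' activity level, the pool fluxes per protocol, and the Euler-Maruyama law of
#' the synapse variables are invariant: a compressed run is a time-rescaled
#' version of the full-scale run, preserving the persist-versus-decay outcome.
#' Used by the fast experiment presets; the methods vignette derives the
#' mapping.
#'
#' @param x A parameter object or protocol.
#' @param lambda Compression factor in (0, 1]; e.g. `0.1` turns a 10 h
#'   protocol into 1 h.
#' @return An object of the same class with rescaled fields.
#' @export
compress_time <- function(x, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda > 0, lambda <= 1)
  UseMethod("compress_time")
}

#' @export
compress_time.wp_params <- function(x, lambda) {
  x$tau_w <- x$tau_w * lambda
  x$tau_T <- x$tau_T * lambda
  x$tau_z <- x$tau_z * lambda
  x$tau_gamma <- x$tau_gamma * lambda
  x$k_down <- x$k_down / lambda
  x$sigma <- x$sigma / sqrt(lambda)
  x$dt <- x$dt * lambda
  x
}

#' @export
compress_time.pool_params <- function(x, lambda) {
  for (f in c("k0", "k1", "k3", "m")) x[[f]] <- x[[f]] / lambda
  x
}

#' @export
compress_time.triplet_params <- function(x, lambda) {
  x$tau_A <- x$tau_A * lambda
  x
}

#' @export
compress_time.reduced_params <- function(x, lambda) {
  x$phi <- x$phi * lambda
  x$eta <- x$eta * lambda
  x$theta_big <- x$theta_big / lambda
  x$omega <- x$omega * lambda
  x$tau_A <- x$tau_A * lambda
  x$dt <- x$dt * lambda
  x$pool <- compress_time(x$pool, lambda)
  x
}

#' @export
compress_time.sb_params <- function(x, lambda) {
  for (f in c("alpha", "beta", "tau_e", "tau_l", "tau_r", "alpha_post_hfs",
              "rate_unit"))
    x[[f]] <- x[[f]] / lambda
  for (f in c("p_denom", "p_tau", "c_denom", "c_tau"))
    x[[f]] <- x[[f]] * lambda
  x$dt <- x$dt * lambda
  x$pool_dt <- x$pool_dt * lambda
  x$pool <- compress_time(x$pool, lambda)
  x
}

#' Scale the stabilizer pool with the synapse population
#'
#' A smaller synapse population is a faithful replica of the full system only
#' if the pool scales with it: the total entity count multiplies by `factor`
#' while the per-entity binding rates divide by it, leaving every per-synapse
#' binding and unbinding flux unchanged (the reservoir's rebinding draw
#' fraction depends on absolute counts, so fixing the pool while shrinking
#' the population would distort the reservoir budget).
#'
#' @param pool A [pool_params()].
#' @param factor Ratio of the reduced synapse count to the reference count.
#' @return The rescaled `pool_params`.
#' @export
scale_pool_size <- function(pool, factor) {
  stopifnot(inherits(pool, "pool_params"), factor > 0)
  pool$N_A_tot <- pool$N_A_tot * factor
  pool$k1 <- pool$k1 / factor
  pool$k3 <- pool$k3 / factor
  pool
}
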