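# event-driven analytic oracle: exact exponentials between spikes
trace_at <- function(spike_times, read_t, tau) {
  sum(exp(-(read_t - spike_times[spike_times < read_t]) / tau))
}

run_traces <- function(pre_t, post_t, t_end, dt = 1e-4, n_syn = 1,
                       params = triplet_params()) {
  tr <- trace_state(n_syn)
  pre_steps <- round(pre_t / dt)
  post_steps <- round(post_t / dt)
  acc_p <- rep(0, n_syn)
  acc_m <- rep(0, n_syn)
  for (i in seq_len(round(t_end / dt))) {
    pre <- rep(i %in% pre_steps, n_syn)
    post <- i %in% post_steps
    ind <- induction(tr, pre, post, params)
    acc_p <- acc_p + ind$I_plus
    acc_m <- acc_m + ind$I_minus
    tr <- update_traces(tr, pre, post, dt, params)
    tr <- update_coactivity(tr, ind$I_plus, ind$I_minus, dt, params)
  }
  list(traces = tr, I_plus = acc_p, I_minus = acc_m)
}

test_that("traces decay exponentially and increment at their own spikes", {
  p <- triplet_params()
  # one spike, read 10 ms later (the stepper decays through the spike step,
  # so the read lags by at most one step)
  out <- run_traces(pre_t = 0.001, post_t = numeric(0), t_end = 0.011)
  expect_equal(out$traces$x_plus, exp(-0.010 / p$tau_x),
               tolerance = 2 * 1e-4 / p$tau_x)

  out2 <- run_traces(numeric(0), post_t = 0.001, t_end = 0.001 + p$tau_y)
  expect_equal(out2$traces$y_minus, exp(-1), tolerance = 2 * 1e-4 / p$tau_y)
  expect_true(all(unlist(out2$traces) >= 0))
})

test_that("induction magnitudes match the event-driven closed form", {
  p <- triplet_params()
  # first-ever pre->post pairing: the slow trace is read before its own
  # increment, so potentiation is exactly zero
  out0 <- run_traces(pre_t = 0.001, post_t = 0.002, t_end = 0.003)
  expect_equal(out0$I_plus, 0)

  # post at 0, pre at 10 ms, post at 20 ms
  out <- run_traces(pre_t = 0.011, post_t = c(0.001, 0.021), t_end = 0.022)
  expected_Ip <- p$A_plus * exp(-0.010 / p$tau_x) * exp(-0.020 / p$tau_triplet)
  expect_equal(out$I_plus, expected_Ip, tolerance = 1e-6)
  expect_equal(out$I_plus, 2.314e-4, tolerance = 1e-3)

  # post at 0, pre at 10 ms: depression reads the fast postsynaptic trace
  expected_Im <- p$A_minus * exp(-0.010 / p$tau_y)
  expect_equal(out$I_minus, expected_Im, tolerance = 1e-6)
  expect_equal(out$I_minus, 1.486e-4, tolerance = 1e-3)

  # against the generic oracle for a longer random spike pattern
  set.seed(9)
  pre <- sort(runif(20, 0, 0.5))
  post <- sort(runif(20, 0, 0.5))
  pre <- round(pre / 1e-4) * 1e-4
  post <- round(post / 1e-4) * 1e-4
  post <- setdiff(post, pre)  # keep events on distinct steps for the oracle
  out <- run_traces(pre, post, 0.51)
  oracle_Ip <- sum(sapply(post, function(t)
    p$A_plus * trace_at(pre, t, p$tau_x) * trace_at(post, t, p$tau_triplet)))
  oracle_Im <- sum(sapply(pre, function(t)
    p$A_minus * trace_at(post, t, p$tau_y)))
  expect_equal(out$I_plus, oracle_Ip, tolerance = 1e-6)
  expect_equal(out$I_minus, oracle_Im, tolerance = 1e-6)
})

test_that("only postsynaptic spikes potentiate; only presynaptic depress", {
  out_pre <- run_traces(pre_t = seq(0.001, 0.1, by = 0.01),
                        post_t = numeric(0), t_end = 0.11)
  expect_equal(out_pre$I_plus, 0)
  expect_equal(out_pre$I_minus, 0)  # no postsynaptic trace to read
  out_post <- run_traces(numeric(0), post_t = seq(0.001, 0.1, by = 0.01),
                         t_end = 0.11)
  expect_equal(out_post$I_minus, 0)
  expect_equal(out_post$I_plus, 0)  # no presynaptic trace to read
})

test_that("weight and gate drives follow the rectified coupling forms", {
  expect_equal(drive_weight(0, 0, w = 0.3, z = -0.5), 0)
  expect_equal(drive_weight(1e-3, 0, w = 1, z = 2), 0)  # saturation at w = 1
  expect_equal(drive_weight(1e-4, 0, w = -1, z = 1), 6e-4)
  expect_equal(drive_weight(0, 1e-4, w = -1, z = 0), 0)  # saturation at w = -1
  # vectorized over synapses
  expect_equal(drive_weight(c(1e-4, 0), c(0, 1e-4), w = c(-1, 1), z = c(1, 0)),
               c(6e-4, -1e-4 * 2 * 2))

  expect_equal(drive_gate(1e-4, 2e-4, w = 0, z = 1, gamma = 1), 0)
  expect_equal(drive_gate(1e-4, 0, w = 0.5, z = 0, gamma = 0), 1e-4)
  # tie w = z: H(0) = 1 on both sides, so both inductions pass
  expect_equal(drive_gate(1e-4, 2e-4, w = 0.2, z = 0.2, gamma = 0), 3e-4)
})

test_that("co-activity integrates inductions with the impulse convention", {
  p <- triplet_params()
  tr <- trace_state(1)
  tr$I_A <- 1
  for (i in seq_len(round(p$tau_A / 0.1)))
    tr <- update_coactivity(tr, 0, 0, dt = 0.1, p)
  expect_equal(tr$I_A, exp(-1), tolerance = 1e-9)

  # constant induction flux c: steady state tau_A * c
  dt <- 0.1
  flux <- 2e-5  # per second
  tr <- trace_state(1)
  for (i in seq_len(round(20 * p$tau_A / dt)))
    tr <- update_coactivity(tr, flux * dt, 0, dt, p)
  expect_equal(tr$I_A, p$tau_A * flux, tolerance = 1e-3)

  expect_equal(trace_state(5)$I_A, rep(0, 5))
})
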