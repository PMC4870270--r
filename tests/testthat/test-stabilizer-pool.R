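test_that("the unbinding rate follows the logistic activity law", {
  p <- pool_params("wp")
  expect_equal(unbinding_rate(p$I0_2, "k2", p), p$k0 + p$m / 2)
  expect_equal(unbinding_rate(p$I0_2, "k2", p), 1.5e-3)
  expect_equal(unbinding_rate(0, "k2", p), p$k0, tolerance = 1e-6)
  expect_equal(unbinding_rate(10, "k4", p), p$k0 + p$m, tolerance = 1e-9)
  expect_equal(unbinding_rate(p$I0_4, "k4", p), p$k0 + p$m / 2)
  # k4's half-activation sits below k2's: activity favors the reservoir
  expect_gt(unbinding_rate(0.05, "k4", p), unbinding_rate(0.05, "k2", p))
})

test_that("the stochastic sweep conserves entities and ignores small synapses", {
  p <- pool_params("wp", N_A_tot = 500)
  pool <- pool_state(p, n_bound = 0)
  syn <- tibble::tibble(is_big = rep(FALSE, 20), b = 0L, I_A = 0)
  set.seed(1)
  out <- step_pool(pool, syn, p, dt = 0.1)
  expect_identical(out$pool$N_A, pool$N_A)
  expect_identical(out$b, syn$b)

  # with big synapses, total count is conserved at every sweep without PSI
  syn <- tibble::tibble(is_big = TRUE, b = rep(c(1L, 0L), 10), I_A = 0.05)
  pool <- pool_state(p, n_bound = sum(syn$b))
  set.seed(2)
  for (i in 1:200) {
    out <- step_pool(pool, syn, p, dt = 0.1)
    pool <- out$pool
    syn$b <- out$b
    expect_equal(pool$N_A + pool$N_A_star + sum(syn$b), p$N_A_tot)
    expect_equal(pool$n_bound, sum(syn$b))
  }

  # a force_unbound synapse never rebinds
  syn2 <- tibble::tibble(is_big = TRUE, b = 0L, I_A = 0,
                         force_unbound = TRUE)
  set.seed(3)
  for (i in 1:50)
    expect_equal(step_pool(pool_state(p), syn2, p, 0.1)$b, 0L)
})

test_that("probability overflow is refused with advice on the step size", {
  p <- pool_params("wp", k1 = 1)  # absurd binding rate
  syn <- tibble::tibble(is_big = TRUE, b = 0L, I_A = 0)
  expect_error(step_pool(pool_state(p), syn, p, dt = 0.1), "smaller time step")
})

test_that("PSI empties, discards and replenishes the susceptible pool", {
  p <- pool_params("wp")
  pool <- pool_state(p, n_bound = 120)
  pool$N_A_star <- 300
  pool$N_A <- pool$N_A - 300
  on <- set_psi(pool, TRUE, p)
  expect_equal(on$N_A, 0)
  expect_true(on$psi_active)
  expect_identical(set_psi(on, TRUE, p), on)  # idempotent

  # entities released into the susceptible pool degrade during PSI
  syn <- tibble::tibble(is_big = TRUE, b = rep(1L, 120),
                        I_A = 10)  # maximal unbinding
  set.seed(4)
  pool2 <- on
  for (i in 1:50) {
    out <- step_pool(pool2, syn, p, dt = 0.1)
    pool2 <- out$pool
    syn$b <- out$b
    expect_equal(pool2$N_A, 0)
  }
  expect_lt(sum(syn$b), 120)

  off <- set_psi(pool2, FALSE, p)
  expect_equal(off$N_A, p$N_A_tot - pool2$N_A_star - sum(syn$b))
  # the worked conservation example
  ex <- structure(list(N_A = 0, N_A_star = 300, n_bound = 120,
                       psi_active = TRUE), class = "pool_state")
  expect_equal(set_psi(ex, FALSE, p)$N_A, 2e4 - 420)
})

test_that("a single synapse reaches the two-state Markov equilibrium", {
  # frozen, balanced rates: k1 = k3 keeps the on-rate constant at
  # k1 * N_A_tot regardless of which pool the entity sits in
  p <- pool_params("wp", k1 = 0.05, k3 = 0.05, k0 = 0.25, m = 0,
                   N_A_tot = 20)
  r_on <- p$k1 * p$N_A_tot          # 1 / s
  r_off <- 2 * p$k0                 # k2 + k4 = 0.5 / s
  set.seed(11)
  out <- cpp_run_pool(2e4, 0.1, 1L, 0, unclass(p), FALSE, 0L,
                      record_dt = 2e4)
  expect_equal(out$mean_bound_fraction, r_on / (r_on + r_off),
               tolerance = 0.03)
})

test_that("reference and compiled sweeps agree in distribution", {
  p <- pool_params("wp", N_A_tot = 1000)
  n <- 40
  reps <- 60
  horizon <- 80
  run_r <- function(seed) {
    set.seed(seed)
    pool <- pool_state(p, n_bound = 0)
    syn <- tibble::tibble(is_big = TRUE, b = rep(0L, n), I_A = 0.05)
    for (i in seq_len(horizon)) {
      out <- step_pool(pool, syn, p, dt = 0.1)
      pool <- out$pool
      syn$b <- out$b
    }
    sum(syn$b)
  }
  r_counts <- vapply(seq_len(reps), run_r, numeric(1))
  set.seed(99)
  c_counts <- vapply(seq_len(reps), function(i) {
    out <- cpp_run_pool(horizon * 0.1, 0.1, as.integer(n), 0.05, unclass(p),
                        FALSE, integer(n), record_dt = horizon * 0.1)
    utils::tail(out$n_bound, 1)
  }, numeric(1))
  expect_lt(abs(mean(r_counts) - mean(c_counts)),
            3 * sqrt(var(r_counts) / reps + var(c_counts) / reps))
})
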