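no_drive <- function(n) list(I_plus = rep(0, n), I_minus = rep(0, n),
                             I_A = rep(0, n))

test_that("the double-well force has the right fixed points and symmetry", {
  expect_equal(bistable_force(c(-1, 0, 1)), c(0, 0, 0))
  expect_equal(bistable_force(0.5), 0.375)
  x <- seq(-2, 2, by = 0.1)
  expect_equal(bistable_force(-x), -bistable_force(x))
})

test_that("initialization splits big/bound and small/unbound synapses", {
  syn <- init_synapses(200, frac_big = 1 / 3, seed = 4)
  expect_equal(sum(syn$big), 67)
  expect_equal(syn$b, as.integer(syn$big))  # initially big <=> bound
  expect_true(all(syn$w[syn$big] == 1 & syn$z[syn$big] == 1))
  expect_true(all(syn$w[!syn$big] == -1 & syn$T[!syn$big] == -1))
  expect_equal(syn$gamma, rep(0, 200))

  expect_equal(sum(init_synapses(50, 0, seed = 1)$b), 0)
  expect_identical(init_synapses(80, 0.25, seed = 9),
                   init_synapses(80, 0.25, seed = 9))
})

test_that("the weight-to-conductance map is the stated affine law", {
  p <- wp_params(g0 = 1)
  expect_equal(conductance_from_weight(-1, p), 0.05)
  expect_equal(conductance_from_weight(1, p), 0.15)
  expect_equal(conductance_from_weight(0, p), 0.10)
  p2 <- wp_params(g0 = 7, w_minus = 0.1, k_w = 2)
  expect_equal(conductance_from_weight(c(-1, 1), p2), 7 * c(0.1, 0.2))
})

test_that("the plasticity-product gate follows its first-order kinetics", {
  p <- wp_params()
  g <- list(p = 0, D = 0)
  for (i in 1:100) g <- update_p(g, 1, p)
  expect_equal(g$p, 0)

  g <- list(p = 0, D = 1)
  for (i in 1:6000) g <- update_p(g, 0.01, p)
  expect_equal(g$p, 1 - exp(-60 * (1 + 1 / 2000)), tolerance = 1e-3)
  expect_equal(round(g$p, 3), 1)

  g$D <- 0
  for (i in 1:200000) g <- update_p(g, 0.01, p)  # 2000 s = one decay time
  expect_equal(g$p, (1 - exp(-60 * (1 + 1 / 2000))) * exp(-1),
               tolerance = 2e-3)
})

test_that("noiseless bound synapses sit at the corners of the triple well", {
  p <- wp_params(sigma = 0)
  for (corner in c(-1, 1)) {
    st <- tibble::tibble(w = corner, T = corner, z = corner, gamma = 0,
                         b = 1L, big = corner > 0)
    for (i in 1:50)
      st <- step_synapse(st, gate = list(p = 0.5), no_drive(1), p,
                         noise = matrix(0, 1, 3))
    expect_equal(c(st$w, st$T, st$z), rep(corner, 3), tolerance = 1e-12)
  }
})

test_that("an unbound consolidated scaffold escapes its well deterministically", {
  # oracle: dz/dt = (f(z) - a_b)/tau_z for z >= 0, integrated independently
  p <- wp_params(sigma = 0)
  zs <- 1
  st <- tibble::tibble(w = 1, T = 1, z = 1, gamma = 0, b = 0L, big = TRUE)
  dt <- p$dt
  path <- numeric(4000)
  for (i in seq_along(path)) {
    st <- step_synapse(st, gate = list(p = 0), no_drive(1), p,
                       noise = matrix(0, 1, 3))
    path[i] <- st$z
  }
  ode <- deSolve::ode(
    y = c(z = 1), times = seq(0, 4000 * dt, by = dt),
    func = function(t, y, parms)
      list((bistable_force(y) - as.numeric(y >= 0)) / p$tau_z))
  expect_lt(max(abs(path - ode[-1, "z"])), 0.02)
  expect_lt(st$z, 0)                       # left the consolidated well
  expect_true(all(diff(path) < 0))         # strictly decreasing
  # the bound synapse under identical conditions does not move
  stb <- tibble::tibble(w = 1, T = 1, z = 1, gamma = 0, b = 1L, big = TRUE)
  stb <- step_synapse(stb, gate = list(p = 0), no_drive(1), p,
                      noise = matrix(0, 1, 3))
  expect_equal(stb$z, 1)
})

test_that("gate accumulator integrates drives, clamps, and switches at 0.37", {
  p <- wp_params(sigma = 0)
  st <- tibble::tibble(w = 1, T = -1, z = -1, gamma = 0.369, b = 0L,
                       big = FALSE)
  # below threshold: the gate is closed, w relaxes toward T
  st1 <- step_synapse(st, list(p = 0), no_drive(1), p,
                      noise = matrix(0, 1, 3))
  expect_lt(st1$w, 1)
  # at/above threshold the gate opens and decouples w from T
  st$gamma <- 0.3701
  st2 <- step_synapse(st, list(p = 0), no_drive(1), p,
                      noise = matrix(0, 1, 3))
  expect_equal(st2$w, 1)

  # large induction drive cannot push gamma beyond 1
  dr <- list(I_plus = 50, I_minus = 0, I_A = 0)
  st$gamma <- 0.9
  st3 <- step_synapse(st, list(p = 0), dr, p, noise = matrix(0, 1, 3))
  expect_lte(st3$gamma, 1)
})

test_that("activity-gated noise equals the original whenever I_A is high", {
  p <- wp_params()
  noise <- matrix(rnorm(30), 10, 3)
  st <- init_synapses(10, 0.5, seed = 2)
  hot <- list(I_plus = rep(0, 10), I_minus = rep(0, 10),
              I_A = rep(p$theta_act * 2, 10))
  a <- step_synapse(st, list(p = 0.5), hot, p, noise = noise,
                    variant = "original")
  b <- step_synapse(st, list(p = 0.5), hot, p, noise = noise,
                    variant = "activity_gated_noise")
  expect_identical(a, b)

  cold <- list(I_plus = rep(0, 10), I_minus = rep(0, 10), I_A = rep(0, 10))
  d <- step_synapse(st, list(p = 0.5), cold, p, noise = noise,
                    variant = "activity_gated_noise")
  # w and T noise silenced, z noise never gated
  expect_true(all(d$w == st$w | abs(d$w - st$w) < 1e-12 |
                    d$w %in% c(-1, 1)))
  expect_false(identical(d$z, b$z) && identical(d$w, b$w))
  expect_equal(d$w, step_synapse(st, list(p = 0.5), cold,
                                 wp_params(sigma = 0),
                                 noise = noise)$w, tolerance = 1e-12)
})
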