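test_that("the activity filter jumps by omega/tau_A per pulse and settles at omega*f", {
  # with the tabulated magnitude the per-pulse jump is 5.4/150
  p54 <- reduced_params(omega = 5.4)
  expect_equal(filter_activity(0, 1, p54, dt = 0.1), 5.4 / 150,
               tolerance = 1e-9)
  p <- reduced_params()
  expect_equal(filter_activity(1, 0, p, dt = 150), exp(-1))

  # periodic steady state: omega * rate
  IA <- filter_activity_series(seq(0.05, 3000, by = 10), 3000, 0.1, p)
  expect_equal(mean(utils::tail(IA, 2000)), p$omega * 0.1, tolerance = 0.02)
  # and the default operating point lies between the two half-activations
  expect_gt(p$omega * 0.1, p$pool$I0_4)
  expect_lt(p$omega * 0.1, p$pool$I0_2)
})

test_that("mean-field derivatives obey the printed closed forms", {
  p <- reduced_params()
  pp <- p$pool

  # an empty system does not move
  st <- reduced_state(0, 0, 0, 0, p)
  st2 <- step_reduced(st, FALSE, p)
  expect_equal(c(st2$n_ASyn, st2$n_A_star, st2$N_big), c(0, 0, 0))

  # rising phase with all big synapses bound: dn_A*/dt = k4 * N_big
  st <- reduced_state(n_ASyn = 100, n_A_star = 0, N_big = 100, I_A = 0, p)
  st2 <- step_reduced(st, FALSE, p)
  k4 <- unbinding_rate(0, "k4", pp)
  expect_equal((st2$n_A_star - st$n_A_star) / p$dt, k4 * 100,
               tolerance = 1e-6)

  # PSI without stimulation: the instantaneous reservoir derivative with all
  # synapses bound is the k4 return flux alone ...
  st <- reduced_state(n_ASyn = 100, n_A_star = 500, N_big = 100, I_A = 0, p)
  st2 <- step_reduced(st, TRUE, p)
  slope <- (st2$n_A_star - st$n_A_star) / p$dt
  expect_equal(slope, k4 * 100, tolerance = 1e-6)
  # ... but once binding and unbinding balance, the quasi-steady decay law
  # is -k0 * n_ASyn = -0.05/s (wp parameters, 100 bound synapses)
  for (i in 1:4000) st <- step_reduced(st, TRUE, p)
  drained <- 500 - st$n_A_star
  expect_equal(drained / (4000 * p$dt), pp$k0 * 100, tolerance = 0.05)
})

test_that("the consolidated count decays only on steep delayed slopes", {
  p <- reduced_params(theta_big = -80, phi = 1, eta = 0.5, dt = 0.5)
  mk <- function(slope) {
    st <- reduced_state(n_ASyn = 1000, n_A_star = 0, N_big = 1000, I_A = 0, p)
    L <- length(st$history)
    st$history <- 1000 + slope * p$dt * (seq_len(L) - L)  # linear history
    st$n_ASyn <- st$history[L]
    st
  }
  flat <- update_Nbig(mk(0), p)
  expect_equal(flat$N_big, 1000)
  steep <- update_Nbig(mk(-100), p)
  expect_equal(steep$N_big, 1000 - 100 * p$dt)
  shallow <- update_Nbig(mk(-10), p)
  expect_equal(shallow$N_big, 1000)
})

test_that("handoff seeds the reduced state and round-trips", {
  p <- reduced_params()
  snap <- list(N_big = 64, n_bound = 64, N_A_star = 410, I_A = 0.01)
  st <- handoff_from_full(snap, p)
  expect_equal(st$n_ASyn, 64)  # all big synapses bound
  expect_equal(st$n_A_star, 410)
  expect_equal(unique(st$history), 64)  # primed flat

  res <- run_reduced_core(st, 0.2, numeric(0), NULL, p, record_dt = 0.1)
  expect_equal(res$final$N_big, 64)
  expect_equal(res$final$n_ASyn, 64, tolerance = 1e-3)

  expect_error(handoff_from_full(list(N_big = 1), p), "missing fields")
})

test_that("a boundary-map cell is stable under a 10x finer integrator", {
  p <- reduced_params()
  init <- reduced_state(n_ASyn = 100, n_A_star = 450, N_big = 100,
                        I_A = 1e-3, p)
  cell <- function(dt) {
    prm <- reduced_params(dt = dt)
    pulses <- nominal_pulses(stim_block(4800, 6000, 0.1))
    res <- run_reduced_core(init, 9000, pulses, c(3600, 7200), prm,
                            record_dt = 9000)
    res$final$N_big / 100
  }
  coarse <- cell(0.1)
  fine <- cell(0.01)
  expect_equal(coarse, fine, tolerance = 0.05)
})

test_that("the boundary map has the reported gross structure", {
  p <- reduced_params()
  init <- reduced_state(n_ASyn = 100, n_A_star = 260, N_big = 100,
                        I_A = 1e-3, p)
  map <- map_boundary(stim_durations = c(0, 1200, 3600),
                      psi_durations = c(0, 2700, 5400),
                      init = init, params = p,
                      t_center = 5400, t_end = 13200)
  expect_s3_class(map, "sr_boundary_map")
  expect_equal(nrow(map), 9)
  # no PSI: remaining fraction exactly 1 for every stimulation duration
  expect_equal(map$remaining_fraction[map$psi_duration == 0], rep(1, 3))
  expect_true(all(map$remaining_fraction >= 0 &
                    map$remaining_fraction <= 1 + 1e-9))

  expect_equal(nrow(map_boundary(numeric(0), numeric(0), init = init,
                                 params = p)), 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_boundary_map(map, path)
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(dim(wide), c(3, 4))
})
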