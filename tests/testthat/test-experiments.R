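tiny_full_config <- function(seed = 77, ...) {
  run_config(paradigm = "p1", model = "write_protected", psi = TRUE,
             n_repeats = 2, seed = seed, time_scale = 0.05, n_synapses = 30,
             overrides = list(duration = 400, lfs_blocks = stim_block(0, 200, 2),
                              hfs_events = 40, psi_window = c(250, 350),
                              dopamine_window = c(40, 43), hfs_duration = 3),
             ...)
}

test_that("full runs are bit-identical under the same master seed", {
  r1 <- run_full(tiny_full_config())
  r2 <- run_full(tiny_full_config())
  expect_identical(r1$series, r2$series)
  expect_identical(r1$summary, r2$summary)
  r3 <- run_full(tiny_full_config(seed = 78))
  expect_false(identical(r1$series$mean_w, r3$series$mean_w))
  # s.e.m. computed over exactly n_repeats
  expect_equal(unique(r1$summary$n), 2)
  # tidy/glance/autoplot surfaces
  expect_identical(tidy(r1), r1$summary)
  g <- glance(r1)
  expect_equal(g$n_repeats, 2)
  expect_s3_class(autoplot(r1), "ggplot")
})

test_that("per-synapse noise streams are mutually independent", {
  # silence-only protocol: trajectories are pure noise around the wells
  cfg <- run_config(paradigm = "p1", model = "write_protected",
                    n_repeats = 1, seed = 5, time_scale = 0.05,
                    n_synapses = 12,
                    overrides = list(duration = 300,
                                     lfs_blocks = stim_block(0, 1, 100),
                                     hfs_events = 0.1,
                                     psi_window = NULL,
                                     dopamine_window = c(0.1, 3),
                                     hfs_duration = 1))
  run <- run_full(cfg)
  fin <- run$finals[[1]]
  # twelve synapses initialized identically would end identically if the
  # noise were shared; they do not
  expect_gt(length(unique(fin$w)), 6)
  expect_gt(stats::sd(fin$T), 0)
})

test_that("a forcibly unbound synapse destabilizes while the rest persist", {
  # keep one initially-big synapse unbound: its scaffold must leave the
  # consolidated well and drag the weight down, while bound neighbours stay
  cfg <- fast_wp_config("p1", psi = FALSE, n_repeats = 1, seed = 55)
  cfg$force_unbound <- 1:100  # indices; only initially-big ones matter
  cfg$record_synapse <- NULL
  # find a big synapse under this seed to record
  big_idx <- which(init_synapses(100, 1 / 3,
                                 seed = synrecon:::repeat_seed(55, 1))$big)[1]
  cfg$force_unbound <- big_idx
  cfg$record_synapse <- big_idx
  run <- run_full(cfg)
  s <- run$series
  expect_true(all(c("syn_w", "syn_z", "syn_b") %in% names(s)))
  expect_true(all(s$syn_b == 0))              # never binds
  expect_equal(s$syn_z[1], 1)
  expect_lt(tail(s$syn_z, 1), 0)              # scaffold degraded
  expect_lt(tail(s$syn_w, 1), 0)              # weight followed
  expect_gt(tail(s$N_big, 1), 90)             # the others persisted
})

test_that("presynaptic counts follow the binomial connectivity law", {
  set.seed(123)
  draws <- rbinom(100, 400, 0.5)
  expect_lt(abs(mean(draws) - 200), 3 * 10)
  # and run_full really uses it when n_synapses is NULL
  cfg <- tiny_full_config()
  cfg$n_synapses <- NULL
  cfg$n_repeats <- 3
  r <- run_full(cfg)
  ns <- unique(r$series[, c("repeat_id", "n_synapses")])$n_synapses
  expect_true(all(ns >= 140 & ns <= 260))
  expect_gt(length(unique(ns)), 1)
})

test_that("configurations and results round-trip through disk", {
  cfg <- run_config(paradigm = "p3", model = "state_based", psi = FALSE,
                    n_repeats = 4, seed = 9, time_scale = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$paradigm, "p3")
  expect_equal(back$psi, FALSE)
  expect_equal(back$time_scale, 0.5)
  expect_equal(back$sb$alpha, cfg$sb$alpha)
  expect_equal(back$pool$k1, cfg$pool$k1)
  expect_equal(back$wp$g0, cfg$wp$g0)

  broken <- jsonlite::read_json(path, simplifyVector = TRUE)
  broken$paradigm <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(broken, path2, auto_unbox = TRUE, null = "null")
  expect_error(read_config(path2), "paradigm")

  run <- run_state_based(run_config(paradigm = "p1", model = "state_based",
                                    n_repeats = 2, seed = 3,
                                    time_scale = 0.2))
  dir <- withr::local_tempdir()
  write_result(run, dir)
  expect_true(file.exists(file.path(dir, "summary.tsv")))
  expect_true(file.exists(file.path(dir, "series.tsv")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$model, "state_based")
  expect_match(manifest$config_hash, "^[0-9a-f]+$")

  # detailed runs also dump the final per-synapse states
  dir2 <- withr::local_tempdir()
  write_result(run_full(tiny_full_config()), dir2)
  states <- readr::read_tsv(file.path(dir2, "synapse_states.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(states), 2 * 30)
  expect_true(all(c("w", "T", "z", "gamma", "b") %in% names(states)))
})

test_that("end-of-run comparisons average the final stimulation window", {
  run <- run_state_based(run_config(paradigm = "p1", model = "state_based",
                                    n_repeats = 3, seed = 3,
                                    time_scale = 0.2))
  fw <- final_window_mean(run)
  expect_equal(nrow(fw), 3)
  t_end <- max(run$series$t)
  manual <- run$series |>
    dplyr::filter(t >= t_end - 1800 * 0.2, repeat_id == 2) |>
    dplyr::pull(fepsp) |> mean()
  expect_equal(fw$value[fw$repeat_id == 2], manual)

  cmp <- compare_runs(run, run)
  expect_equal(cmp$p_value, 1, tolerance = 1e-9)

  single <- run_state_based(run_config(paradigm = "p1",
                                       model = "state_based",
                                       n_repeats = 1, seed = 3,
                                       time_scale = 0.2))
  expect_true(all(is.na(single$summary$sem)))  # absent, not zero
})

test_that("halving the synapse step does not change paradigm outcomes", {
  run_mean <- function(paradigm, dt) {
    cfg <- fast_wp_config(paradigm, psi = TRUE, n_repeats = 2, seed = 31)
    cfg$wp$dt <- dt
    mean(final_window_mean(run_full(cfg))$value)
  }
  expect_lt(run_mean("p2", 0.1), 0.8)
  expect_lt(run_mean("p2", 0.05), 0.8)
  expect_gt(run_mean("p1", 0.1), 0.9)
  expect_gt(run_mean("p1", 0.05), 0.9)
})
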