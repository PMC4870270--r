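#' Configuration of a simulation experiment
#'
#' Bundles the paradigm, model choice, variant, repeat count, master seed and
#' scale of a run. Per-repeat seeds derive from the master seed as
#' `seed + 7919 * repeat_index`, so a fixed master seed reproduces every
#' repeat bit for bit.
#'
#' @param paradigm Paradigm name, see [build_paradigm()].
#' @param model One of `"write_protected"`, `"state_based"`, `"reduced"`.
#' @param variant `"original"`, or the delayed-decay variants
#'   `"activity_gated_noise"` (write-protected) / `"activity_gated_beta"`
#'   (state-based).
#' @param psi Include the PSI window (`FALSE` gives the control condition).
#' @param n_repeats Number of independent repeats (simulated neurons).
#' @param seed Master seed.
#' @param time_scale Slow-layer compression factor passed to
#'   [compress_time()]; 1 runs the full printed time scale.
#' @param n_synapses Fixed presynaptic count; `NULL` draws each repeat's
#'   count from a binomial law with mean 200 (size 400, probability 0.5).
#' @param frac_big Fraction of synapses initialized consolidated.
#' @param record_dt Output sampling interval (s) at `time_scale = 1`; scaled
#'   with the protocol.
#' @param snapshot_t Time (s, unscaled) at which to capture a state snapshot
#'   for the reduced-model handoff; `NULL` for none.
#' @param overrides Protocol overrides, see [build_paradigm()].
#' @param stim_duration,psi_duration Window durations (s, unscaled) for the
#'   `fig3_grid` paradigm.
#' @param neuron,triplet,wp,pool,reduced,sb Parameter objects; defaults are
#'   the printed tables (the pool defaults to the column matching `model`).
#' @param force_unbound Integer indices of synapses artificially kept
#'   unbound for the whole run (they start unbound and can never rebind),
#'   the override used to demonstrate binding-dependent destabilization of
#'   a single consolidated synapse.
#' @param record_synapse Optional index of one synapse whose weight, tag,
#'   scaffold and bound flag are recorded alongside the population series.
#' @param dt_fine Neuron time step (s).
#' @return An object of class `run_config`.
#' @export
run_config <- function(paradigm = "p2",
                       model = c("write_protected", "state_based", "reduced"),
                       variant = "original", psi = TRUE, n_repeats = 10,
                       seed = 1, time_scale = 1, n_synapses = NULL,
                       frac_big = 1 / 3, record_dt = 10, snapshot_t = NULL,
                       overrides = list(), stim_duration = 1200,
                       psi_duration = 7200,
                       neuron = neuron_params(), triplet = triplet_params(),
                       wp = wp_params(),
                       pool = NULL, reduced = reduced_params(),
                       sb = sb_params(), force_unbound = integer(0),
                       record_synapse = NULL, dt_fine = 1e-4) {
  model <- match.arg(model)
  stopifnot(n_repeats >= 1, time_scale > 0, time_scale <= 1)
  pool <- pool %||% pool_params(if (model == "state_based") "sb" else "wp")
  neuron <- neuron %||% neuron_params()
  triplet <- triplet %||% triplet_params()
  wp <- wp %||% wp_params()
  reduced <- reduced %||% reduced_params()
  sb <- sb %||% sb_params()
  structure(list(paradigm = paradigm, model = model, variant = variant,
                 psi = psi, n_repeats = n_repeats, seed = as.integer(seed),
                 time_scale = time_scale, n_synapses = n_synapses,
                 frac_big = frac_big, record_dt = record_dt,
                 snapshot_t = snapshot_t, overrides = overrides,
                 stim_duration = stim_duration, psi_duration = psi_duration,
                 neuron = neuron, triplet = triplet, wp = wp, pool = pool,
                 reduced = reduced, sb = sb,
                 force_unbound = as.integer(force_unbound),
                 record_synapse = record_synapse, dt_fine = dt_fine),
            class = "run_config")
}

repeat_seed <- function(master, i) as.integer(master + 7919L * i)

scaled_protocol <- function(config) {
  p <- build_paradigm(config$paradigm, psi = config$psi,
                      stim_duration = config$stim_duration,
                      psi_duration = config$psi_duration,
                      overrides = config$overrides)
  if (config$time_scale < 1) p <- compress_time(p, config$time_scale)
  p
}

# per-neuron spike-time vectors for a protocol realization
protocol_spike_trains <- function(protocol, n_neurons, seed) {
  pieces <- list()
  for (i in seq_len(nrow(protocol$lfs_blocks)))
    pieces[[length(pieces) + 1]] <-
      generate_lfs(protocol$lfs_blocks[i, ], n_neurons, seed + i)
  for (k in seq_along(protocol$hfs_events))
    pieces[[length(pieces) + 1]] <-
      generate_hfs(protocol$hfs_events[k], n_neurons, seed + 1000L + k,
                   rate = protocol$hfs_rate,
                   duration = protocol$hfs_duration,
                   jitter_sd = protocol$jitter_sd)
  all <- dplyr::arrange(dplyr::bind_rows(pieces), .data$neuron, .data$time)
  lapply(split(all$time, factor(all$neuron, levels = seq_len(n_neurons))),
         as.numeric)
}

summarise_repeats <- function(series, value_col) {
  dplyr::summarise(
    dplyr::group_by(series, .data$t),
    mean = mean(.data[[value_col]]),
    sem = if (dplyr::n() > 1) sd(.data[[value_col]]) / sqrt(dplyr::n())
          else NA_real_,
    n = dplyr::n(), .groups = "drop")
}

new_sr_run <- function(series, summary, config, model, protocol,
                       snapshots = NULL, extra = list()) {
  structure(c(list(series = series, summary = summary, config = config,
                   model = model, protocol = protocol,
                   snapshots = snapshots), extra),
            class = "sr_run")
}

#' Run the full extended write-protected simulation
#'
#' For each repeat: the presynaptic count is drawn from the binomial
#' connectivity law (unless fixed), synapses are initialized with one third
#' consolidated and bound, presynaptic spike trains are generated for the
#' paradigm, and the layered simulation runs (neuron and triplet traces on
#' the fine step, synapse variables and stabilizer pool on the 100 ms step,
#' protocol events on schedule). The result averages the mean synaptic
#' weight across repeats.
#'
#' @param config A [run_config()] with `model = "write_protected"`.
#' @return An `sr_run` with per-repeat `series`, across-repeat `summary`
#'   (`t`, `mean`, `sem`, `n` of the population-mean weight), snapshots (if
#'   requested) and per-repeat final states.
#' @export
run_full <- function(config = run_config(model = "write_protected")) {
  stopifnot(inherits(config, "run_config"),
            config$model == "write_protected")
  protocol <- scaled_protocol(config)
  lam <- config$time_scale
  wp <- config$wp; pool <- config$pool; trip <- config$triplet
  if (lam < 1) {
    wp <- compress_time(wp, lam)
    pool <- compress_time(pool, lam)
    trip <- compress_time(trip, lam)
  }
  steps_per_slow <- max(1L, round(wp$dt / config$dt_fine))
  record_dt <- config$record_dt * lam
  snapshot_t <- if (is.null(config$snapshot_t)) -1 else config$snapshot_t * lam
  gated <- identical(config$variant, "activity_gated_noise")

  res <- purrr::map(seq_len(config$n_repeats), function(i) {
    seed_i <- repeat_seed(config$seed, i)
    set.seed(seed_i)
    n_pre <- config$n_synapses %||% rbinom(1, 400, 0.5)
    syn0 <- init_synapses(n_pre, config$frac_big, seed = seed_i)
    trains <- protocol_spike_trains(protocol, n_pre, seed_i)
    fu <- integer(n_pre)
    fu[config$force_unbound[config$force_unbound <= n_pre]] <- 1L
    rec_syn <- if (is.null(config$record_synapse)) -1L
               else as.integer(config$record_synapse) - 1L
    set.seed(seed_i + 500000L)
    out <- cpp_run_full(
      trains, protocol$duration, config$dt_fine, steps_per_slow,
      unclass(config$neuron), unclass(trip), unclass(wp), unclass(pool),
      as.numeric(protocol$psi_window %||% numeric(0)),
      as.numeric(protocol$dopamine_window %||% numeric(0)),
      as.integer(syn0$big), gated,
      fu, record_dt, rec_syn, snapshot_t)
    series <- tibble::as_tibble(out$series) |>
      dplyr::mutate(repeat_id = i, n_synapses = n_pre)
    if (!is.null(out$synapse_trace))
      series <- dplyr::bind_cols(
        series, tibble::as_tibble(out$synapse_trace) |>
          stats::setNames(paste0("syn_", names(out$synapse_trace))))
    list(series = series, final = out$final, snapshot = out$snapshot)
  })
  series <- dplyr::bind_rows(purrr::map(res, "series"))
  summary <- summarise_repeats(series, "mean_w")
  new_sr_run(series, summary, config, "write_protected", protocol,
             snapshots = purrr::map(res, "snapshot"),
             extra = list(finals = purrr::map(res, "final")))
}

#' Run the reduced reservoir model over a paradigm
#'
#' The mapped phase starts from a handoff state (the detailed model's state
#' at the end of the 60 min initiation phase). If no `init` state is given,
#' one detailed repeat is run to the snapshot time to generate it (with a
#' message). For the `fig3_grid` paradigm a boundary map over stimulation
#' and PSI durations is attached.
#'
#' @param config A [run_config()] with `model = "reduced"`.
#' @param init Optional `reduced_state` for the start of the mapped phase.
#' @param handoff_t Handoff time (s, unscaled protocol time).
#' @param grid_n Grid resolution per axis for the `fig3_grid` boundary map.
#' @return An `sr_run`; for `fig3_grid`, element `boundary_map` holds the
#'   [map_boundary()] result.
#' @export
run_reduced <- function(config = run_config(model = "reduced"), init = NULL,
                        handoff_t = 3600, grid_n = 26) {
  stopifnot(inherits(config, "run_config"), config$model == "reduced")
  protocol <- scaled_protocol(config)
  lam <- config$time_scale
  red <- config$reduced
  if (lam < 1) red <- compress_time(red, lam)
  t0 <- handoff_t * lam
  if (is.null(init)) {
    message("no handoff state supplied; running one detailed repeat to t = ",
            t0, " s to generate it")
    fc <- config
    fc$model <- "write_protected"
    fc$n_repeats <- 1
    fc$snapshot_t <- handoff_t
    fc$pool <- pool_params("wp", N_A_tot = config$pool$N_A_tot)
    snap <- run_full(fc)$snapshots[[1]]
    init <- handoff_from_full(snap, red)
  }
  # events after the handoff, shifted to the reduced clock
  pulses <- pulse_times(protocol)
  pulses <- pulses[pulses >= t0] - t0
  psi <- protocol$psi_window
  if (!is.null(psi)) psi <- pmax(psi - t0, 0)
  duration <- protocol$duration - t0
  res <- run_reduced_core(init, duration, pulses, psi, red,
                          record_dt = config$record_dt * lam)
  series <- dplyr::mutate(res$series, t = .data$t + t0, repeat_id = 1)
  summary <- tibble::tibble(t = series$t, mean = series$N_big,
                            sem = NA_real_, n = 1)
  bmap <- NULL
  if (identical(config$paradigm, "fig3_grid") && grid_n > 0) {
    ctr <- 150 * 60 * lam - t0
    bmap <- map_boundary(
      stim_durations = seq(0, 9000 * lam, length.out = grid_n),
      psi_durations = seq(0, 9000 * lam, length.out = grid_n),
      init = init, params = red, t_center = ctr,
      t_end = duration, lfs_rate = protocol$lfs_rate)
  }
  new_sr_run(series, summary, config, "reduced", protocol,
             extra = list(final = res$final, init = init,
                          boundary_map = bmap, handoff_t = t0))
}

#' Run the extended state-based simulation
#'
#' The population starts with 800 weak-basal and 200 strong-basal synapses;
#' a single HFS burst induces LTP. The global activity driving the
#' stabilizer unbinding rates is the reduced model's pulse-driven filter
#' (the state-based model itself has no activity dependence). Reports the
#' percent fEPSP averaged over repeats.
#'
#' @param config A [run_config()] with `model = "state_based"`.
#' @return An `sr_run` with per-repeat fEPSP series and summary.
#' @export
run_state_based <- function(config = run_config(model = "state_based")) {
  stopifnot(inherits(config, "run_config"), config$model == "state_based")
  protocol <- scaled_protocol(config)
  lam <- config$time_scale
  sb <- config$sb; red <- config$reduced
  if (lam < 1) {
    sb <- compress_time(sb, lam)
    red <- compress_time(red, lam)
  }
  sb$pool <- config$pool
  if (lam < 1) sb$pool <- compress_time(config$pool, lam)
  record_dt <- config$record_dt * lam
  IA <- filter_activity_series(pulse_times(protocol), protocol$duration,
                               sb$dt, red)
  hfs_t <- if (length(protocol$hfs_events)) protocol$hfs_events[1] else -1
  gated <- identical(config$variant, "activity_gated_beta")
  series <- purrr::map(seq_len(config$n_repeats), function(i) {
    set.seed(repeat_seed(config$seed, i))
    out <- cpp_run_sb(protocol$duration, sb$dt, sb$pool_dt, IA,
                      unclass(sb), unclass(sb$pool), hfs_t,
                      as.numeric(protocol$psi_window %||% numeric(0)),
                      gated, record_dt)
    tibble::as_tibble(out) |> dplyr::mutate(repeat_id = i)
  }) |> dplyr::bind_rows()
  summary <- summarise_repeats(series, "fepsp")
  new_sr_run(series, summary, config, "state_based", protocol)
}

#' Time-averaged readout over the final stimulation window
#'
#' Averages each repeat's readout (mean weight or fEPSP) over the last
#' `window` seconds of the run, reducing single-point noise in end-of-run
#' comparisons.
#'
#' @param run An `sr_run`.
#' @param window Averaging window (s); defaults to the last 30 simulated
#'   minutes at the run's time scale.
#' @return A tibble with one row per repeat (`repeat_id`, `value`).
#' @export
final_window_mean <- function(run, window = NULL) {
  window <- window %||% (1800 * run$config$time_scale)
  value_col <- if (run$model == "state_based") "fepsp" else "mean_w"
  t_end <- max(run$series$t)
  dplyr::summarise(
    dplyr::group_by(dplyr::filter(run$series, .data$t >= t_end - window),
                    .data$repeat_id),
    value = mean(.data[[value_col]]), .groups = "drop")
}

#' Compare the end-of-run readouts of two conditions
#'
#' Welch two-sample test on the per-repeat time-averaged readouts of the
#' final stimulation window (e.g. PSI versus control).
#'
#' @param run_a,run_b `sr_run` objects (same model and time scale).
#' @param window Averaging window (s), see [final_window_mean()].
#' @param alternative Passed to [stats::t.test()]; `"less"` tests whether
#'   condition A ends below condition B.
#' @return A one-row tibble: `estimate_a`, `estimate_b`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`, `method`.
#' @export
compare_runs <- function(run_a, run_b, window = NULL,
                         alternative = "two.sided") {
  a <- final_window_mean(run_a, window)$value
  b <- final_window_mean(run_b, window)$value
  ht <- t.test(a, b, alternative = alternative)
  tibble::tibble(estimate_a = mean(a), estimate_b = mean(b),
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 conf_low = ht$conf.int[1], conf_high = ht$conf.int[2],
                 method = ht$method)
}

#' @export
print.sr_run <- function(x, ...) {
  cat(sprintf("<%s run: paradigm %s%s, %d repeat(s), time scale %g>\n",
              x$model, x$config$paradigm,
              if (x$config$psi) " +PSI" else " (control)",
              x$config$n_repeats, x$config$time_scale))
  print(utils::tail(x$summary, 3))
  invisible(x)
}

#' @rdname run_full
#' @param x An `sr_run`.
#' @param ... Unused.
#' @export
tidy.sr_run <- function(x, ...) x$summary

#' @rdname run_full
#' @export
glance.sr_run <- function(x, ...) {
  fin <- final_window_mean(x)
  tibble::tibble(model = x$model, paradigm = x$config$paradigm,
                 psi = x$config$psi, variant = x$config$variant,
                 n_repeats = x$config$n_repeats,
                 duration = x$protocol$duration,
                 time_scale = x$config$time_scale,
                 end_mean = mean(fin$value),
                 end_sem = if (nrow(fin) > 1)
                   sd(fin$value) / sqrt(nrow(fin)) else NA_real_)
}

#' Plot the averaged readout of a run
#'
#' Mean across repeats with a ribbon of plus/minus one s.e.m., plus shaded
#' PSI window and HFS marker.
#'
#' @param object An `sr_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sr_run <- function(object, ...) {
  lab <- if (object$model == "state_based") "% fEPSP" else "mean weight"
  g <- ggplot2::ggplot(object$summary,
                       ggplot2::aes(x = .data$t / 3600, y = .data$mean))
  if (!is.null(object$protocol$psi_window))
    g <- g + ggplot2::annotate(
      "rect", xmin = object$protocol$psi_window[1] / 3600,
      xmax = object$protocol$psi_window[2] / 3600,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  if (any(!is.na(object$summary$sem)))
    g <- g + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), alpha = 0.3)
  g + ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = lab) +
    ggplot2::theme_minimal()
}

#' Calibrate the synaptic conductance scale
#'
#' The conductance scale `g0` is not identified by the printed parameters;
#' it is fixed by requiring that a single stimulation volley (one jittered
#' spike from every presynaptic neuron, at the potentiated weight
#' configuration) drives a postsynaptic burst whose summed triplet induction
#' `J` matches the reduced model's per-pulse activity increment
#' `omega / tau_A = 0.0036`. The co-activity under sustained 0.1 Hz
#' stimulation then settles at `J * 0.1 * tau_A = 0.054`, between the two
#' unbinding half-activations — the operating point at which stimulation
#' strongly accelerates unbinding into the immune reservoir while only
#' mildly accelerating unbinding into the susceptible pool, which is what
#' separates the four slice paradigms. The same calibration keeps the
#' per-volley weight drive in the depressed configuration (about
#' `2 * J_dep`, with `J_dep` roughly a third of `J`) well below the
#' bistable restoring flux per pulse period (about 0.019), so monitoring
#' stimulation neither potentiates the naive baseline nor re-potentiates a
#' degraded population. Bisection on `g0`; the result is cached as the
#' default of [wp_params()].
#'
#' The calibration volley uses the potentiated weight configuration (all
#' weights at +1), because the reconsolidation-phase stimulation the
#' co-activity must report occurs after LTP induction has saturated the
#' weights.
#'
#' @param n_synapses Presynaptic count used for calibration.
#' @param frac_big Fraction of big synapses (used when `potentiated =
#'   FALSE`).
#' @param target Target per-volley induction sum (default `5.4 / 150`).
#' @param seed Seed for the jitter and initialization.
#' @param lower,upper Bisection bracket for `g0`.
#' @param tol Relative tolerance on the achieved induction.
#' @param potentiated Calibrate at the post-LTP weight configuration.
#' @param n_volleys Number of independently jittered volleys averaged per
#'   probe (the burst response is steep in `g0`, so single volleys are
#'   noisy).
#' @return A list: `g0`, `achieved` (mean per-volley induction),
#'   `n_post_spikes` (mean burst size).
#' @export
calibrate_g0 <- function(n_synapses = 200, frac_big = 1 / 3,
                         target = 0.0039, seed = 1, lower = 2,
                         upper = 2000, tol = 0.02, potentiated = TRUE,
                         n_volleys = 10) {
  probe <- function(g0) {
    v <- purrr::map(seq_len(n_volleys), function(k)
      volley_induction(g0, n_synapses, frac_big, seed + k - 1, potentiated))
    list(induction = mean(purrr::map_dbl(v, "induction")),
         n_post = mean(purrr::map_dbl(v, "n_post")))
  }
  lo <- lower; hi <- upper
  f_hi <- probe(hi)
  if (f_hi$induction < target)
    abort("upper bracket too small for calibration target")
  mid <- sqrt(lo * hi); f <- probe(mid)
  for (i in 1:30) {
    if (abs(f$induction - target) / target < tol) break
    if (f$induction < target) lo <- mid else hi <- mid
    if (hi / lo < 1.0005) break
    mid <- sqrt(lo * hi)
    f <- probe(mid)
  }
  list(g0 = mid, achieved = f$induction, n_post_spikes = f$n_post)
}

# simulate one synchronized stimulation volley and return the mean
# per-synapse triplet induction it generates
volley_induction <- function(g0, n_synapses, frac_big, seed,
                             potentiated = TRUE) {
  np <- neuron_params()
  tp <- triplet_params()
  wp <- wp_params(g0 = g0)
  w <- if (potentiated) rep(1, n_synapses)
  else init_synapses(n_synapses, frac_big, seed)$w
  dg <- conductance_from_weight(w, wp)
  with_seed(seed + 1, {
    spike_t <- 0.01 + rnorm(n_synapses, 0, 3e-3)
  })
  dt <- 1e-4
  steps <- round(0.3 / dt)
  spike_step <- pmax(1, round(spike_t / dt))
  st <- neuron_state(np)
  tr <- trace_state(n_synapses)
  acc <- rep(0, n_synapses)
  n_post <- 0
  for (i in seq_len(steps)) {
    pre <- spike_step == i
    ind_pre <- induction(tr, pre, FALSE, tp)
    acc <- acc + ind_pre$I_minus
    res <- step_neuron(st, dg[pre], np, dt)
    st <- res$state
    if (res$spiked) {
      ind_post <- induction(tr, rep(FALSE, n_synapses), TRUE, tp)
      acc <- acc + ind_post$I_plus
      n_post <- n_post + 1
    }
    tr <- update_traces(tr, pre, res$spiked, dt, tp)
  }
  list(induction = mean(acc), n_post = n_post)
}

#' Write a run result to disk / read a configuration
#'
#' Writes the summary and per-repeat series as TSV (plus the final
#' per-synapse states for detailed runs and the boundary map when present)
#' and a JSON manifest carrying the configuration and its hash.
#'
#' @param result An `sr_run`.
#' @param dir Output directory (created if needed).
#' @param path Configuration file path.
#' @return `write_result()` returns `dir` invisibly; `read_config()` a
#'   `run_config`; `write_config()` returns `path` invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$summary, file.path(dir, "summary.tsv"))
  readr::write_tsv(result$series, file.path(dir, "series.tsv"))
  if (!is.null(result$finals)) {
    fin <- purrr::imap(result$finals, function(f, i)
      tibble::tibble(repeat_id = i, synapse = seq_along(f$w), w = f$w,
                     T = f$T, z = f$z, gamma = f$gamma, I_A = f$I_A,
                     b = f$b))
    readr::write_tsv(dplyr::bind_rows(fin),
                     file.path(dir, "synapse_states.tsv"))
  }
  if (!is.null(result$boundary_map))
    write_boundary_map(result$boundary_map, file.path(dir, "boundary_map.tsv"))
  manifest <- list(model = result$model,
                   config = config_as_list(result$config),
                   config_hash = rlang::hash(config_as_list(result$config)),
                   package_version =
                     as.character(utils::packageVersion("synrecon")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

config_as_list <- function(config) {
  strip <- function(v) {
    if (is.data.frame(v)) return(as.data.frame(v))
    if (is.list(v)) return(lapply(unclass(v), strip))
    unclass(v)
  }
  strip(config)
}

#' @rdname write_result
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_as_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_result
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scalars <- c("paradigm", "model", "variant", "psi", "n_repeats", "seed",
               "time_scale", "frac_big", "record_dt", "stim_duration",
               "psi_duration", "dt_fine")
  miss <- setdiff(scalars, names(x))
  if (length(miss))
    abort(paste0("configuration file is missing field(s): ",
                 paste(miss, collapse = ", ")))
  par_of <- function(nm, ctor) {
    if (is.null(x[[nm]])) return(NULL)
    do.call(ctor, x[[nm]][setdiff(names(x[[nm]]), c("model", "pool"))])
  }
  pool_of <- function(lst) {
    if (is.null(lst)) return(NULL)
    do.call(pool_params, lst)
  }
  run_config(paradigm = x$paradigm, model = x$model, variant = x$variant,
             psi = x$psi, n_repeats = x$n_repeats, seed = x$seed,
             time_scale = x$time_scale, n_synapses = x$n_synapses,
             frac_big = x$frac_big, record_dt = x$record_dt,
             snapshot_t = x$snapshot_t,
             overrides = x$overrides %||% list(),
             stim_duration = x$stim_duration, psi_duration = x$psi_duration,
             neuron = par_of("neuron", neuron_params),
             triplet = par_of("triplet", triplet_params),
             wp = par_of("wp", wp_params),
             pool = pool_of(x$pool),
             reduced = {
               r <- x$reduced
               if (is.null(r)) NULL else
                 reduced_params(phi = r$phi, theta_big = r$theta_big,
                                eta = r$eta, omega = r$omega,
                                tau_A = r$tau_A, dt = r$dt,
                                pool = pool_of(r$pool))
             },
             sb = {
               s <- x$sb
               if (is.null(s)) NULL else
                 do.call(sb_params,
                         c(s[setdiff(names(s), "pool")],
                           list(pool = pool_of(s$pool))))
             },
             force_unbound = as.integer(x$force_unbound %||% integer(0)),
             record_synapse = x$record_synapse,
             dt_fine = x$dt_fine)
}
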