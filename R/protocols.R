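#' Define a block of periodic, jittered low-frequency stimulation
#'
#' A stimulation block delivers one presynaptic pulse per period `1/rate` to
#' every presynaptic neuron, each pulse independently jittered by a Gaussian
#' delay (mean 0, sd `jitter_sd`).
#'
#' @param t_start,t_end Block boundaries (s), `t_end > t_start`.
#' @param rate Nominal pulse rate (Hz).
#' @param jitter_sd Standard deviation of the Gaussian jitter (s).
#' @return A one-row tibble with columns `t_start`, `t_end`, `rate`,
#'   `jitter_sd`.
#' @examples
#' stim_block(0, 600, rate = 0.1)
#' @export
stim_block <- function(t_start, t_end, rate = 0.1, jitter_sd = 3e-3) {
  if (!(t_end > t_start)) abort("invalid stimulation block: t_end <= t_start")
  if (!(rate > 0)) abort("invalid stimulation block: rate must be positive")
  if (jitter_sd < 0) abort("invalid stimulation block: negative jitter_sd")
  tibble::tibble(t_start = t_start, t_end = t_end, rate = rate,
                 jitter_sd = jitter_sd)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

nominal_pulses <- function(block) {
  n <- floor((block$t_end - block$t_start) * block$rate + 1e-9)
  if (n < 1) return(numeric(0))
  block$t_start + (seq_len(n) - 1) / block$rate
}

#' Generate jittered low-frequency spike trains
#'
#' Each of `n_neurons` presynaptic neurons receives one spike per nominal
#' pulse of the block, shifted by an independent Gaussian delay. Jittered
#' spikes are clamped to `[t_start, t_end)` and re-sorted, so the spike count
#' per neuron is invariant under the seed; only the jitters vary. Spikes of
#' one neuron falling into the same 0.1 ms step are merged.
#'
#' @param block A [stim_block()].
#' @param n_neurons Number of presynaptic neurons (>= 1).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param step Merge resolution (s), the neuron time step.
#' @return A tibble with columns `neuron` (1-based id) and `time` (s), sorted
#'   by neuron then time.
#' @examples
#' trains <- generate_lfs(stim_block(0, 600, 0.1), n_neurons = 3, seed = 1)
#' dplyr::count(trains, neuron) # 60 spikes each
#' @export
generate_lfs <- function(block, n_neurons, seed, step = 1e-4) {
  stopifnot(is.data.frame(block), nrow(block) == 1, n_neurons >= 1)
  if (block$t_end <= block$t_start || block$rate <= 0)
    abort("invalid stimulation block")
  pulses <- nominal_pulses(block)
  n_p <- length(pulses)
  with_seed(seed, {
    t <- rep(pulses, times = n_neurons) +
      rnorm(n_p * n_neurons, 0, block$jitter_sd)
  })
  t <- pmin(pmax(t, block$t_start), block$t_end - step)
  out <- tibble::tibble(neuron = rep(seq_len(n_neurons), each = n_p),
                        time = t)
  out <- dplyr::arrange(out, .data$neuron, .data$time)
  out <- dplyr::distinct(out, .data$neuron,
                         bin = round(.data$time / step), .keep_all = TRUE)
  dplyr::select(out, "neuron", "time")
}

#' Generate a high-frequency stimulation burst
#'
#' 100 Hz stimulation for 60 s by default, jittered spike-by-spike in the same
#' manner as low-frequency stimulation.
#'
#' @param t_start Burst onset (s), >= 0.
#' @param n_neurons Number of presynaptic neurons.
#' @param seed Integer seed.
#' @param rate Burst rate (Hz).
#' @param duration Burst duration (s).
#' @param jitter_sd Gaussian jitter sd (s).
#' @param step Merge resolution (s).
#' @return A tibble with columns `neuron`, `time`.
#' @examples
#' nrow(generate_hfs(0, n_neurons = 1, seed = 1)) # <= 6000 (collisions merge)
#' @export
generate_hfs <- function(t_start, n_neurons, seed, rate = 100, duration = 60,
                         jitter_sd = 3e-3, step = 1e-4) {
  stopifnot(t_start >= 0)
  generate_lfs(stim_block(t_start, t_start + duration, rate, jitter_sd),
               n_neurons, seed, step)
}

new_protocol <- function(duration, lfs_blocks, hfs_events,
                         psi_window = NULL, dopamine_window = NULL,
                         hfs_rate = 100, hfs_duration = 60,
                         lfs_rate = 0.1, jitter_sd = 3e-3) {
  p <- structure(list(duration = duration, lfs_blocks = lfs_blocks,
                      hfs_events = hfs_events, psi_window = psi_window,
                      dopamine_window = dopamine_window, hfs_rate = hfs_rate,
                      hfs_duration = hfs_duration, lfs_rate = lfs_rate,
                      jitter_sd = jitter_sd),
                 class = "sr_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "sr_protocol"))
  if (p$duration <= 0) abort("protocol duration must be positive")
  b <- p$lfs_blocks
  if (nrow(b) > 0) {
    if (any(b$t_start < 0) || any(b$t_end > p$duration + 1e-9))
      abort("stimulation blocks must lie within [0, duration]")
    if (any(b$t_end <= b$t_start)) abort("degenerate stimulation block")
  }
  if (any(p$hfs_events < 0 | p$hfs_events > p$duration))
    abort("HFS events must lie within [0, duration]")
  for (w in list(p$psi_window, p$dopamine_window)) {
    if (!is.null(w)) {
      if (length(w) != 2 || w[2] <= w[1] || w[1] < 0 || w[2] > p$duration)
        abort("windows must be non-degenerate intervals within [0, duration]")
    }
  }
  if (!is.null(p$dopamine_window) && length(p$hfs_events) > 0) {
    ok <- any(p$hfs_events >= p$dopamine_window[1] - p$hfs_duration &
                p$hfs_events <= p$dopamine_window[2])
    if (!ok) abort("the dopamine window must co-occur with an HFS event")
  }
  invisible(p)
}

#' @export
print.sr_protocol <- function(x, ...) {
  cat("<stimulation protocol>\n")
  cat(sprintf("  duration: %.0f s (%.1f h)\n", x$duration, x$duration / 3600))
  cat(sprintf("  LFS blocks (%.2g Hz):\n", x$lfs_rate))
  for (i in seq_len(nrow(x$lfs_blocks)))
    cat(sprintf("    %8.0f - %8.0f s\n", x$lfs_blocks$t_start[i],
                x$lfs_blocks$t_end[i]))
  if (length(x$hfs_events))
    cat(sprintf("  HFS (%g Hz, %g s) at: %s s\n", x$hfs_rate, x$hfs_duration,
                paste(x$hfs_events, collapse = ", ")))
  if (!is.null(x$psi_window))
    cat(sprintf("  PSI: %8.0f - %8.0f s\n", x$psi_window[1], x$psi_window[2]))
  if (!is.null(x$dopamine_window))
    cat(sprintf("  dopamine: %.0f - %.0f s\n", x$dopamine_window[1],
                x$dopamine_window[2]))
  invisible(x)
}

paradigm_names <- c("p1", "p2", "p3", "p4", "fig3_grid", "fig5")

#' Build the stimulation timeline of a named experimental paradigm
#'
#' Returns the full event timeline (low-frequency stimulation blocks, HFS,
#' PSI and dopamine windows) for the four slice-reconsolidation paradigms,
#' the boundary-condition grid protocol, and the delayed-decay paradigm.
#' Timings follow the slice experiments the models emulate: LTP induction by
#' HFS at minute 20 during background 0.1 Hz stimulation, PSI beginning after
#' 60 min without stimulation, and a final extended stimulation block; see
#' the methods vignette for the full default timelines. Every field can be
#' overridden.
#'
#' @param name One of `"p1"` (PSI alone), `"p2"` (20 min stimulation in the
#'   midst of PSI), `"p3"` (like p2 but initial stimulation prolonged past
#'   1 h after induction), `"p4"` (continuous stimulation, extended PSI),
#'   `"fig3_grid"` (variable stimulation and PSI windows centered at minute
#'   150), `"fig5"` (alias of p2, used with the activity-gated variants).
#' @param psi Logical; include the PSI window (the control condition sets
#'   `psi = FALSE`).
#' @param stim_duration,psi_duration For `"fig3_grid"`: durations (s) of the
#'   stimulation and PSI windows, both centered at 150 min.
#' @param overrides Named list of protocol fields to replace (`duration`,
#'   `lfs_blocks`, `hfs_events`, `psi_window`, `dopamine_window`,
#'   `hfs_duration`, `lfs_rate`, `jitter_sd`).
#' @return An `sr_protocol` object.
#' @examples
#' build_paradigm("p2")
#' build_paradigm("fig3_grid", stim_duration = 1200, psi_duration = 3600)
#' @export
build_paradigm <- function(name, psi = TRUE, stim_duration = 1200,
                           psi_duration = 7200, overrides = list()) {
  if (!is.character(name) || length(name) != 1 || !(name %in% paradigm_names))
    abort(paste0("unknown paradigm '", name, "'; valid names: ",
                 paste(paradigm_names, collapse = ", ")))
  min_ <- 60
  hfs_t <- 20 * min_
  base <- switch(
    name,
    p1 = list(duration = 600 * min_,
              lfs = list(c(0, 40 * min_), c(480 * min_, 600 * min_)),
              psi_window = c(100 * min_, 150 * min_)),
    p2 = ,
    fig5 = list(duration = 600 * min_,
                lfs = list(c(0, 40 * min_), c(150 * min_, 170 * min_),
                           c(480 * min_, 600 * min_)),
                psi_window = c(100 * min_, 250 * min_)),
    p3 = list(duration = 600 * min_,
              lfs = list(c(0, 110 * min_), c(150 * min_, 170 * min_),
                         c(480 * min_, 600 * min_)),
              psi_window = c(100 * min_, 250 * min_)),
    p4 = list(duration = 600 * min_,
              lfs = list(c(0, 600 * min_)),
              psi_window = c(200 * min_, 280 * min_)),
    fig3_grid = {
      ctr <- 150 * min_
      lfs <- list(c(0, 40 * min_))
      if (stim_duration > 0)
        lfs <- c(lfs, list(c(ctr - stim_duration / 2, ctr + stim_duration / 2)))
      list(duration = 280 * min_, lfs = lfs,
           psi_window = if (psi_duration > 0)
             c(ctr - psi_duration / 2, ctr + psi_duration / 2) else NULL)
    })
  lfs_rate <- overrides$lfs_rate %||% 0.1
  jitter_sd <- overrides$jitter_sd %||% 3e-3
  hfs_duration <- overrides$hfs_duration %||% 60
  blocks <- dplyr::bind_rows(lapply(base$lfs, function(b)
    stim_block(b[1], b[2], lfs_rate, jitter_sd)))
  psi_window <- if (psi) base$psi_window else NULL
  p <- new_protocol(
    duration = overrides$duration %||% base$duration,
    lfs_blocks = overrides$lfs_blocks %||% blocks,
    hfs_events = overrides$hfs_events %||% hfs_t,
    psi_window = if ("psi_window" %in% names(overrides))
      overrides$psi_window else psi_window,
    dopamine_window = if ("dopamine_window" %in% names(overrides))
      overrides$dopamine_window else
        c(hfs_t, hfs_t + hfs_duration),
    hfs_rate = overrides$hfs_rate %||% 100,
    hfs_duration = hfs_duration,
    lfs_rate = lfs_rate, jitter_sd = jitter_sd)
  p
}

#' @export
compress_time.sr_protocol <- function(x, lambda) {
  x$duration <- x$duration * lambda
  x$lfs_blocks$t_start <- x$lfs_blocks$t_start * lambda
  x$lfs_blocks$t_end <- x$lfs_blocks$t_end * lambda
  x$lfs_blocks$rate <- x$lfs_blocks$rate / lambda
  x$hfs_events <- x$hfs_events * lambda
  if (!is.null(x$psi_window)) x$psi_window <- x$psi_window * lambda
  if (!is.null(x$dopamine_window))
    x$dopamine_window <- x$dopamine_window * lambda
  x$hfs_duration <- x$hfs_duration * lambda
  x$lfs_rate <- x$lfs_rate / lambda
  validate_protocol(x)
  x
}

#' Nominal stimulation pulse times of a protocol
#'
#' The un-jittered pulse times of all low-frequency blocks (and optionally
#' the HFS pulses), used to drive the reduced model's activity filter.
#'
#' @param protocol An `sr_protocol`.
#' @param include_hfs Include the individual HFS pulses.
#' @return Sorted numeric vector of pulse times (s).
#' @export
pulse_times <- function(protocol, include_hfs = FALSE) {
  ts <- unlist(lapply(seq_len(nrow(protocol$lfs_blocks)), function(i)
    nominal_pulses(protocol$lfs_blocks[i, ])))
  if (include_hfs && length(protocol$hfs_events) > 0) {
    hfs <- unlist(lapply(protocol$hfs_events, function(t0)
      t0 + seq(0, protocol$hfs_duration - 1 / protocol$hfs_rate,
               by = 1 / protocol$hfs_rate)))
    ts <- c(ts, hfs)
  }
  sort(ts)
}

#' Serialize a protocol to JSON / read it back
#'
#' Times are stored in seconds.
#'
#' @param protocol An `sr_protocol`.
#' @param path File path.
#' @return `protocol_to_json()` returns `path` invisibly;
#'   `protocol_from_json()` returns an `sr_protocol`.
#' @export
protocol_to_json <- function(protocol, path) {
  x <- unclass(protocol)
  x$lfs_blocks <- as.data.frame(x$lfs_blocks)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname protocol_to_json
#' @export
protocol_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_protocol(duration = x$duration,
               lfs_blocks = tibble::as_tibble(x$lfs_blocks),
               hfs_events = as.numeric(x$hfs_events %||% numeric(0)),
               psi_window = if (!is.null(x$psi_window))
                 as.numeric(x$psi_window),
               dopamine_window = if (!is.null(x$dopamine_window))
                 as.numeric(x$dopamine_window),
               hfs_rate = x$hfs_rate, hfs_duration = x$hfs_duration,
               lfs_rate = x$lfs_rate, jitter_sd = x$jitter_sd)
}

#' Write spike trains as two-column TSV
#'
#' @param trains Tibble with columns `neuron`, `time`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  readr::write_tsv(trains[, c("neuron", "time")], path, col_names = TRUE)
  invisible(path)
}
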