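# Shared fixtures for the suite. Scaled runs use a compressed slow layer
# (see the methods vignette) with 100 fixed synapses; g0 is doubled so the
# per-volley conductance (and hence the burst and co-activity operating
# point) matches the 200-synapse calibration.
fast_wp_config <- function(paradigm, psi, variant = "original",
                           n_repeats = 6, seed = 101, lambda = 0.1,
                           n_syn = 100) {
  run_config(paradigm = paradigm, model = "write_protected", psi = psi,
             variant = variant, n_repeats = n_repeats, seed = seed,
             time_scale = lambda, n_synapses = n_syn,
             wp = wp_params(g0 = wp_params()$g0 * 200 / n_syn),
             pool = scale_pool_size(pool_params("wp"), n_syn / 200))
}

sb_config <- function(paradigm, psi, variant = "original", n_repeats = 10,
                      seed = 103) {
  run_config(paradigm = paradigm, model = "state_based", psi = psi,
             variant = variant, n_repeats = n_repeats, seed = seed)
}

# pooled standard error of a difference in means
pooled_se <- function(a, b) {
  sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

# memoised expensive runs shared between acceptance checks
.acc_env <- new.env(parent = emptyenv())
acc_cached <- function(key, expr) {
  if (!exists(key, .acc_env)) assign(key, force(expr), .acc_env)
  get(key, .acc_env)
}

# paradigm sweep used by the qualitative-classification checks
wp_paradigm_sweep <- function() {
  acc_cached("wp_sweep", {
    out <- list()
    for (par in c("p1", "p2", "p3", "p4")) {
      for (psi in c(TRUE, FALSE)) {
        run <- run_full(fast_wp_config(par, psi))
        out[[paste0(par, if (psi) "_psi" else "_ctrl")]] <- run
      }
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
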