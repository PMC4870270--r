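# synrecon

Stochastic simulation of **synaptic reconsolidation**: the degradation of
consolidated (late-phase LTP) synapses when protein synthesis inhibition
(PSI) coincides with renewed stimulation, and its "boundary conditions" —
the stimulation/PSI combinations under which degradation does or does not
occur. The package is for computational neuroscientists studying synaptic
consolidation models and for experimentalists who want a quantitative
sandbox for slice-style reconsolidation protocols.

## The model

Consolidated synapses are maintained by a finite pool of *stabilizing
entities* shared across the postsynaptic neuron. A consolidated synapse
(scaffold `z ≥ 0`) binds an entity at rate `k₁N_A + k₃N_A*` and releases it
at activity-dependent rates

```
k_α(I_A) = k₀ + m / (1 + exp((I₀^α − I_A)/r)),   α ∈ {2, 4},
```

into the PSI-susceptible pool (`k₂`) or the PSI-immune *reservoir* (`k₄`).
PSI sets `N_A = 0`; survival of consolidation then hinges on the reservoir,
which grows with stimulation before PSI and drains at `k̂₂·n_bound` during
it. This pool is layered on top of:

* the **write-protected model** — per-synapse bistable weight/tag/scaffold
  dynamics `τ dx/dt = f(x) + couplings + τσξ(t)`, `f(x) = x − x³`, driven
  by triplet STDP in a conductance-based LIF neuron (0.1 ms spikes, 100 ms
  synapse step), with the scaffold destabilized by `a_b/τ_z H(z)(b−1)`
  while unbound;
* a **reduced two-dimensional mean-field model** of `(n_ASyn, n_A*)` with a
  pulse-filtered activity and a delayed-slope rule for the consolidated
  count, used to map boundary conditions;
* a **seven-state Markov model** of 1000 synapses (readout
  `%fEPSP = (N_weak + 2N_strong)/1200 × 100`).

See `vignette("reconsolidation-methods")` for equations, parameter tables,
calibration of the conductance scale, and the numerical scheme.

## Worked example

A time-compressed run (slow layer compressed 10×; see the vignette) of the
degrading paradigm — 20 min of 0.1 Hz stimulation in the midst of PSI —
against its no-PSI control:

```r
library(synrecon)

psi  <- run_full(run_config(paradigm = "p2", model = "write_protected",
                            psi = TRUE,  n_repeats = 10, seed = 1,
                            time_scale = 0.1))
ctrl <- run_full(run_config(paradigm = "p2", model = "write_protected",
                            psi = FALSE, n_repeats = 10, seed = 1,
                            time_scale = 0.1))
compare_runs(psi, ctrl)
#> # A tibble: 1 x 7
#>   estimate_a estimate_b statistic  p_value conf_low conf_high method
#>        <dbl>      <dbl>     <dbl>    <dbl>    <dbl>     <dbl> <chr>
#> 1     -0.415      0.986     -14.5  1.47e-7    -1.62     -1.18 Welch Two...
```

The mean synaptic weight (±1 per synapse) ends near its potentiated value
(+0.99) in the control but collapses toward the depressed state under
PSI-plus-stimulation (−0.41 averaged over the final 30 compressed minutes);
the Welch test across the 10 simulated neurons puts the difference at
p ≈ 1.5×10⁻⁷. `autoplot(psi)` shows the full time course with the PSI window
shaded; paradigms `"p1"`, `"p3"`, `"p4"` instead end indistinguishable from
control.

The boundary-condition map of the reduced model:

```r
red  <- run_reduced(run_config(paradigm = "fig3_grid", model = "reduced",
                               time_scale = 0.1, seed = 1, n_repeats = 1))
autoplot(red$boundary_map)   # remaining consolidated fraction, U-shaped
```

The state-based analogue runs at full scale in seconds:

```r
sb <- run_state_based(run_config(paradigm = "p2", model = "state_based",
                                 psi = TRUE, n_repeats = 10, seed = 1))
glance(sb)$end_mean  # 135.4 %fEPSP vs 145.3 for the no-PSI control
```

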