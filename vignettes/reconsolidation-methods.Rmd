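---
title: "Models and methods: simulating synaptic reconsolidation with a shared stabilizer pool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating synaptic reconsolidation with a shared stabilizer pool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(synrecon)
```

# The scientific problem

Hippocampal slice experiments show that consolidated (late-phase LTP)
synapses can be *degraded* when protein synthesis inhibition (PSI) coincides
with renewed low-frequency stimulation (LFS), while PSI alone, or PSI after
prolonged stimulation, leaves them intact — a synaptic analogue of
behavioral memory reconsolidation and its "boundary conditions". `synrecon`
simulates this phenomenology with three interlocking models:

1. a **detailed write-protected network**: a conductance-based
   leaky-integrate-and-fire (LIF) neuron receiving ~200 plastic synapses,
   each with coupled bistable weight/tag/scaffold variables driven by
   triplet spike-timing-dependent plasticity (STDP), and a finite shared
   pool of *stabilizing entities* whose binding maintains consolidated
   scaffolds;
2. a **reduced two-dimensional mean-field model** of the bound-synapse
   count and the PSI-immune *reservoir* of stabilizers, used to map the
   boundary conditions over stimulation-duration × PSI-duration grids;
3. a **seven-state Markov model** of 1000 synapses (weak/strong ×
   stability tiers plus a stabilizer-bound state) sharing the same pool
   kinetics.

# Stabilizer pool

Each consolidated ("big", scaffold `z >= 0`) synapse binds one stabilizing
entity at rate `k1*N_A + k3*N_A_star`, where `N_A` counts free
PSI-susceptible entities and `N_A_star` the free PSI-immune reservoir. A
bound synapse releases its entity at rate `k2(I_A) + k4(I_A)`, into the
susceptible pool or the reservoir respectively, with the logistic activity
dependence

```
k(I_A) = k0 + m / (1 + exp((I0 - I_A)/r)).
```

PSI empties the susceptible pool (`N_A <- 0`; entities released into it
degrade immediately); its end replenishes `N_A` to
`N_A_tot - N_A_star - n_bound`. The stochastic update processes synapses in
a fresh random order each step with first-order probabilities `rate * dt`
(asserted `< 1`).

The mechanism in one paragraph: stimulation raises the co-activity `I_A`,
which accelerates unbinding — mostly into the immune reservoir (`I0_4 <
I0_2`) — so *stimulation before PSI grows the reservoir*; during PSI the
susceptible pool is gone and every rebinding draws the reservoir down at
rate `k2(I_A) * n_bound`, so *stimulation during PSI drains it faster*.
Consolidation collapses exactly when the reservoir empties while synapses
still need rebinding.

# Detailed model

The LIF neuron (Table-standard parameters: `tau_m` 20 ms, reversal 0 mV,
adaptive threshold resetting to +100 mV with 2 ms relaxation,
spike-triggered adaptation `g_spike = 10` toward −80 mV) receives AMPA-like
(5 ms) and NMDA-like (100 ms low-pass) conductances mixed 50/50. Presynaptic
spike trains are jittered periodic pulses (Gaussian sd 3 ms): 0.1 Hz LFS for
monitoring, 100 Hz for 60 s as HFS to induce LTP, with a coincident 60 s
dopamine pulse driving the plasticity-product gate `p` (rise `k_up` = 1/s,
decay `k_down` = 1/2000 s).

Each synapse's weight `w`, tag `T` and scaffold `z` follow coupled
double-well dynamics `dx/dt = f(x)/tau + couplings + sigma xi(t)` with
`f(x) = x - x^3`; the weight-tag gate opens when the accumulator `gamma`
crosses 0.37; the scaffold is destabilized by `a_b/tau_z * H(z)(b-1)`
whenever the synapse is unbound (`b = 0`), which is what makes consolidation
binding-dependent. Triplet STDP supplies the drives: potentiation
`A+ x+ y_triplet` at postsynaptic spikes (the slow trace read before its own
increment), depression `A- y-` at presynaptic spikes; their sum,
low-passed with `tau_A` = 150 s, is the per-synapse co-activity `I_A` that
the unbinding rates read.

## Numerical scheme and impulse convention

Spikes live on a 0.1 ms grid; synapse variables and the pool are updated
every 100 ms (Euler–Maruyama, noise `sigma*sqrt(dt)*N(0,1)`); inductions
are accumulated over each slow step and applied as *direct impulses* (a
per-event increment of magnitude `I`, not `I*dt`) to `w`, to `gamma`
(times `kappa` = 1 s), and to `I_A`. Two numerical choices deviate from a
plain explicit scheme and are deliberate:

* **Membrane integrator.** A synchronized volley drives the total
  conductance to hundreds of leak units, far beyond the explicit-Euler
  stability bound `2*tau_m/dt = 400`; an explicit step produces a spurious
  self-sustaining ~5 kHz oscillation. The membrane therefore uses the
  exponential integrator (exact for conductances held over a step,
  unconditionally stable); conductances, threshold and all slow variables
  keep their explicit updates. The closed-form membrane decay test passes
  exactly.
* **Saturating impulse application.** During HFS the 100 ms-aggregated
  induction can exceed the width of the weight's well; the accumulated
  impulse is applied in sub-chunks of at most 0.05 with the saturation
  factors `(1 + [z-w]_+)(1-w)` recomputed between chunks, which converges
  to the continuous-drive limit and cannot overshoot.

Triplet traces use exact exponential decay between events (event-driven in
the compiled core), which makes them identical to the analytic closed form.

## Calibrating the conductance scale, and the activity operating point

The conductance scale `g0` in `dg = g0*(w_- + (w+1)(w_+-w_-)/2)` is not
fixed by the printed parameters, yet everything hinges on it, because it
sets the postsynaptic burst per LFS volley and hence the co-activity level
during stimulation. The model's activity-dependent unbinding only
differentiates stimulation from silence if LFS-driven `I_A` falls *between*
the half-activations `I0_4 = 0.045` and `I0_2 = 0.057`: below, the
reservoir never grows faster with activity; above (both sigmoids
saturated), the susceptible-pool unbinding `k2` is maximal during any
stimulation and the continuous-stimulation paradigm necessarily depletes
its reservoir, contradicting the phenomenology it must reproduce. In the
reduced model the same operating point is set by `omega`: each pulse
raises the filtered activity by `omega/tau_A`, so sustained 0.1 Hz LFS
settles at `omega * 0.1`. The package default `omega = 0.54 s` places that
at 0.054, inside the window. (A per-second reading of the tabulated
magnitude, 5.4 s, would put LFS activity at 0.54, an order of magnitude
above both half-activations, and destroys the paradigm separation for the
reasons above; we treat it as a units slip and expose `omega` as a
parameter.)

`calibrate_g0()` matches the full model to this operating point: it
bisects `g0` until a single synchronized volley at the potentiated weight
configuration yields a summed per-synapse induction `J ~= omega/tau_A`
(about 6 burst spikes). The calibration deliberately uses the potentiated
configuration because the stimulation whose co-activity matters occurs
after LTP induction; at the depressed configuration the same `g0` yields a
per-volley weight drive (~`2*J_dep` ≈ 0.004 per pulse period) well below
the bistable restoring flux (~0.019), so monitoring stimulation neither
potentiates the naive baseline nor re-potentiates a degraded population.
The cached default (`g0 = 20.4`) targets `J = 0.0039` because within a
pulse train the per-pulse induction runs ~8% below the isolated volley at
the package's working pulse spacing (adaptation and trace carry-over).

# Protocol timelines

`build_paradigm()` encodes the four slice paradigms on a 10 h span, HFS at
minute 20 under background 0.1 Hz LFS, with a final extended LFS block at
8–10 h:

| paradigm | LFS blocks (min) | PSI (min) | outcome |
|---|---|---|---|
| p1 | 0–40, 480–600 | 100–150 | persists |
| p2 | 0–40, 150–170, 480–600 | 100–250 | degrades (delayed) |
| p3 | 0–110, 150–170, 480–600 | 100–250 | persists |
| p4 | continuous | 200–280 | persists |

The PSI durations are not printed in the source experiments and were fixed
here from the reservoir flux budget: buildup to PSI start is ~535 entities
for the 40-min-LFS paradigms and ~1400+ for the long/continuous ones, and
the drains are `k0*N_big ~= 0.1/s` without stimulation and ~0.21/s during
in-window LFS. The chosen windows give persist margins of roughly 3–5
ensemble standard deviations for p1/p3/p4 and a clear depletion (~200
entities past the budget) for p2, whose decay consequently begins tens of
minutes into the PSI — the delayed, highly significant degradation the
experiments report. p4's PSI is placed later because its continuous
stimulation needs no silence anchor and its reservoir, like the
experimental preparation, tolerates PSI best after long stimulation. These
are editable defaults, not fitted quantities; nearby values flip p1/p2,
which is faithful to the knife-edge character of the original model (its
authors note that slightly longer PSI would have degraded their
continuous-stimulation simulation too).

# Reduced model

The mean bound count and reservoir follow

```
dn_ASyn/dt = -(k2^ + k4^) n_ASyn + (k1 n_A + k3 n_A*) (N_big - n_ASyn)
dn_A*/dt   = -k3 n_A* (N_big - n_ASyn) + k4^ n_ASyn
```

with `n_A = N_A_tot - n_ASyn - n_A*` (zero during PSI), driven by the
pulse-filtered activity. The consolidated count `N_big` decays by a
delayed-slope rule: the finite-difference slope of `n_ASyn` over `eta` =
10 s, read `phi` = 72 s in the past, is applied to `N_big` only when
steeper than `theta_big`. The package default is `theta_big = -80` per
*hour* (−0.022/s): the fastest possible collapse of the bound count is
`(k0+m)*N_big ~= 0.4/s`, so a per-second reading of the tabulated
magnitude can never fire and would leave the boundary map identically 1,
while −0.022/s cleanly separates depletion collapse (~−0.2/s) from
ordinary cycling drift (~−0.002/s). Integration uses Euler at `dt` = 0.1 s.

`handoff_from_full()` seeds the reduced model from a detailed-model
snapshot at the end of the 60 min initiation phase (20 min LFS, HFS,
20 min LFS, 20 min silence), after which all big synapses are bound.
`map_boundary()` then sweeps stimulation × PSI windows (both centered at
minute 150, 0–2.5 h, protocol end at minute 280) and reports the remaining
consolidated fraction. The map's signature feature reproduces: at fixed
PSI duration the outcome is non-monotonic in stimulation duration —
short stimulation leaves the reservoir drain slow (persist), intermediate
stimulation drains it inside PSI (degrade), and stimulation longer than the
PSI window rebuilds the reservoir before PSI begins (persist).

# State-based model

Seven states: weak stable/intermediate/basal (1–3), strong
basal/intermediate/stable (4–6), and the stabilizer-bound state 7
(`state 7 == bound`; binding 6→7, unbinding 7→6). Baseline rates
(per minute in the tables, stored per second): `alpha` 0.017, `beta`
0.067, `tau_e` 0.017, `tau_l` 0.01, `tau_r` 1e-4. An HFS pulse moves all
weak-basal synapses to strong-basal, raises `alpha` to 1/h and switches on
the transient rates `p(t)` (4→5) and `c(t)` (5→6). State 6 decays to the
strong-basal state at `tau_l` (a configuration switch targets state 3
instead, matching an alternative reading of the scheme); state 7 decays at
`tau_r`, releasing its entity into the susceptible pool. The readout is
`%fEPSP = (N_weak + 2 N_strong)/1200 * 100`, 100% at the 800/200 start.

Because all rates are global, synapses are exchangeable and the per-synapse
scheme is simulated *exactly* on state counts with sequential binomial
draws (this is the stochastic process itself, not a mean-field
approximation); the reported s.e.m. comes from independent repeats. The
model has no spiking front end; the unbinding rates read the reduced
model's pulse-filtered activity.

Two tabulated values for the state-based pool required correction before
the model could reproduce its own figures, and both are exposed as
parameters: (i) the pool rate column is read per minute like every other
state-based rate — per second, the binding probability at the printed 1 s
step exceeds 6 and the PSI drain `k0*N7 ~= 18/s` would exhaust the entire
pool in minutes, making every paradigm degrade; (ii) the immune-binding
avidity is set to the same `k3/k1` ratio as the write-protected column
(≈5.7) — at the printed ratio of 100, rebinding drains the reservoir back
into circulation so fast that it equilibrates at ~1% of the pool and no
paradigm survives PSI. The stabilizer exchange runs on a 0.5 s substep of
the 1 s state step to keep first-order probabilities below 0.1.

# Scaled-down runs: exact time compression

Full-scale detailed runs (10 h at 0.1 ms) are expensive, so the experiment
runners support `time_scale = lambda`: durations and slow time constants
(`tau_w/T/z`, `tau_gamma`, `tau_A`, pool rates, `k_down`, the synapse step,
`omega`, `theta_big`, the state-based rates and HFS rate shapes) are
rescaled so that the compressed run is an exact time-rescaling of the slow
subsystem — fluxes per protocol, Euler–Maruyama law (`sigma` scales as
`1/sqrt(lambda)`), and persist/decay outcomes are invariant by
construction. Stimulation *rates* scale inversely (LFS 0.1→1 Hz at
`lambda = 0.1`; HFS stays 100 Hz but shortens), while the millisecond-scale
neuron and trace dynamics are untouched; the only compression artifact is
the ~8% pulse-spacing effect on per-volley induction absorbed by the
calibration above. The package's canonical study conditions for the
detailed model are `lambda = 0.1` (1 h compressed span), 10 repeats,
presynaptic counts drawn per repeat from Binomial(400, 0.5) (mean 200);
the state-based and reduced models run at full printed scale. The test
suite uses `lambda = 0.05` with 100 fixed synapses for the paradigm sweeps
and the acceptance script uses `lambda = 0.1`; these sizes are the
package's chosen operating points, stated here so results are read at the
scale that produced them.

# What the generator does and does not emulate

The protocol generator reproduces the stimulation structure of the slice
experiments: jittered periodic afferent volleys, a single tetanus with a
coincident neuromodulatory pulse, pharmacological PSI as a hard window.
It does not emulate slice variability in afferent recruitment, incomplete
pharmacological washout (PSI edges are instantaneous), heterosynaptic
competition, or inhibitory circuitry (absent from the model by design).
Passing tests therefore show that the implemented mechanism produces the
reported phenomenology under idealized stimulation, not that the parameter
values are uniquely determined by slice data.

# Known limitations

* The paradigm separation is intrinsically knife-edged: the LFS operating
  point sits in a 0.012-wide logistic window and the p1/p2 distinction
  rests on PSI-duration budgets of order 20–40% of the reservoir. This is
  a property of the model, not of the implementation; single repeats can
  and do cross the boundary.
* The mean-field reduction slightly underestimates the reservoir during
  fast drains (synapse-rate correlations are neglected, as its derivation
  acknowledges); agreement is within ~3 ensemble s.e.m. on the tested
  protocols once the handoff uses an ensemble-averaged snapshot.
* Degradation magnitude in the state-based model is modest (a few fEPSP
  points) because the post-depletion spill 6→4 is rate-limited by
  `tau_l`; claims about it are therefore tested as ensemble-mean
  orderings.
* In the activity-gated-noise variant, the mid-PSI stimulation window
  briefly re-arms the noise while scaffolds are already collapsing, so the
  pre-final-stimulation trace carries a small residue of decay (a few
  hundredths of the weight scale) rather than being literally identical to
  control.
* Entities bound to a synapse whose scaffold collapses stay bound until a
  stochastic unbinding; the alternative (immediate release) was not
  explored.

# Reproducing the headline quantities

`scripts/acceptance.R` re-runs, from scratch: the state-based readout
normalization at initialization, and the paradigm-2 PSI-versus-control
comparison of end-of-run mean weights (10 compressed repeats each, Welch
test on the final-window time averages). See the README for invocation.
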