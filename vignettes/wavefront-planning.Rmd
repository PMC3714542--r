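---
title: "Wavefront path planning in a spiking place-cell network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavefront path planning in a spiking place-cell network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`wavenav` simulates a sheet of excitatory place cells tiling a 2-D
environment. Each cell fires maximally when a simulated agent is near the
center of its receptive field; recurrent excitatory synapses connect only
cells whose fields overlap. Planning proceeds in four phases:

1. **Exploration.** A noisy constant-speed trajectory with specular wall
   bounces samples the environment. Co-activation statistics of place-cell
   spikes select, for each cell, incoming synapses of equal strength from its
   `m` most strongly co-active partners — in practice its geometric
   neighbours that share no intervening wall. This baseline connectivity is
   snapshotted for later resets.
2. **Planning.** An "exciter" briefly drives the cells at the target
   location; a single wavefront of spikes then propagates outward, each cell
   firing exactly once. During the passage, plasticity runs in *reverse*
   (anti-STDP, polarity `d = -1`): a synapse whose presynaptic cell fired
   before its postsynaptic cell (pointing away from the source) weakens, and
   the reverse synapse strengthens. The resulting **synaptic vector field**
   (SVF) — each cell's weighted centroid of outgoing synapses — points back
   along the front's arrival direction, i.e. toward the target along the
   shortest route.
3. **Navigation.** With plasticity off (`d = 0`) and weak global inhibition
   on, the cells around the agent's position receive tonic drive. Every
   spike delivers a force impulse pulling the agent toward that cell's field
   center; because the asymmetric weights make target-side cells fire
   preferentially, the agent flows along the field.
4. **Reset.** Before a new plan, all synapses return to the baseline
   snapshot, which makes the SVF identically zero again.

Membrane dynamics are adaptive leaky integrate-and-fire: time constant
`tau_m = C_m R_m` = 20 ms (1 nF x 20 MOhm), rest and reset at 0 mV, threshold
10 mV, absolute refractory period 2 ms, Euler integration at `dt` = 0.2 ms.
Each spike increments a calcium-like adaptation current `i_Ca` that decays
with `tau_ca` (default 2 s); it blocks re-firing, which is what keeps the
front single-spike and forbids a second front until adaptation fades.
Synaptic currents rise instantaneously and decay with 25 ms. Input currents
sum **supralinearly**: `i_syn = a_syn tanh(b_syn N) * sum_j w_j i_j` with `N`
the number of recently active inputs, so a cooperative volley is far more
effective per input than an isolated spike. Global inhibition is a
continuous population variable driven by every excitatory spike; it is
gated off during planning and on during exploration and navigation.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `neuron$dt` | 2e-4 | s | Euler step |
| `neuron$threshold` | 10 | mV | spike threshold |
| `neuron$tau_ca`, `dI_ca` | 2, 40 | s, nA | adaptation decay / increment |
| `neuron$tau_syn` | 0.025 | s | synaptic current decay |
| `neuron$eps_active` | 0.3 | nA | trace level at which an input counts as "active" for the coincidence count |
| `neuron$syn_delay` | 0 | s | synaptic transmission delay (dual-map scenario: 5 ms) |
| `synapse$a_syn`, `b_syn` | 10, 0.05 | — | supralinear gain and sharpness |
| `stdp$A_ji`, `A_ij`, `tau_w` | 1, 0.5, 0.02 | —, —, s | learning-window amplitudes (causal > anti-causal) and width |
| `stdp$eta` | 0.4 | — | learning-rate scale |
| `exploration$m` | 12 | — | incoming synapses kept per cell |
| `exploration$w0` | 0.5 | — | baseline synaptic weight |
| `placefields$footprint` | 35 | cells | cells within `2 sigma` of a center |
| `agent$a_F`, `damping`, `tonic_amp` | 2, 5, 1.6 | — | spike-force gain, viscous drag, tonic drive |

The field width `sigma` is derived from the grid pitch so the footprint
covers the configured cell count (25–50 at the ~2000-cell scale): `sigma =
pitch * sqrt(footprint / pi) / 2`. Only the footprint count is constrained by
the modelling regime; neither `sigma` nor the pitch is meaningful on its own.

Several quantities were deliberately calibrated, once, against the model's
own qualitative requirements (and are not per-experiment dials):

* `m = 12` with `dI_ca = 40` places the front deep in the stable single-fire
  regime. At `m = 8` propagation is marginal: coverage collapses for some
  map realizations (corridor mazes are the first to fail); 2-D fronts need
  enough convergent inputs that the supralinear volley reliably clears
  threshold one hop ahead.
* `eta = 0.4` makes the causal/anti-causal weight changes roughly 40%/20% of
  the baseline weight. Much smaller changes are swamped by the geometric
  asymmetry that center jitter induces in the baseline weighted centroid;
  clipping at `w_min = 0`, `w_max = 2` still never engages during a single
  passage.
* The seed pulse (30 nA for 1 ms over cells within `sigma` of the target,
  typically 5–15 cells) drives the cluster to fire within 2 ms; a single
  cell cannot start a front, which is exactly the supralinear noise guard.
* `tonic_amp = 1.6` nA makes the navigation bump wide enough that the
  direction statistics of its spikes resolve the field reliably; at 1.2 nA
  paths meander (ratios to the geodesic around 1.7 instead of 1.1).
* The stall window during navigation is 12 s: when the agent overshoots
  into a corner whose cells are all adapted, re-excitation takes
  `tau_ca * log(dI_ca / i_margin)` (about 7–9 s), after which the bump
  re-ignites and the run usually completes.

## The synthetic environments

Built-in mazes: a unit square (`"open"`), a T-shaped corridor (`"T"`: one
junction, three arm tips), a triangular loop with one hole (`"A"`), and a
figure-of-eight with two holes (`"inf"`). Only the topology of the latter
two is contractual; their proportions are fixture choices. Place-field
centers sit on a per-environment regular grid (pitch chosen so `n` cells
tile the area) with Gaussian jitter of 0.15 pitch, re-drawn if pushed
outside a wall; neurons are paired to centers by an independent uniform
permutation per environment.

What the generator emulates: uniform coverage, local-only connectivity,
wall-respecting adjacency, independent multi-map assignments. What it does
not: place-field learning from sensory input, non-uniform field densities,
multi-scale fields, realistic rodent trajectories. Passing tests therefore
validate the planning mechanism on idealized maps, not the formation of the
maps themselves.

## Numerical choices

* All state decays use exact per-step exponentials; the membrane equation is
  forward Euler. Spike timestamps are quantized to the step (no sub-step
  interpolation); halving `dt` moves the median first-spike time by about
  half a coarse step, which is the quantization floor.
* The online STDP uses pre/post exponential traces and is algebraically
  identical to the all-pairs double-sum for exponential kernels; the
  acceptance suite verifies agreement to ~1e-14 relative. Simultaneous
  (same-step) pairs take the causal branch on both synapses, matching the
  `s <= 0` boundary convention. Weight clipping is applied per event.
* The activity-independent decay term (`a_decay <= 0`) drifts weights toward
  the baseline snapshot and is gated off together with the pairing term when
  `d = 0`; a decay that persisted during movement would erase the field
  while it is being used.
* The SVF is computed by default on the rectified wavefront-induced change
  `max(w - w_baseline, 0)` ("delta" mode), restricted to projections within
  `3 sigma` in the rendering coordinates. Two reasons: the reset-zero
  invariant is then exact, and in multi-map networks the raw-weight field is
  dominated by a spurious centripetal pull from the other map's partners
  (whose positions in these coordinates are uniform, so their baseline-
  weighted centroid is the region centroid). The literal raw-weight form
  remains available (`mode = "direct"`).
* The attractor is located from two smoothed score maps whose minima mark
  the wavefront source — the raw mean outgoing weight (sources weaken their
  outgoing synapses) and the delta outflow/total-flow ratio (sources gain
  inflow) — averaging their depth-weighted minima. Localization accuracy is
  about 0.5–1 grid pitch; single-score minima are noisier and can be
  captured by boundary cells.
* Ties in the top-`m` connectivity selection break toward the lower neuron
  index; geodesic-Voronoi ties break toward the lower target index and are
  flagged.
* Degenerate inputs rejected with errors: targets outside the environment,
  seeding footprints below 3 cells, self-intersecting or disconnected
  geometries, empty spike records, runaway population activity (guard at
  `6 n` spikes).

## Design decisions on open points

* The exploration spike generator is a rate-proportional Poisson emitter
  (rate `rate_max` at the field center); the full integrate-and-fire path
  driven along the trajectory exists behind `full_lif`, but the selection
  of top-`m` co-active partners only consumes pair timings and is
  insensitive to the emitter's details (halving the pair constant changes
  the selected sets by under 10%).
* Exploration pair weighting uses causal amplitude 1 and anti-causal
  amplitude 0.5 (the net-potentiating `d = +1` reading). A symmetric
  `exp(-|dt|/tau_e)` sum would be exactly symmetric in (pre, post) and make
  the direction-asymmetry diagnostic vacuous.
* Wavefront source labels are assigned by causal attribution: a cell takes
  the majority label among its presynaptic partners that spiked within the
  integration window before it; exciter pulses and injected noise events
  carry their own labels (targets 1..k, noise 0). Basins of attraction are
  then label sets, comparable to the geodesic-Voronoi oracle.
* The front speed used to convert reward differences into initiation delays
  is measured from a calibration fit of first-spike time against geodesic
  distance, never assumed.
* Planning terminates either when a cell within `sigma` of the agent fires
  (the agent-reached rule, applied globally) or after a 50 ms quiescence
  window when charting the whole map.
* Navigation stops inside a capture radius of `2 sigma`; trial-to-trial
  variability comes from the per-step membrane noise (0.25 nA during
  navigation), and distinct seeds give distinct microscopic paths with the
  same macroscopic route.

## Two maps in one network

When each neuron has an independent field in two environments and both maps'
connectivities are present, the other map's synapses act as long-range
projections. This condition is *qualitatively harder* than a single map: a
volley of front spikes projects, through the foreign map, onto essentially
random cells, and any parameter set strong enough to guarantee full-map
coverage also lets those scattered coincidences relay activity non-locally
(measured as the first-spike-vs-geodesic correlation collapsing from 0.95+
to ~0.6 while the apparent speed inflates by an order of magnitude). The
dual-map scenario therefore runs at its own operating point — per-map
in-degree 16, `a_syn = 3.4`, a 5 ms synaptic transmission delay to cap the
front speed, `eps_active = 0.5`, `dI_ca = 80`, and area-matched mazes — where
the front is a clean map-local wave. The trade-off is range: the wave maps
the target's neighbourhood (roughly 10–20% of the cells around the target)
before dying, rather than the whole arena. Within the mapped region the
field aligns with the geodesic descent direction at median cosine ~0.93, the
same weights rendered in the other map's coordinates are directionally
random (local coherence below the shuffled-assignment null), and navigation
from starts inside the region reaches the target; from starts outside it,
navigation is unreliable. The single-map experiments are unaffected: they
run at the strong-drive default, full coverage, with no transmission delay.

## Known limitations

* Dual-map planning covers the target's neighbourhood, not the full map
  (previous section); with the printed membrane and summation model we found
  no parameter set that does both.
* Attractor localization is accurate to about one grid pitch and can be
  worse for targets at corridor dead-ends.
* Inhibition is a single global continuous variable, not a spiking
  interneuron population; bursts, conductance synapses and learned
  initiation delays are out of scope.
* The agent's motor model is a damped point mass with velocity kicks; no
  neural motor readout is simulated.

## Problem sizes used by the shipped checks

Wavefront/SVF checks run at 2000 cells (open arena and T maze); the basin
experiment at 1600; refractoriness and noise at 900; the dual-map scenario
at 1800 cells per map; the plasticity-oracle comparison on a 30-cell
scripted network. A full plan-plus-navigate scenario takes seconds to a few
minutes on one CPU at these sizes.
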