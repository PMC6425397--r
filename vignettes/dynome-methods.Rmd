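---
title: "Methods: the dynome model, its numerics, and the design choices behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dynome model, its numerics, and the design choices behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynome)
```

This vignette documents the model the package integrates, the numerical
choices behind the integrator and the playback protocol, and the design
decisions taken where the problem was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model and its assumptions

*C. elegans* neurons are graded-potential (non-spiking) cells, so each
neuron is modelled as a single isopotential compartment with a leak, gap
junction (electrical) couplings, and chemical synapses gated by a
first-order activity variable:

$$C \frac{dV_i}{dt} = -G_c (V_i - E_{cell})
  - \sum_j G^g_{ij}(V_i - V_j)
  - \sum_j G^s_{ij}\, s_j (V_i - E_j)
  + I^{ext}_i$$

$$\frac{ds_i}{dt} = a_r\, \Phi(V_i;\beta,V_{th,i})(1-s_i) - a_d\, s_i,
  \qquad \Phi(V) = \frac{1}{1 + e^{-\beta (V - V_{th})}}$$

Assumptions worth making explicit:

* **Single compartment, no morphology.** All spatial structure is
  collapsed; the connectome matrices are the only geometry.
* **Graded transmission.** Synaptic release is a smooth sigmoid of the
  presynaptic voltage; there are no spikes, no transmission delays and no
  autaptic terms.
* **Static weights.** No plasticity; conductivities change only through
  ablation/reinsertion or the explicit robustness perturbations.
* **Two transmitter classes.** A synapse is excitatory (reversal 0 mV) or
  GABAergic/inhibitory (−48 mV) according to the *presynaptic* neuron's
  class.

## Parameters and units

| parameter | default | unit | meaning |
|---|---|---|---|
| `C` | 1.5 | pF | membrane capacitance |
| `Gc` | 10 | pS | membrane (leak) conductance |
| `Ecell` | −35 | mV | leak potential |
| `g` | 100 | pS | conductance per gap/synaptic junction |
| `a_r`, `a_d` | 1/1.5, 5/1.5 | s⁻¹ | synaptic rise/decay rates |
| `beta` | 0.125 | mV⁻¹ | activation sigmoid width |
| `E_j` | 0 / −48 | mV | excitatory / inhibitory reversal |

These are the standard literature values for this model class; none are
fitted here. `C` and `Gc` accept per-neuron vectors, which is what the
robustness scan perturbs.

**Normalization.** The voltage equation is divided through by the
per-junction conductance (100 pS). Conductance matrices then become
dimensionless junction counts, `Gc` becomes 0.1, `C/g` becomes 0.015 s
(leak time constant `C/Gc` = 0.15 s), and the natural unit of injected
current — 1 "arb" — equals 0.1 pA, so 1 nA = 10,000 arb. All user-facing
stimulus interfaces take nA and convert (`nA_to_arb()`); matrices are
stored in pS and normalized on entry to the right-hand side.

## The threshold potentials

$V_{th}$ plays two roles: it is the network's operating point, and it
centres the activation sigmoid. It is obtained by imposing $dV/dt = 0$
with $s$ frozen at its half-activation equilibrium
$s_{eq} = a_r/(a_r + 2 a_d) = 1/11$ and solving the linear system
$Ax = b$ built from the leak, gap and synaptic conductances
(`compute_vth()`); the solution's residual is checked against
$10^{-10}\,\|b\|_\infty$.

**Gap term: Laplacian vs diagonal (design decision).** A literal reading
of some descriptions of this system treats the gap contribution as a
purely diagonal term $-\sum_j G^g_{ij}$ on $A$'s diagonal. The
zero-derivative condition of the membrane equation, however, also carries
the off-diagonal $+G^g_{ij} V_j$ couplings: the consistent gap operator is
the full weighted graph Laplacian. The diagonal-only variant coincides
with the Laplacian one exactly when all gap neighbours sit at 0 mV, but
for a driven gap pair it predicts thresholds near −2 mV where the
consistent solution gives ≈ −30 mV — physically implausible for a cell
whose every input reverses below −35 mV. The package therefore defaults to
the Laplacian (`mode = "laplacian"`), which is also the fixed point the
simulated dynamics actually converge to on gap-only networks (an oracle
equivalence the test suite checks); `mode = "diagonal"` is kept for
comparison.

**Recomputation policy (open question).** Nothing in the model fixes when
$V_{th}$ should be refreshed while stimuli are in flight. The package
recomputes it (i) at every structural event and (ii) at the first block
boundary after a stimulus transition completes ($t_{switch} + 2\,
t_{offset}$), using the stimulus vector evaluated at that boundary. It is
*not* recomputed continuously during a transition; the transition period
is 300 ms against a 150 ms membrane time constant, and refreshing at
completion keeps the fixed point consistent with the settled stimulus
while keeping the factorization count proportional to the number of
events, not blocks.

## Integration

The 2N-dimensional system is integrated with `deSolve`'s `lsoda` — an
adaptive, stiff-capable method with dense output — at relative tolerance
1e−9, absolute tolerance 1e−10 and minimum step 1e−9 s, sampled uniformly
every 10 ms. Simulation proceeds in 50 ms blocks (the playback protocol's
data-stack length). `tcrit` pins the solver at each block end so it never
evaluates the right-hand side beyond the block — this matters for
event-ordering exactness (below).

* **Initial condition.** V and s are drawn i.i.d. Normal(0, 0.94)·10⁻⁴
  (a 2N draw, V first), i.e. the network starts within a fraction of a
  microvolt of 0; s is clamped into [0, 1], which at that scale changes
  nothing at reported precision but keeps the activity invariant exact.
  The draw is deterministic given the seed and restores the caller's RNG
  state.
* **Events.** Stimulus changes are continuous in time (tanh blends), so
  they need no discontinuity handling inside the solver. Structural
  events (ablation/reinsertion) are instantaneous matrix edits and are
  quantized to the next block boundary — the protocol quantizes user
  actions to blocks anyway — with the state vector untouched: an ablated
  neuron keeps integrating as an isolated leaky cell under its stimulus.
* **Invariants checked in the suite.** s stays in [0, 1] (the vector
  field points inward at both boundaries); voltages stay within
  conductance-weighted bounds plus I/G; chaining two 50 ms blocks equals
  one 100 ms block within 10·atol; halving tolerances moves sampled
  trajectories by less than a small multiple of the coarser tolerance
  (global error accumulates a modest factor over the per-step bound).

## Stimulus transitions

An amplitude change at $t_{switch}$ blends old and new values with a pair
of hyperbolic tangents centred $t_{offset} = 150$ ms after the switch with
width $r = 25$ ms; the transition is complete (residue below
$10^{-4}\,|\Delta S|$) by $t_{switch} + 2 t_{offset} \approx 300$ ms.

Two semantics were open:

* **Superseding transitions.** A second change arriving mid-flight reads
  its `S_old` from the *currently evaluated* value, not the previous
  target, so rapid successive changes stay continuous.
* **Pre-declaration equivalence.** An event contributes only strictly
  after its own switch time. Together with `tcrit`, this makes a
  pre-declared event schedule *bit-identical* to the same events injected
  live at block boundaries: the tanh's sub-$10^{-5}$ onset tail is never
  sampled before the event exists in either mode. (The residual jump at
  onset, $\tfrac12(1+\tanh(-6))\,\Delta S \approx 6\times10^{-6} \Delta S$,
  is far below integration tolerances at physiological amplitudes.)
* **Ties.** Events landing on the same block boundary apply in timestamp
  order with ablation first.

## The playback protocol

The computation/visualization loop keeps two clocks, `t_computed` and
`t_visualization`, and computes the next 50 ms block only while
`t_computed − t_visualization ≤ t_buffer` (100 ms), polling with a 50 ms
refractory period between failed checks. Playback advances at 100 ms of
simulated time per wall second, dropping to 40 ms/s while a transition or
ablation is in flight. The induction is immediate and asserted at every
iteration: the lead never exceeds `t_buffer + Δt`.

Design choices:

* **Transport-agnostic, wall-clock free.** The original WebSocket layer
  is replaced by an in-process loop in *simulated* wall time (discrete
  ticks of the refractory period, with an optional simulated computation
  cost per block), so the protocol is deterministic and unit-testable. A
  "stutter" is a tick in which playback wants to advance but finds
  `t_visualization = t_computed`.
* **Transparency by construction.** Both `run_session()` and the offline
  `integrate_session()` step the same internal engine, so for identical
  event logs the block sequences are identical objects — the protocol
  buffers, it cannot alter the math. The test suite still verifies this
  end-to-end with scripted mid-run stimulus and ablation events.
* **Lag metric aggregation.** The figure of merit multiplies an
  aggregated desynchronization by the stutter count. How to aggregate
  desync over a session is unspecified; the session records the full
  trace and both mean and max are reported, with the metric taking the
  aggregate as an argument.
* **Review.** `seek()` snaps to the nearest 10 ms sample (ties to the
  earlier one, computed index-arithmetically to be robust to float
  accumulation) and replays from cache; fast-forward/backward is a rate
  multiplier, not separate machinery.

## Visual mapping

Activity maps to node radii through the saturating odd map
$|R| = R_{max} V^2 / (\rho + V^2)$, $R_{max} = 15$. Two choices here are
the package's own:

* **ρ = 225 mV².** The slope factor has no established value; 225 puts
  half-saturation at 15 mV of activity, a scale at which the oscillations
  the analysis module measures modulate radii visibly without saturating.
* **Threshold-relative activity.** The mapped voltage defaults to
  $V - V_{th}$: with raw voltages every neuron rests near −35 mV, the
  sign channel would be constant and the red/blue alternation during
  oscillations impossible. `activity_reference = "absolute"` restores raw
  voltages for both `viz_frame()` and `node_radius()` consumers.

Static layout exports carry in+out synaptic degree as node radius and
`max(n(A→B), n(B→A))` as synaptic edge width; force-directed coordinates
are left to the renderer.

## Analysis

* **Period estimator (artifact-defined).** Reported periods are "~" values
  in the literature with no estimator attached, so the estimator is the
  package's own: locate the fundamental in the periodogram (preferring a
  subharmonic when a lower bin carries ≥ 20% of the peak power, so
  harmonic-rich waveforms do not halve), gate on the *raw*
  autocorrelation reaching 0.2 near the candidate lag (narrowband-filtered
  noise would otherwise masquerade as periodic), low-pass just above the
  fundamental, and read the period off the filtered autocorrelation peak
  with parabolic refinement. The acceptance suite shows recovery of
  0.5–6 s periods within 2% under additive noise up to 0.2 of the
  amplitude; the trace should span ≳ 4 cycles.
* **Phase.** The shift (within ± half a period) maximizing the
  cross-correlation, in (−π, π]; positive means the second trace lags.
* **Responsiveness (artifact-defined).** A neuron is responsive when its
  maximum threshold-relative excursion after the settle window reaches
  5 mV (configurable). Active fraction = responsive / non-ablated.
  Because the cut-off is a reporting choice, responsive sets and
  fractions should be read qualitatively (e.g. backward ≫ forward), not
  as calibrated numbers.
* **Scenario defaults.** 30 s duration with a 10 s settle window — at
  least five cycles of the slowest reported circuit period (~5.7 s)
  remain after the transient is discarded. Consensus period = median over
  responsive motor neurons (the literature quotes single circuit
  periods); phases are reported relative to the most responsive neuron.
* **Class expansion.** Stimulation protocols name cell classes ("PLM",
  "AVB", "ALM"); each expands to every roster neuron sharing the prefix
  (PLML/PLMR, ...), all receiving the stated amplitude. The nictation
  protocol's IL2 amplitude is not fixed anywhere; the built-in default is
  2.0 nA and is exposed as an argument.
* **Robustness scan.** Each draw multiplies every nonzero connection
  (gap entries mirrored to preserve symmetry) and each neuron's `C` and
  `Gc` by independent Uniform(0.8, 1.2) factors and reruns the scenario.
  On the ring fixture the oscillation persists in all draws.

## Synthetic networks and fixtures

`random_connectome()` reproduces the *structure* of the real data —
non-negative integer junction counts scaled by 100 pS, symmetric gap
layer, directed synapses, signed transmitter classes, sensory/inter/motor
labels — but deliberately not its degree distribution, left/right
symmetry or community structure. Tests passing on these networks
therefore validate the machinery (solvers, protocol, algebra), not any
biological claim about the real circuit; scenario-level statements about
named neurons require the real 279-neuron bundle, which is an optional
download.

The micro-fixtures are chosen so every numerical path has an independent
closed form: an isolated neuron ($V_{th} = E_{cell}$, shift $I/G_c$,
relaxation $e^{-t/0.15}$), a gap pair (mean shift $I/2G_c$, split
$I/(G_c + 2g)$: −625/21 and −635/21 mV under 1 arb), excitatory and
inhibitory synapse pairs (conductance-weighted averages −385/21 and
−865/21 mV), and a three-neuron inhibitory ring whose frustrated loop
oscillates under 0.02 nA drive. The ring's reference period, 0.963 s, was
frozen from 20 s runs at the default tolerances (initial-condition seeds
1/7/42 agree within 0.2%) and is re-measured by the suite within 2%; its
three phases come out at 0, ±2π/3.

## Problem sizes and runtime

The suite runs entirely on synthetic networks: property loops use 8–12
neuron networks over 0.25–3 s horizons (100 draws where a distributional
claim is made), the protocol tests a dozen 50 ms blocks, and the ring
scenarios 10–20 s. These sizes keep the whole suite under a minute while
leaving every estimator at least 4 cycles and every relaxation at least
10 time constants.

## Known limitations

* No delays, autapses, plasticity, or multi-compartment variants; no
  musculature or body mechanics downstream of the motor neurons.
* `V_th` refreshes are block-quantized; sub-block threshold dynamics
  during a transition are not modelled.
* The period estimator assumes a dominant stationary rhythm in the
  analysis window; drifting or intermittent oscillations will be reported
  as the window's average or rejected.
* The responsiveness cut-off and ρ are reporting conventions, not
  measured quantities.
* HDF5 export is not provided; saved dynamics go to npy (NumPy-compatible)
  and CSV.
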