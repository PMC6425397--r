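# dynome

Simulation backend for the *dynome* of *Caenorhabditis elegans*: a
biophysical dynamical system layered on top of the worm's static wiring
diagram (connectome). The package is aimed at computational neuroscientists
who want to stimulate, ablate and replay the somatic nervous system (279
neurons) — or any synthetic network with the same structure — from scripts
rather than a browser, and to quantify the oscillatory dynamics that
stimulation protocols induce.

## The model

*C. elegans* neurons are non-spiking: their membrane voltage is a graded
potential. Each neuron *i* is a single compartment obeying

    C dV_i/dt = -G_c (V_i - E_cell) - I_gap_i - I_syn_i + I_ext_i
    I_gap_i   = Σ_j G^g_ij (V_i - V_j)
    I_syn_i   = Σ_j G^s_ij s_j (V_i - E_j)
    ds_i/dt   = a_r Φ(V_i; β, V_th,i) (1 - s_i) - a_d s_i
    Φ(V)      = 1 / (1 + exp(-β (V - V_th)))

where `G^g` is the symmetric gap-junction (electrical) conductivity matrix,
`G^s[i, j]` the maximal conductivity of chemical synapses **to i from j**
(gated by the presynaptic activity `s_j`), `E_j` the presynaptic reversal
potential (0 mV excitatory, −48 mV GABAergic), and `Φ` a sigmoid centred on
the per-neuron threshold potential `V_th`. Defaults: C = 1.5 pF, G_c =
10 pS, E_cell = −35 mV, 100 pS per junction, a_r = 1/1.5 s⁻¹, a_d =
5/1.5 s⁻¹, β = 0.125 mV⁻¹. For a 279-neuron roster the ODE system has 558
dimensions.

`V_th` is the network's linear fixed point: impose `dV/dt = 0` with
synaptic activity frozen at its equilibrium `s_eq = a_r/(a_r + 2 a_d)` and
solve the resulting system `A x = b` (`compute_vth()`; the gap coupling
enters through the full weighted Laplacian by default).

On top of the integrator the package provides:

* **connectome bundles** (`load_connectome()`, `write_connectome()`):
  CSV/JSON or the npy matrices of the original release, with in-silico
  `ablate()` / `reinsert()` that zero and exactly restore rows/columns;
* **live stimulation** (`set_stimulus()`): injected currents in nA that
  change through smooth tanh transitions (midpoint 150 ms after the
  switch, complete by ~300 ms) instead of jumps;
* **the playback protocol** (`run_session()`): block-wise computation
  (Δt = 50 ms) gated by a buffer condition
  `t_computed − t_visualization ≤ t_buffer`, with `seek()`, replayable
  event logs and a `lag_metric()` for tuning — the protocol buffers but
  never alters the dynamics;
* **analysis** (`run_scenario()`, `estimate_period()`,
  `phase_difference()`, `responsive_neurons()`, `robustness_scan()`):
  oscillation periods, phase relations, responsive sets and ±20%
  perturbation scans;
* **visual mapping** (`node_radius()`, `layout_export()`): saturating
  signed radii `|R| = R_max V²/(ρ + V²)` and static graph exports for any
  force-directed renderer;
* **synthetic networks** (`random_connectome()`, `fixture()`): random
  connectomes with the real data's structure plus analytically solvable
  micro-fixtures, so everything above is testable with no download.

## Worked example

A three-neuron inhibitory ring under constant 0.02 nA drive — the package's
smallest oscillator:

```r
library(dynome)

r    <- fixture("ring_oscillator")
spec <- scenario_spec("ring",
                      stimuli_nA = list(R1 = 0.02, R2 = 0.02, R3 = 0.02),
                      duration = 20, settle_time = 5, seed = 7)
res <- run_scenario(spec, r$connectome, r$params)
print(res)
#> <scenario_result> 'ring': 3 responsive (100.0% of active)
#>   consensus period 0.96 s (reference neuron R1)
round(res$periods, 3)
#>    R1    R2    R3
#> 0.964 0.961 0.963
round(res$phases, 2)
#>    R1    R2    R3
#>  0.00 -2.09  2.09
```

All three neurons oscillate with a common ~0.96 s period, mutually out of
phase by 2π/3 — the signature of a frustrated inhibitory loop. Threshold
potentials have closed forms on the micro-fixtures; for a gap-junction pair
with 1 arb (0.1 pA) injected into the first neuron:

```r
g <- fixture("gap_pair")
round(compute_vth(g$connectome, g$params, c(1, 0)), 4)
#> [1] -29.7619 -30.2381
```

(the pair mean shifts by I/(2 G_c) = 5 mV above E_cell; the gap junction
splits the pair by I/(G_c + 2 g)).

Command-line wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/synth.R --n 30 --gap-density 0.1 --syn-density 0.15 \
    --seed 7 --out bundle/
Rscript inst/cli/simulate-scenario.R --name forward --connectome bundle/ \
    --duration 30 --seed 42 --out result/
```

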