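---
title: "Inside flatbrain: signatures, flat tables, generated kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside flatbrain: signatures, flat tables, generated kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flatbrain)
```

flatbrain is a desk-scale, general-purpose simulator for a documented subset
of NeuroML v2 / LEMS neural-network models. This vignette explains the
pipeline, the numerical choices, and what the synthetic fixtures and tests
do and do not establish.

## The pipeline

A simulation goes through four stages.

**1. Parsing.** `parse_model()` loads NeuroML/LEMS XML into an object model.
Every built-in component type the package supports (Izhikevich and
integrate-and-fire point cells, morphological cells with Hodgkin-Huxley
channel densities, exponential and double-exponential event synapses, gap
junctions, pulse and Poisson inputs) is expressed internally as the same
`dynamics_spec` structure that custom LEMS `ComponentType`s parse into, so
standard and custom components flow through one analysis path. All
quantities are converted to SI on entry against a closed unit table —
an unknown unit is an error, never silently treated as SI.

**2. Model analysis.** Each neuron type used by the target network is
turned into a *signature*: the paired code (ordered "eval" statements
defining every assigned variable, per-state "update" rules tagged with an
integrator, event handlers) and data (constants, states, requirements,
exposures, variable-sized table kinds) needed to simulate it.
Morphologies are discretized one compartment per segment; compartments
with identical mathematical structure — the same ordered mechanism kinds
and the same synapse/input kinds; constant *values* are data, not
structure — share a dedup group. A neuron with at most `K` compartments
(default 8) gets a fully flattened signature, one code unit per
compartment; a larger neuron gets one code unit per dedup group,
vectorized over the group members with offset-shifted data slices. The two
forms are semantically identical and produce bitwise-identical
trajectories; the loop form's statement count depends only on the number
of groups, not compartments.

**3. Instantiation.** `allocate_tables()` lays the whole network out in
flat, typed one-dimensional tables (f32/f64/i64 by const/state, state
tables double-buffered A/B), scalar slices per work item plus one table
per (item, synapse/input kind, column). Any value is addressable by a
packed (table serial, offset) reference, and references stored in the data
can be redirected without touching generated code — which is exactly how
the multi-worker mode points remote reads at mirror buffers. Packed
references live in R doubles: exactness requires the packed value to fit
in 53 bits, which holds for every serial the desk-scale allocator produces
and for the reserved sentinel `pack_ref(2^31-1, 0)`; `pack_ref()` refuses
combinations that would round.

**4. Execution.** `emit_kernel()` renders each type's signature as R
source for a kernel with the fixed contract `(tables, item, t, dt, step)`;
`load_kernel()` parses it into a callable, cached by a hash of the source
(regeneration is byte-identical). Each step: due spike events are applied
to the read-side flag tables, every work item runs once, probes are
sampled from the write buffers, fired spikes are routed with arrival step
`emission + max(1, round(delay/dt))`, and the buffers swap. Because
kernels read old state only from the read buffers and write only their own
slots, work items can execute in any order — the engine exposes a
permutation argument purely to let tests assert this.

## Numerical methods

* **Hodgkin-Huxley gates** advance with the exponential-Euler (cnexp) rule
  `x' = x_inf + (x - x_inf) * exp(-dt/tau)` with rates frozen at the
  start-of-step voltage; for alpha/beta gates the canonical forms are
  `tau = 1/(a+b)`, `inf = a*tau`. `choose_integrator()` applies cnexp
  exactly when a state is an HH gate whose derivative is linear in the
  state; all other states — synapse conductances, point-cell states,
  custom LEMS states — use forward Euler.
* **Membrane voltage of multi-compartment cells** is advanced by backward
  Euler over the cable system, with channel conductances frozen within the
  step: `(C/dt + G_chan + sum g_axial) v' - sum g_axial v'_nbr =
  (C/dt) v + sum g_chan E + i_syn + i_ext`. The tree system is solved in
  O(n) by one elimination and one substitution pass (`hines_solve()`). The
  implicit scheme is unconditionally stable and keeps single-compartment
  behaviour consistent with the analytic steady state `E + I/g`. Synaptic
  and gap-junction currents use the previous step's voltages (explicit),
  which keeps cells decoupled within a step.
* **Precision.** By default state is held in IEEE single precision —
  realized by rounding the f32 state buffers after initialization and
  after every step, since R has no native f32 arithmetic — while simulated
  time and everything multiplying it stays in doubles. `fp64 = TRUE`
  keeps everything in doubles; the oracle-equivalence tests run in that
  mode. On the HH protocol the two modes differ by well under 0.01 mV RMS
  with identical spike steps.
* **Events** are quantized to steps: a spike emitted during step k reaches
  its targets at step `k + max(1, round(delay/dt))` — double buffering
  imposes the one-step floor. Multiple events into one synapse entry
  accumulate as a pending count; handlers run once per pending event.
  Current accumulation into a compartment is ordered by (kind, entry),
  fixed at instantiation, so floating-point sums are reproducible.
* **Randomness** (Poisson inputs, LEMS `random()`) draws from a
  counter-based 32-bit mixer keyed by (seed, neuron index, input index)
  and the step counter. A draw is a pure function of its keys, so results
  do not depend on worker count or execution order, and R's global RNG is
  never consulted by the engine.

## The interpreted oracle

`reference_simulate()` advances the model by direct interpretation of the
parsed dynamics and compartment structures — no signatures, no flat
tables, no generated code. It deliberately shares the engine's *contracts*
(integrator tags, step-phase order, (kind, entry) accumulation order,
event arrival rule, RNG streams): with those pinned, double-precision
recordings from the two paths must agree bit for bit, so the equality test
exercises the signature/table/codegen machinery rather than arithmetic
choices. The acceptance suite asserts bitwise equality on all four network
fixtures.

## The multi-worker mode

`run_distributed()` emulates multi-node execution in-process: neurons are
split into contiguous, balanced ranges; each worker instantiates only its
own range. Cross-worker dependencies are collected as symbolic send lists
— (population, instance, segment, fractionAlong, payload kind), ordered
lexicographically so the list order defines wire indices — exchanged with
a request/ack protocol that sends nothing between non-communicating
workers, and realized as per-peer mirror buffers (graded dependencies,
e.g. gap-junction peer voltages; tracked sentinel references are rewritten
to mirror slots) and spike-recipient structures (event synapses). Each
step starts by packing one framed message per communicating pair — a u32
byte-length header, a fixed-size part with the requested values, a
variable-size part with the indices of entries that fired — delivering and
unpacking it before any kernel runs. The wire format is little-endian with
4-byte values; in `fp64` mode values widen to 8 bytes so that mirrors keep
working precision and the worker-count-invariance claim stays exact.
Since messages only relocate reads of previous-step values, the merged
recording is bitwise-identical to the single-worker run for every worker
count — the module's central invariant, asserted for W in {1, 2, 3, 5}.

## Validation statistics

The metrics module implements the cross-simulator comparison toolkit:
upward-crossing spike detection at a −20 mV threshold, the NeuroML-DB
waveform similarity `1 - mean(|x - xhat|)/(max(x) - min(x))`, the signed
per-cent difference in mean inter-spike interval, per-unit firing rate /
mean ISI / local variation (`LV = 3/(n-1) * sum(((I_i - I_{i+1})/(I_i +
I_{i+1}))^2)`, 0 for regular trains, near 1 for Poisson — the standard
local-variation statistic, adopted here as the external definition),
pairwise Pearson correlations of spike counts binned at a small (2 ms) and
a large (100 ms) bin, the eigenvalue spectrum of the waveform correlation
matrix, and Cohen's d with the 95% confidence half-width
`1.96*sqrt((N1+N2)/(N1*N2) + d^2/(2*(N1+N2-2)))`. Bin widths are
configurable; the defaults are documented choices, not externally pinned
values.

## Synthetic fixtures and the study conditions

The generators produce the network classes the simulator targets, as
self-contained NeuroML documents with their simulation protocol attached:

* `gen_hh_soma()` — one 80 µm compartment with classic squid Na/K/leak
  channels under the single-neuron protocol: 2 nA DC clamp from 10 to
  90 ms, 100 ms total, dt = 0.025 ms, somatic voltage recorded. The soma
  diameter was chosen so the clamp corresponds to ≈10 µA/cm², inside the
  squid model's repetitive-firing range.
* `gen_ball_and_stick_net()` — four compartments per cell (HH soma,
  passive dendrite), double-exponential soma-to-soma synapses under
  Bernoulli(p) connectivity, Poisson drive on the dendrite tip.
* `gen_izhikevich_net()` — 80% regular-spiking / 20% fast-spiking cells
  with fixed-probability connectivity (synapse count grows quadratically
  with n) and external Poisson drive strong enough to sustain activity.
* `gen_gap_ring()` — a ring of multi-compartment cells coupled *only* by
  gap junctions on the dendrite tips, with 100 Poisson inputs per cell
  spread over the apical compartments.
* `gen_big_cell()` — one chain cell with three structural profiles and
  jittered segment lengths, for the deduplication-scaling checks.
* `gen_custom_lif_net()` — a custom LEMS leaky integrator with reset,
  exercising the LEMS-dynamics path end to end.

Generation is pure: identical arguments yield bitwise-identical XML, with
connectivity drawn from the package's counter RNG. The default durations
(100 ms at dt = 0.025 ms) and sizes (n = 10 ball-and-stick, n = 50
Izhikevich, 4-cell gap ring in the acceptance suite) keep a full
engine/oracle/multi-worker sweep within minutes on one CPU; they are the
package's chosen desk-scale study conditions.

What passing these tests shows: that analysis, code generation, flat-table
instantiation and the communication protocol are exact — the engine
reproduces the interpreted semantics bit for bit, independently of worker
count and execution order. What it does not show: fidelity of the fixture
models to any particular published tissue model (the fixtures are
synthetic stand-ins, not byte-faithful reproductions of deposited
networks), and accuracy against other simulators, which would require
cross-simulator runs outside this package's scope.

## Degenerate inputs and edge rules

* A trace sitting exactly at the spike threshold and then rising counts
  one spike, on the first at-threshold sample (`x[i-1] < θ <= x[i]`).
* `nmldb_similarity()` refuses constant reference waveforms
  (`DegenerateRange`); mean ISI needs two spikes, LV three (NA
  otherwise).
* A neuron with no attached synapses still owns its kind tables, at
  length zero — table *count* per item is fixed, lengths vary.
* `fractionAlong` defaults to 0.5; missing proximal points inherit the
  parent's distal point; a zero-length root segment with equal diameters
  is treated as a sphere.
* Exponential-linear HH rates use a guarded `x/(1-exp(-x))` with the
  limit value 1 at the removable singularity.
* Reading an unresolved sentinel reference traps (`DanglingSentinel`)
  rather than returning garbage; non-finite state aborts the run with the
  step index (`NumericalBlowup`).

## Known limitations

LEMS `KineticScheme`, `Regime` and structural build elements are outside
the subset, as are NeuroML v1, SBML and SONATA. One compartment per
morphological segment (no further subdivision); no variable time steps; no
online model modification; the model structure is fixed once instantiated.
Only membrane voltage is probeable on detailed cells. The specialized
hand-written-kernel extension point exists as the kernel calling contract
(`emit_kernel()`/`load_kernel()` accept any source honouring it) but no
specialized kernels ship. The multi-worker transport is in-process; it
exercises the partitioning, send-list, mirror and framing logic, not
network hardware.
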