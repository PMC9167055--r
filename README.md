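# flatbrain

A desk-scale, general-purpose simulator for a documented subset of
NeuroML v2 / LEMS neural-network models, written in R. It is built around
a code-generation architecture rather than run-time traversal of the
model's object hierarchy:

1. **Model analysis** turns every neuron type into a paired *code/data
   signature* — the ordered evaluation statements, per-state update rules
   and event handlers next to the flat layout of its constants, states,
   requirements and exposures. Compartments with identical mathematical
   structure are deduplicated so one code unit simulates all of them.
2. **Code generation** emits each signature as kernel source, loaded at
   run time under a fixed calling contract; regeneration is
   byte-identical and kernels are cached by source hash.
3. **Flat-table instantiation** realizes the whole network in typed
   one-dimensional arrays (double-buffered state), with every value
   addressable by a packed (table serial, offset) reference that can be
   redirected without touching generated code.
4. **A time-driven engine** runs one kernel per neuron per step: spike
   events arrive at step `emission + max(1, round(delay/dt))`,
   Hodgkin-Huxley gates use exponential Euler (cnexp), other states use
   forward Euler, and multi-compartment voltages solve a backward-Euler
   cable system with a linear-time tree (Hines) solver.
5. **An emulated multi-worker mode** partitions neurons contiguously,
   exchanges symbolic send lists, installs mirror buffers, and frames one
   message per communicating pair per step — producing recordings
   bitwise-identical to the single-worker run for every worker count.

An interpreted reference simulator (`reference_simulate()`) executes the
same semantics with no signatures, tables or code generation; in
double-precision mode the engine must match it bit for bit, which is the
package's central correctness test. A metrics module implements the
cross-simulator comparison statistics: the NeuroML-DB waveform similarity
`1 − mean(|x − x̂|)/(max(x) − min(x))`, per-cent inter-spike-interval
difference at a −20 mV threshold, firing rate / mean ISI / local
variation, binned spike-count correlations, waveform correlation spectra,
and Cohen's *d* with `±1.96·sqrt((N1+N2)/(N1·N2) + d²/(2(N1+N2−2)))`
confidence intervals.

Who it is for: computational neuroscientists who want to study this
simulator architecture — signatures, deduplication, table-offset
referencing, send-list communication — on models they can hold in one
hand, and tool builders who need a reference implementation of the
NeuroML/LEMS subset with an executable specification of its numerics.

## A worked example

Simulate a classic Hodgkin-Huxley soma under a 2 nA current clamp
(10–90 ms of a 100 ms run, dt = 0.025 ms), and compare the generated-kernel
engine against the interpreted oracle:

```r
library(flatbrain)

m   <- gen_hh_soma()                   # model + protocol, self-contained
rec <- run_simulation(m, fp64 = TRUE)  # generated kernels
orc <- reference_simulate(m, fp64 = TRUE)  # direct interpretation

rec
#> <recording: 4000 steps of 0.025 ms, 1 probe(s), 6 spike(s) from 1 unit(s)>

identical(rec$waveforms, orc$waveforms)
#> [1] TRUE

nmldb_similarity(orc$waveforms[, 1], rec$waveforms[, 1])
#> [1] 1

rec$spikes$time
#> [1] 0.011925 0.027100 0.042025 0.056925 0.071825 0.086750
```

The soma fires 6 spikes (75 Hz) during the clamp; the engine and the
oracle agree exactly, so the similarity metric sits at its identity value
1. Multi-worker runs are equally exact:

```r
d3 <- run_distributed(m, workers = 3, fp64 = TRUE)
identical(rec$waveforms, d3$waveforms)
#> [1] TRUE
```

Spike-train statistics come back as tibbles:

```r
train_statistics(rec$spikes$time, duration = 0.1)
#> # A tibble: 1 × 4
#>   n_spikes  rate mean_isi        lv
#>      <int> <dbl>    <dbl>     <dbl>
#> 1        6    60   0.0150 0.0000528
```

A thin command-line wrapper lives at `inst/cli/flatbrain.R`
(`run`, `compare`, `netstats`, `fixtures` subcommands).

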