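Package: flatbrain
Title: Desk-Scale NeuroML/LEMS Network Simulator with Generated Kernels and Flat State Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A general-purpose, time-driven simulator for a documented subset of
    NeuroML v2 and LEMS neural network models. Model documents are analysed into
    paired code/data signatures per neuron type, from which executable kernels
    are generated and loaded at run time. All instantiated model data live in
    flat, typed one-dimensional tables addressed by packed table-offset
    references, with double-buffered state so that per-neuron work items can run
    in any order within a time step. Multi-compartment cells are integrated with
    a linear-time tree (Hines) solver; Hodgkin-Huxley gates use the exponential
    Euler (cnexp) rule and other states use forward Euler. A multi-worker mode
    emulates distributed execution with symbolic send lists, mirror buffers and
    per-step framed messages, and is bitwise-identical to single-worker runs.
    Also included: synthetic model generators, an interpreted reference
    simulator used as an equivalence oracle, and spike-train/waveform comparison
    statistics (NeuroML-DB similarity, inter-spike-interval difference, local
    variation, binned correlations, Cohen's d with confidence interval).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
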