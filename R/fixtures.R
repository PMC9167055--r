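# Synthetic NeuroML fixtures.
#
# The generators emulate the benchmark-style networks the simulator targets:
# a classic Hodgkin-Huxley soma under the single-neuron stimulation protocol
# (2 nA DC clamp from 10 to 90 ms, 100 ms total, dt 0.025 ms), a
# ball-and-stick network with 4 compartments per cell and event synapses, an
# Izhikevich point-cell network with double-exponential synapses and
# quadratically growing synapse counts, a ring of multi-compartment cells
# coupled solely by gap junctions with 100 Poisson inputs per cell, a large
# many-compartment cell with few structural profiles (for deduplication
# scaling), and a small network of a custom LEMS point neuron (to exercise
# the LEMS dynamics path end to end).
#
# Generation is pure: the same arguments produce bitwise-identical XML.
# Connectivity and input placement draw from the package's counter-based
# RNG, never from R's global RNG.

#' @keywords internal
#' Uniform [0,1) draw for fixture construction, keyed by (seed, i, j).
fb_fix_u <- function(seed, i, j) {
  fb_rng_uniform(fb_rng_stream(seed, i, j), 0)
}

#' @keywords internal
#' Standard squid HH channel definitions (rates in per_s, voltages in V).
fb_hh_channels_xml <- function() {
  paste0(
    '<ionChannelHH id="naChan">',
    '<gateHHrates id="m" instances="3">',
    '<forwardRate type="HHExpLinearRate" rate="1000per_s" midpoint="-0.040V" scale="0.010V"/>',
    '<reverseRate type="HHExpRate" rate="4000per_s" midpoint="-0.065V" scale="-0.018V"/>',
    '</gateHHrates>',
    '<gateHHrates id="h" instances="1">',
    '<forwardRate type="HHExpRate" rate="70per_s" midpoint="-0.065V" scale="-0.020V"/>',
    '<reverseRate type="HHSigmoidRate" rate="1000per_s" midpoint="-0.035V" scale="0.010V"/>',
    '</gateHHrates>',
    '</ionChannelHH>',
    '<ionChannelHH id="kChan">',
    '<gateHHrates id="n" instances="4">',
    '<forwardRate type="HHExpLinearRate" rate="100per_s" midpoint="-0.055V" scale="0.010V"/>',
    '<reverseRate type="HHExpRate" rate="125per_s" midpoint="-0.065V" scale="-0.080V"/>',
    '</gateHHrates>',
    '</ionChannelHH>',
    '<ionChannelHH id="leakChan"/>')
}

#' @keywords internal
#' Assemble a LEMS document string with a model and a <Simulation>.
fb_fixture_doc <- function(model_xml, net_id, duration_ms, dt_ms, seed,
                           output_cols = character(0),
                           event_sels = character(0)) {
  oc <- paste(vapply(seq_along(output_cols), function(i) {
    sprintf('<OutputColumn id="c%d" quantity="%s"/>', i, output_cols[i])
  }, character(1)), collapse = "")
  es <- paste(vapply(seq_along(event_sels), function(i) {
    sprintf('<EventSelection id="%d" select="%s" eventPort="spike"/>',
            i - 1L, event_sels[i])
  }, character(1)), collapse = "")
  paste0(
    "<Lems>", model_xml,
    sprintf('<Simulation id="sim" length="%gms" step="%gms" target="%s" seed="%d">',
            duration_ms, dt_ms, net_id, seed),
    if (length(output_cols) > 0L)
      sprintf('<OutputFile id="of0" fileName="out.dat">%s</OutputFile>', oc)
    else "",
    if (length(event_sels) > 0L)
      sprintf('<EventOutputFile id="ef0" fileName="out.spikes" format="TIME_ID">%s</EventOutputFile>', es)
    else "",
    "</Simulation></Lems>")
}

#' @keywords internal
#' Parse a fixture document and return the model with the simulation spec
#' and the raw XML attached as attributes.
fb_fixture_finish <- function(xml) {
  ls <- load_simulation(xml)
  m <- ls$model
  attr(m, "simulation") <- ls$spec
  attr(m, "xml") <- xml
  m
}

#' Single Hodgkin-Huxley soma under the DC-clamp protocol
#'
#' One compartment (80 um cylinder) carrying classic squid Na/K/leak
#' channels, stimulated with a DC current clamp (default 2 nA from 10 to
#' 90 ms), simulated for 100 ms at dt = 0.025 ms, with the somatic membrane
#' voltage recorded and spikes detected on the soma.
#'
#' @param amplitude_nA clamp amplitude in nA.
#' @return a `model_document` with the bound `simulation_spec` in
#'   `attr(, "simulation")`.
#' @export
gen_hh_soma <- function(amplitude_nA = 2) {
  model <- paste0(
    fb_hh_channels_xml(),
    '<cell id="hhcell">',
    '<morphology>',
    '<segment id="0" name="soma">',
    '<proximal x="0" y="0" z="0" diameter="80"/>',
    '<distal x="80" y="0" z="0" diameter="80"/>',
    '</segment>',
    '<segmentGroup id="soma_group"><member segment="0"/></segmentGroup>',
    '</morphology>',
    '<biophysicalProperties id="bio"><membraneProperties>',
    '<channelDensity id="na" ionChannel="naChan" condDensity="1200 S_per_m2" erev="0.050 V"/>',
    '<channelDensity id="k" ionChannel="kChan" condDensity="360 S_per_m2" erev="-0.077 V"/>',
    '<channelDensity id="leak" ionChannel="leakChan" condDensity="3 S_per_m2" erev="-0.054387 V"/>',
    '<spikeThresh value="-0.020 V"/>',
    '<specificCapacitance value="0.01 F_per_m2"/>',
    '<initMembPotential value="-0.065 V"/>',
    '</membraneProperties>',
    '<intracellularProperties><resistivity value="1 ohm_m"/></intracellularProperties>',
    '</biophysicalProperties></cell>',
    sprintf('<pulseGenerator id="clamp" delay="10ms" duration="80ms" amplitude="%.9gnA"/>',
            amplitude_nA),
    '<network id="net">',
    '<population id="hhpop" component="hhcell" size="1"/>',
    '<inputList id="il0" component="clamp" population="hhpop">',
    '<input id="0" target="hhpop[0]" segmentId="0" fractionAlong="0.5"/>',
    '</inputList>',
    '</network>')
  fb_fixture_finish(fb_fixture_doc(model, "net", 100, 0.025, 1,
                                   output_cols = "hhpop[0]/0/v",
                                   event_sels = "hhpop[0]"))
}

#' Ball-and-stick network
#'
#' `n` four-compartment cells (Hodgkin-Huxley soma plus a passive
#' three-segment dendrite), recurrently connected soma-to-soma with
#' double-exponential event synapses under Bernoulli(p) connectivity
#' (ordered pairs, no self-connections), each cell driven by a Poisson
#' firing synapse on its dendrite tip. Deterministic under `seed`.
#'
#' @param n number of cells.
#' @param p_connect connection probability per ordered pair.
#' @param seed integer seed (connectivity and input streams).
#' @param duration_ms,record_all simulation length; record all somata or
#'   only cell 0.
#' @return a `model_document` with the simulation spec attached.
#' @export
gen_ball_and_stick_net <- function(n = 10, p_connect = 0.2, seed = 1,
                                   duration_ms = 100, record_all = TRUE) {
  dend <- paste(vapply(1:3, function(i) {
    paste0(sprintf('<segment id="%d" name="dend%d"><parent segment="%d"/>', i, i, i - 1L),
           if (i == 1L)
             sprintf('<proximal x="%d" y="0" z="0" diameter="2"/>', 20L)
           else "",
           sprintf('<distal x="%d" y="0" z="0" diameter="2"/>', 20L + 50L * i),
           '</segment>')
  }, character(1)), collapse = "")
  conns <- character(0)
  ci <- 0L
  for (i in seq_len(n) - 1L) {
    for (j in seq_len(n) - 1L) {
      if (i == j) next
      if (fb_fix_u(seed, i, j) < p_connect) {
        conns <- c(conns, sprintf(
          paste0('<connectionWD id="%d" preCellId="pop[%d]" postCellId="pop[%d]" ',
                 'preSegmentId="0" postSegmentId="0" weight="1" delay="2ms"/>'),
          ci, i, j))
        ci <- ci + 1L
      }
    }
  }
  model <- paste0(
    fb_hh_channels_xml(),
    '<cell id="bscell">',
    '<morphology>',
    '<segment id="0" name="soma">',
    '<proximal x="0" y="0" z="0" diameter="20"/>',
    '<distal x="20" y="0" z="0" diameter="20"/>',
    '</segment>', dend,
    '<segmentGroup id="soma_group"><member segment="0"/></segmentGroup>',
    '<segmentGroup id="dendrites"><member segment="1"/><member segment="2"/><member segment="3"/></segmentGroup>',
    '</morphology>',
    '<biophysicalProperties id="bio"><membraneProperties>',
    '<channelDensity id="na" ionChannel="naChan" condDensity="1200 S_per_m2" erev="0.050 V" segmentGroup="soma_group"/>',
    '<channelDensity id="k" ionChannel="kChan" condDensity="360 S_per_m2" erev="-0.077 V" segmentGroup="soma_group"/>',
    '<channelDensity id="leak" ionChannel="leakChan" condDensity="3 S_per_m2" erev="-0.054387 V"/>',
    '<spikeThresh value="-0.020 V"/>',
    '<specificCapacitance value="0.01 F_per_m2"/>',
    '<initMembPotential value="-0.065 V"/>',
    '</membraneProperties>',
    '<intracellularProperties><resistivity value="1 ohm_m"/></intracellularProperties>',
    '</biophysicalProperties></cell>',
    '<expTwoSynapse id="ampa" gbase="5nS" erev="0mV" tauRise="1ms" tauDecay="5ms"/>',
    '<poissonFiringSynapse id="drive" averageRate="100Hz" gbase="20nS" erev="0mV" tauDecay="5ms"/>',
    '<network id="net">',
    sprintf('<population id="pop" component="bscell" size="%d"/>', n),
    if (length(conns) > 0L) paste0(
      '<projection id="prj" presynapticPopulation="pop" postsynapticPopulation="pop" synapse="ampa">',
      paste(conns, collapse = ""),
      '</projection>') else "",
    '<inputList id="il0" component="drive" population="pop">',
    paste(vapply(seq_len(n) - 1L, function(i) {
      sprintf('<input id="%d" target="pop[%d]" segmentId="3" fractionAlong="0.5"/>', i, i)
    }, character(1)), collapse = ""),
    '</inputList>',
    '</network>')
  probes <- if (record_all) sprintf("pop[%d]/0/v", seq_len(n) - 1L)
            else "pop[0]/0/v"
  fb_fixture_finish(fb_fixture_doc(model, "net", duration_ms, 0.025, seed,
                                   output_cols = probes,
                                   event_sels = sprintf("pop[%d]", seq_len(n) - 1L)))
}

#' Izhikevich point-cell network
#'
#' Regular-spiking excitatory (80%) and fast-spiking inhibitory (20%)
#' Izhikevich cells, recurrently connected with double-exponential
#' conductance synapses at a fixed pairwise probability (so the synapse
#' count grows quadratically with n), each cell driven by an external
#' Poisson firing synapse.
#'
#' @param n total cell count.
#' @param p_connect connection probability per ordered pair.
#' @param seed integer seed.
#' @param duration_ms simulation length.
#' @return a `model_document` with the simulation spec attached.
#' @export
gen_izhikevich_net <- function(n = 100, p_connect = 0.05, seed = 2,
                               duration_ms = 100) {
  ne <- max(1L, as.integer(round(0.8 * n)))
  ni <- n - ne
  pops <- c(rep("exc", ne), rep("inh", ni))
  idx_in_pop <- c(seq_len(ne) - 1L, seq_len(max(ni, 0L)) - 1L)
  # one projection per (pre population, post population) pair
  conns <- list("exc.exc" = character(0), "exc.inh" = character(0),
                "inh.exc" = character(0), "inh.inh" = character(0))
  cnt <- c("exc.exc" = 0L, "exc.inh" = 0L, "inh.exc" = 0L, "inh.inh" = 0L)
  for (i in seq_len(n) - 1L) {
    for (j in seq_len(n) - 1L) {
      if (i == j) next
      if (fb_fix_u(seed, i, j) < p_connect) {
        pre_pop <- pops[i + 1L]; post_pop <- pops[j + 1L]
        key <- paste0(pre_pop, ".", post_pop)
        conns[[key]] <- c(conns[[key]], sprintf(
          paste0('<connectionWD id="%d" preCellId="%s[%d]" postCellId="%s[%d]" ',
                 'weight="1" delay="1ms"/>'),
          cnt[[key]], pre_pop, idx_in_pop[i + 1L], post_pop, idx_in_pop[j + 1L]))
        cnt[[key]] <- cnt[[key]] + 1L
      }
    }
  }
  mk_inputs <- function(pop, size, id0) {
    paste(vapply(seq_len(size) - 1L, function(i) {
      sprintf('<input id="%d" target="%s[%d]" segmentId="0" fractionAlong="0.5"/>',
              i, pop, i)
    }, character(1)), collapse = "")
  }
  model <- paste0(
    '<izhikevichCell id="rs" v0="-65mV" thresh="30mV" a="0.02" b="0.2" c="-65mV" d="8"/>',
    '<izhikevichCell id="fs" v0="-65mV" thresh="30mV" a="0.1" b="0.2" c="-65mV" d="2"/>',
    '<expTwoSynapse id="synE" gbase="2nS" erev="0mV" tauRise="0.5ms" tauDecay="3ms"/>',
    '<expTwoSynapse id="synI" gbase="4nS" erev="-80mV" tauRise="0.5ms" tauDecay="6ms"/>',
    '<poissonFiringSynapse id="drive" averageRate="200Hz" gbase="80nS" erev="0mV" tauDecay="4ms"/>',
    '<network id="net">',
    sprintf('<population id="exc" component="rs" size="%d"/>', ne),
    if (ni > 0L) sprintf('<population id="inh" component="fs" size="%d"/>', ni) else "",
    paste(vapply(names(conns), function(key) {
      if (length(conns[[key]]) == 0L) return("")
      pp <- strsplit(key, ".", fixed = TRUE)[[1]]
      syn <- if (pp[1] == "exc") "synE" else "synI"
      paste0(sprintf(paste0('<projection id="prj_%s_%s" presynapticPopulation="%s" ',
                            'postsynapticPopulation="%s" synapse="%s">'),
                     pp[1], pp[2], pp[1], pp[2], syn),
             paste(conns[[key]], collapse = ""), '</projection>')
    }, character(1)), collapse = ""),
    '<inputList id="ile" component="drive" population="exc">',
    mk_inputs("exc", ne, 0L), '</inputList>',
    if (ni > 0L) paste0(
      '<inputList id="ili" component="drive" population="inh">',
      mk_inputs("inh", ni, ne), '</inputList>') else "",
    '</network>')
  sels <- c(sprintf("exc[%d]", seq_len(ne) - 1L),
            if (ni > 0L) sprintf("inh[%d]", seq_len(ni) - 1L))
  probes <- c("exc[0]/v", if (ni > 0L) "inh[0]/v")
  fb_fixture_finish(fb_fixture_doc(model, "net", duration_ms, 0.025, seed,
                                   output_cols = probes, event_sels = sels))
}

#' Gap-junction-coupled ring of multi-compartment cells
#'
#' A ring of `n` detailed cells (HH soma plus a passive apical dendrite
#' chain) communicating solely through gap junctions placed on the dendrite
#' tips, with `n_inputs` Poisson firing synapses per cell distributed over
#' the apical compartments.
#'
#' @param n cells in the ring (>= 2).
#' @param n_compartments compartments per cell (soma + dendrites).
#' @param n_inputs Poisson inputs per cell (100 matches the benchmark-style
#'   protocol).
#' @param seed integer seed.
#' @param duration_ms simulation length.
#' @param rate_hz per-input Poisson rate.
#' @return a `model_document` with the simulation spec attached.
#' @export
gen_gap_ring <- function(n = 4, n_compartments = 5, n_inputs = 100, seed = 3,
                         duration_ms = 100, rate_hz = 20) {
  stopifnot(n >= 2, n_compartments >= 2)
  nd <- n_compartments - 1L
  tip <- nd  # segment id of the dendrite tip
  dend <- paste(vapply(seq_len(nd), function(i) {
    paste0(sprintf('<segment id="%d" name="dend%d"><parent segment="%d"/>', i, i, i - 1L),
           if (i == 1L) '<proximal x="20" y="0" z="0" diameter="2"/>' else "",
           sprintf('<distal x="%d" y="0" z="0" diameter="2"/>', 20L + 40L * i),
           '</segment>')
  }, character(1)), collapse = "")
  dend_members <- paste(vapply(seq_len(nd), function(i) {
    sprintf('<member segment="%d"/>', i)
  }, character(1)), collapse = "")
  gaps <- paste(vapply(seq_len(n) - 1L, function(i) {
    sprintf(
      paste0('<electricalConnection id="%d" preCell="ring[%d]" postCell="ring[%d]" ',
             'preSegment="%d" postSegment="%d" synapse="gj"/>'),
      i, i, (i + 1L) %% n, tip, tip)
  }, character(1)), collapse = "")
  inputs <- character(0)
  k <- 0L
  for (i in seq_len(n) - 1L) {
    for (j in seq_len(n_inputs) - 1L) {
      segj <- 1L + as.integer(floor(fb_fix_u(seed, i, j + 1L) * nd))
      if (segj > nd) segj <- nd
      inputs <- c(inputs, sprintf(
        '<input id="%d" target="ring[%d]" segmentId="%d" fractionAlong="0.5"/>',
        k, i, segj))
      k <- k + 1L
    }
  }
  model <- paste0(
    fb_hh_channels_xml(),
    '<cell id="gcell">',
    '<morphology>',
    '<segment id="0" name="soma">',
    '<proximal x="0" y="0" z="0" diameter="20"/>',
    '<distal x="20" y="0" z="0" diameter="20"/>',
    '</segment>', dend,
    '<segmentGroup id="soma_group"><member segment="0"/></segmentGroup>',
    sprintf('<segmentGroup id="apical">%s</segmentGroup>', dend_members),
    '</morphology>',
    '<biophysicalProperties id="bio"><membraneProperties>',
    '<channelDensity id="na" ionChannel="naChan" condDensity="1200 S_per_m2" erev="0.050 V" segmentGroup="soma_group"/>',
    '<channelDensity id="k" ionChannel="kChan" condDensity="360 S_per_m2" erev="-0.077 V" segmentGroup="soma_group"/>',
    '<channelDensity id="leak" ionChannel="leakChan" condDensity="3 S_per_m2" erev="-0.054387 V"/>',
    '<spikeThresh value="-0.020 V"/>',
    '<specificCapacitance value="0.01 F_per_m2"/>',
    '<initMembPotential value="-0.065 V"/>',
    '</membraneProperties>',
    '<intracellularProperties><resistivity value="1 ohm_m"/></intracellularProperties>',
    '</biophysicalProperties></cell>',
    '<gapJunction id="gj" conductance="2nS"/>',
    sprintf('<poissonFiringSynapse id="pin" averageRate="%.9gHz" gbase="0.5nS" erev="0mV" tauDecay="5ms"/>', rate_hz),
    '<network id="net">',
    sprintf('<population id="ring" component="gcell" size="%d"/>', n),
    '<electricalProjection id="ep" presynapticPopulation="ring" postsynapticPopulation="ring">',
    gaps,
    '</electricalProjection>',
    '<inputList id="il0" component="pin" population="ring">',
    paste(inputs, collapse = ""),
    '</inputList>',
    '</network>')
  probes <- sprintf("ring[%d]/0/v", seq_len(n) - 1L)
  sels <- sprintf("ring[%d]", seq_len(n) - 1L)
  fb_fixture_finish(fb_fixture_doc(model, "net", duration_ms, 0.025, seed,
                                   output_cols = probes, event_sels = sels))
}

#' Large cell with few structural profiles
#'
#' One neuron with `n_comp` compartments on a chain, drawing their channel
#' mechanisms from three structural profiles (active soma-like, passive,
#' K-only), used to exercise signature deduplication: the generated loop-form
#' kernel has one code unit per profile regardless of `n_comp`.
#'
#' @param n_comp total compartments.
#' @param seed integer seed (unused; kept for the fixture signature).
#' @param duration_ms simulation length.
#' @return a `model_document` with the simulation spec attached.
#' @export
gen_big_cell <- function(n_comp = 319, seed = 1, duration_ms = 1) {
  stopifnot(n_comp >= 3)
  # jittered segment lengths so per-compartment constants differ within a
  # structural profile (constants are data, not structure)
  xpos <- 20L + 10L * seq_len(n_comp - 1L) +
    (seq_len(n_comp - 1L)^2 %% 5L)
  segs <- paste(vapply(seq_len(n_comp - 1L), function(i) {
    paste0(sprintf('<segment id="%d"><parent segment="%d"/>', i, i - 1L),
           if (i == 1L) '<proximal x="20" y="0" z="0" diameter="2"/>' else "",
           sprintf('<distal x="%d" y="0" z="0" diameter="2"/>', xpos[i]),
           '</segment>')
  }, character(1)), collapse = "")
  ids <- seq_len(n_comp) - 1L
  grp2 <- ids[ids > 0L & ids %% 2L == 1L]
  grp3 <- ids[ids > 0L & ids %% 2L == 0L]
  mk_members <- function(v) paste(sprintf('<member segment="%d"/>', v), collapse = "")
  model <- paste0(
    fb_hh_channels_xml(),
    '<cell id="bigcell">',
    '<morphology>',
    '<segment id="0" name="soma">',
    '<proximal x="0" y="0" z="0" diameter="20"/>',
    '<distal x="20" y="0" z="0" diameter="20"/>',
    '</segment>', segs,
    '<segmentGroup id="soma_group"><member segment="0"/></segmentGroup>',
    sprintf('<segmentGroup id="odd">%s</segmentGroup>', mk_members(grp2)),
    sprintf('<segmentGroup id="even">%s</segmentGroup>', mk_members(grp3)),
    '</morphology>',
    '<biophysicalProperties id="bio"><membraneProperties>',
    '<channelDensity id="na" ionChannel="naChan" condDensity="1200 S_per_m2" erev="0.050 V" segmentGroup="soma_group"/>',
    '<channelDensity id="k" ionChannel="kChan" condDensity="360 S_per_m2" erev="-0.077 V" segmentGroup="soma_group"/>',
    '<channelDensity id="kd" ionChannel="kChan" condDensity="36 S_per_m2" erev="-0.077 V" segmentGroup="even"/>',
    '<channelDensity id="leak" ionChannel="leakChan" condDensity="3 S_per_m2" erev="-0.054387 V"/>',
    '<spikeThresh value="-0.020 V"/>',
    '<specificCapacitance value="0.01 F_per_m2"/>',
    '<initMembPotential value="-0.065 V"/>',
    '</membraneProperties>',
    '<intracellularProperties><resistivity value="1 ohm_m"/></intracellularProperties>',
    '</biophysicalProperties></cell>',
    '<network id="net">',
    '<population id="big" component="bigcell" size="1"/>',
    '</network>')
  fb_fixture_finish(fb_fixture_doc(model, "net", duration_ms, 0.025, seed,
                                   output_cols = "big[0]/0/v"))
}

#' Small network of a custom LEMS point neuron
#'
#' Defines a leaky-integrator ComponentType in LEMS (state v, constant
#' drive, spike threshold with reset), instantiates it with per-cell drive
#' values and couples the cells in a ring with exponential-conductance
#' synapses — exercising the custom-dynamics parsing, code generation and
#' event paths end to end.
#'
#' @param n cells.
#' @param seed integer seed.
#' @param duration_ms simulation length.
#' @return a `model_document` with the simulation spec attached.
#' @export
gen_custom_lif_net <- function(n = 3, seed = 4, duration_ms = 100) {
  ctype <- paste0(
    '<ComponentType name="driftLif">',
    '<Parameter name="rest" dimension="voltage"/>',
    '<Parameter name="tau" dimension="time"/>',
    '<Parameter name="thresh" dimension="voltage"/>',
    '<Parameter name="reset" dimension="voltage"/>',
    '<Parameter name="drive" dimension="voltage"/>',
    '<Requirement name="iSyn" dimension="current"/>',
    '<Exposure name="v" dimension="voltage"/>',
    '<EventPort name="spike" direction="out"/>',
    '<Dynamics>',
    '<StateVariable name="v" dimension="voltage"/>',
    '<TimeDerivative variable="v" value="(rest + drive - v)/tau + iSyn * 1e8"/>',
    '<OnStart><StateAssignment variable="v" value="rest"/></OnStart>',
    '<OnCondition test="v .gt. thresh">',
    '<StateAssignment variable="v" value="reset"/>',
    '<EventOut port="spike"/>',
    '</OnCondition>',
    '</Dynamics>',
    '</ComponentType>')
  cells <- paste(vapply(seq_len(n) - 1L, function(i) {
    drive <- 0.020 + 0.004 * i
    sprintf(paste0('<driftLif id="lif%d" rest="-0.065" tau="0.01" ',
                   'thresh="-0.050" reset="-0.066" drive="%.9g"/>'), i, drive)
  }, character(1)), collapse = "")
  pops <- paste(vapply(seq_len(n) - 1L, function(i) {
    sprintf('<population id="p%d" component="lif%d" size="1"/>', i, i)
  }, character(1)), collapse = "")
  prjs <- paste(vapply(seq_len(n) - 1L, function(i) {
    j <- (i + 1L) %% n
    sprintf(paste0('<projection id="r%d" presynapticPopulation="p%d" ',
                   'postsynapticPopulation="p%d" synapse="exc">',
                   '<connectionWD id="0" preCellId="p%d[0]" postCellId="p%d[0]" ',
                   'weight="1" delay="1ms"/></projection>'),
            i, i, j, i, j)
  }, character(1)), collapse = "")
  model <- paste0(
    ctype,
    '<expOneSynapse id="exc" gbase="1nS" erev="0mV" tauDecay="5ms"/>',
    cells,
    '<network id="net">', pops, prjs, '</network>')
  probes <- sprintf("p%d[0]/v", seq_len(n) - 1L)
  sels <- sprintf("p%d[0]", seq_len(n) - 1L)
  fb_fixture_finish(fb_fixture_doc(model, "net", duration_ms, 0.025, seed,
                                   output_cols = probes, event_sels = sels))
}
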