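# Shared tiny model documents, built in code.

tiny_izh_xml <- function() {
  paste0(
    "<neuroml>",
    '<izhikevichCell id="izh" v0="-70mV" thresh="30mV" a="0.02" b="0.2" c="-50mV" d="2"/>',
    '<network id="net"><population id="pop" component="izh" size="1"/></network>',
    "</neuroml>")
}

# Two izhikevich cells, cell 0 driven by a strong pulse so it fires, cell 1
# receiving an event synapse from cell 0 with the given delay.
two_cell_event_xml <- function(delay = "0ms") {
  paste0(
    "<Lems>",
    '<izhikevichCell id="izh" v0="-70mV" thresh="30mV" a="0.02" b="0.2" c="-50mV" d="2"/>',
    '<expOneSynapse id="syn" gbase="1nS" erev="0mV" tauDecay="5ms"/>',
    '<pulseGenerator id="pg" delay="1ms" duration="50ms" amplitude="10nA"/>',
    '<network id="net">',
    '<population id="pop" component="izh" size="2"/>',
    '<projection id="p" presynapticPopulation="pop" postsynapticPopulation="pop" synapse="syn">',
    sprintf('<connectionWD id="0" preCellId="pop[0]" postCellId="pop[1]" weight="1" delay="%s"/>', delay),
    "</projection>",
    '<inputList id="il" component="pg" population="pop">',
    '<input id="0" target="pop[0]" segmentId="0" fractionAlong="0.5"/>',
    "</inputList>",
    "</network>",
    '<Simulation id="sim" length="20ms" step="0.025ms" target="net" seed="1">',
    '<OutputFile id="o" fileName="o.dat">',
    '<OutputColumn id="c0" quantity="pop[0]/v"/>',
    '<OutputColumn id="c1" quantity="pop[1]/v"/>',
    "</OutputFile>",
    "</Simulation></Lems>")
}

# Single passive compartment driven by a DC current: analytic steady state
# v_inf = E + I/g. Leak conductance density 10 S/m2 on a 20x20 um cylinder.
passive_cell_xml <- function(amplitude = "0.5nA", duration_ms = 200,
                             with_input = TRUE) {
  paste0(
    "<Lems>",
    '<ionChannelHH id="leak"/>',
    '<cell id="pcell"><morphology>',
    '<segment id="0"><proximal x="0" y="0" z="0" diameter="20"/>',
    '<distal x="20" y="0" z="0" diameter="20"/></segment>',
    "</morphology>",
    '<biophysicalProperties id="b"><membraneProperties>',
    '<channelDensity id="l" ionChannel="leak" condDensity="10 S_per_m2" erev="-0.065 V"/>',
    '<spikeThresh value="-0.020 V"/>',
    '<specificCapacitance value="0.01 F_per_m2"/>',
    '<initMembPotential value="-0.065 V"/>',
    "</membraneProperties>",
    '<intracellularProperties><resistivity value="1 ohm_m"/></intracellularProperties>',
    "</biophysicalProperties></cell>",
    sprintf('<pulseGenerator id="pg" delay="0ms" duration="%gms" amplitude="%s"/>',
            duration_ms, amplitude),
    '<network id="net"><population id="pop" component="pcell" size="1"/>',
    if (with_input) paste0(
      '<inputList id="il" component="pg" population="pop">',
      '<input id="0" target="pop[0]" segmentId="0" fractionAlong="0.5"/>',
      "</inputList>") else "",
    "</network>",
    sprintf('<Simulation id="sim" length="%gms" step="0.025ms" target="net" seed="1">',
            duration_ms),
    '<OutputFile id="o" fileName="o.dat">',
    '<OutputColumn id="c0" quantity="pop[0]/0/v"/>',
    "</OutputFile>",
    "</Simulation></Lems>")
}

load_fixture_sim <- function(xml) {
  ls <- load_simulation(xml)
  m <- ls$model
  attr(m, "simulation") <- ls$spec
  m
}

# passive-cell parameters used by hand oracles in tests
passive_params <- function() {
  area <- pi * (10e-6 + 10e-6) * sqrt(0 + (20e-6)^2)  # frustum, r1 = r2
  list(area = area,
       g = 10 * area,        # S
       C = 0.01 * area,      # F
       E = -0.065)
}
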