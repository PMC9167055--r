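test_that("compartment capacitance follows membrane area", {
  # 10x10 um cylinder at 1 uF/cm^2: C = 1e-2 F/m^2 * pi * d * L ~ 3.1416e-12 F
  xml <- paste0(
    "<neuroml>",
    '<ionChannelHH id="leak"/>',
    '<cell id="c"><morphology>',
    '<segment id="0"><proximal x="0" y="0" z="0" diameter="10"/>',
    '<distal x="10" y="0" z="0" diameter="10"/></segment>',
    "</morphology>",
    '<biophysicalProperties id="b"><membraneProperties>',
    '<channelDensity id="l" ionChannel="leak" condDensity="1 S_per_m2" erev="-0.065 V"/>',
    '<specificCapacitance value="1 uF_per_cm2"/>',
    '<initMembPotential value="-0.065 V"/>',
    "</membraneProperties>",
    '<intracellularProperties><resistivity value="1 ohm_m"/></intracellularProperties>',
    "</biophysicalProperties></cell>",
    '<network id="n"><population id="p" component="c" size="1"/></network>',
    "</neuroml>")
  doc <- parse_model(xml)
  comps <- discretize(doc$cell_types$c, doc)
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$capacitance, 1e-2 * pi * 1e-5 * 1e-5,
               tolerance = 1e-12)
  expect_identical(comps[[1]]$parent, -1L)
})

test_that("ball-and-stick discretizes with correct topology and axial conductance", {
  m <- gen_ball_and_stick_net(n = 1, p_connect = 0, duration_ms = 1)
  doc <- m
  comps <- discretize(doc$cell_types$bscell, doc)
  expect_length(comps, 4L)
  expect_identical(vapply(comps, `[[`, integer(1), "parent"),
                   c(-1L, 0L, 1L, 2L))
  # child's axial conductance: (pi/4) dbar^2 / (Ra L), dendrite d = 2 um,
  # L = 50 um, Ra = 1 ohm m
  g_expect <- (pi / 4) * (2e-6)^2 / (1 * 50e-6)
  expect_equal(comps[[2]]$g_axial, g_expect, tolerance = 1e-12)
  expect_true(all(vapply(comps, `[[`, numeric(1), "capacitance") > 0))
})

test_that("segment-group-scoped densities only reach member compartments", {
  m <- gen_ball_and_stick_net(n = 1, p_connect = 0, duration_ms = 1)
  comps <- discretize(m$cell_types$bscell, m)
  soma_mechs <- vapply(comps[[1]]$mechanisms, `[[`, character(1), "id")
  dend_mechs <- vapply(comps[[3]]$mechanisms, `[[`, character(1), "id")
  expect_true(all(c("na", "k", "leak") %in% soma_mechs))
  expect_identical(dend_mechs, "leak")
})
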