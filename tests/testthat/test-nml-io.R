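test_that("a minimal document parses into one cell type and one population", {
  doc <- parse_model(tiny_izh_xml())
  expect_length(doc$cell_types, 1L)
  net <- doc$networks$net
  expect_length(net$populations, 1L)
  expect_identical(net$populations$pop$size, 1L)
})

test_that("unresolved references raise", {
  bad <- sub('component="izh"', 'component="nope"', tiny_izh_xml())
  expect_error(parse_model(bad), class = "UnresolvedReference")
  bad2 <- paste0(
    "<neuroml>",
    '<izhikevichCell id="izh" v0="-70mV" thresh="30mV" a="0.02" b="0.2" c="-50mV" d="2"/>',
    '<network id="net"><population id="pop" component="izh" size="2"/>',
    '<projection id="p" presynapticPopulation="pop" postsynapticPopulation="pop" synapse="ghost"/>',
    "</network></neuroml>")
  expect_error(parse_model(bad2), class = "UnresolvedReference")
  expect_error(parse_model("<neuroml><quantumCell id='q'/></neuroml>"),
               class = "UnsupportedElement")
})

test_that("fixture documents serialize and parse back to an equal object model", {
  fixtures <- list(
    gen_ball_and_stick_net(n = 3, p_connect = 0.4, seed = 1, duration_ms = 10),
    gen_izhikevich_net(n = 6, p_connect = 0.2, seed = 2, duration_ms = 10),
    gen_gap_ring(n = 3, n_compartments = 3, n_inputs = 5, duration_ms = 10),
    gen_custom_lif_net(n = 3, duration_ms = 10))
  for (m in fixtures) {
    doc <- m
    attributes(doc) <- attributes(doc)["names"]
    class(doc) <- "model_document"
    back <- parse_model(serialize_model(doc))
    expect_equal(back, doc)
  }
})

test_that("load_simulation binds duration, dt and probes", {
  sim <- load_simulation(attr(gen_hh_soma(), "xml"))
  expect_equal(sim$spec$duration, 0.1)
  expect_equal(sim$spec$dt, 2.5e-5)
  expect_length(sim$spec$output_files, 1L)
  expect_length(sim$spec$event_files, 1L)
  # probe to a nonexistent segment
  bad <- sub("hhpop\\[0\\]/0/v", "hhpop[0]/7/v", attr(gen_hh_soma(), "xml"))
  expect_error(load_simulation(bad), class = "UnresolvedProbePath")
})

test_that("a document with no Simulation raises MissingSimulation", {
  expect_error(load_simulation(tiny_izh_xml()), class = "MissingSimulation")
})

test_that("recordings round-trip through disk bit-identically", {
  m <- load_fixture_sim(two_cell_event_xml())
  rec <- run_simulation(m)
  dir <- withr::local_tempdir()
  spec <- attr(m, "simulation")
  write_recordings(rec, spec, dir = dir)
  wf <- read_waveforms(file.path(dir, "o.dat"))
  expect_equal(nrow(wf$waveforms), rec$steps + 1L)
  expect_identical(wf$time, rec$time)
  expect_identical(wf$waveforms, unname(rec$waveforms))
  # writing the same recording twice gives identical bytes
  f1 <- file.path(dir, "o.dat")
  bytes1 <- readBin(f1, "raw", file.size(f1))
  write_recordings(rec, spec, dir = dir)
  bytes2 <- readBin(f1, "raw", file.size(f1))
  expect_identical(bytes1, bytes2)
})

test_that("empty spike trains give an empty, header-free event file", {
  m <- gen_hh_soma(amplitude_nA = 0)
  rec <- run_simulation(m)
  expect_identical(nrow(rec$spikes), 0L)
  dir <- withr::local_tempdir()
  write_recordings(rec, attr(m, "simulation"), dir = dir)
  ev <- read_events(file.path(dir, "out.spikes"))
  expect_identical(nrow(ev), 0L)
})
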