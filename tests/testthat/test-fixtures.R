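test_that("fixture generation is pure: same spec, same bytes", {
  x1 <- attr(gen_ball_and_stick_net(n = 4, p_connect = 0.3, seed = 9), "xml")
  x2 <- attr(gen_ball_and_stick_net(n = 4, p_connect = 0.3, seed = 9), "xml")
  expect_identical(x1, x2)
  x3 <- attr(gen_ball_and_stick_net(n = 4, p_connect = 0.3, seed = 10), "xml")
  expect_false(identical(x1, x3))
})

test_that("the HH soma fires repetitively under the clamp and not without", {
  rec <- run_simulation(gen_hh_soma(), fp64 = TRUE)
  expect_gte(nrow(rec$spikes), 2L)
  # all spikes fall within the 10-90 ms clamp window (plus latency)
  expect_true(all(rec$spikes$time > 0.010))
  rec0 <- run_simulation(gen_hh_soma(amplitude_nA = 0), fp64 = TRUE)
  expect_identical(nrow(rec0$spikes), 0L)
})

test_that("ball-and-stick cells contribute exactly 4 compartments and seeded edges", {
  n <- 6; p <- 0.25; seed <- 3
  m <- gen_ball_and_stick_net(n = n, p_connect = p, seed = seed,
                              duration_ms = 1)
  comps <- discretize(m$cell_types$bscell, m)
  expect_length(comps, 4L)
  # edge count equals an independent regeneration of the Bernoulli draws
  edges <- nrow(m$networks$net$projections[[1]]$connections)
  expected <- 0L
  for (i in seq_len(n) - 1L) {
    for (j in seq_len(n) - 1L) {
      if (i != j && flatbrain:::fb_fix_u(seed, i, j) < p) {
        expected <- expected + 1L
      }
    }
  }
  expect_identical(edges, expected)
  # p = 0: no synapses at all
  m0 <- gen_ball_and_stick_net(n = 3, p_connect = 0, duration_ms = 1)
  expect_length(m0$networks$net$projections, 0L)
})

test_that("izhikevich synapse counts grow quadratically with n", {
  count_edges <- function(m) {
    sum(vapply(m$networks$net$projections,
               function(p) nrow(p$connections), integer(1)))
  }
  e100 <- count_edges(gen_izhikevich_net(n = 100, p_connect = 0.05, seed = 2,
                                         duration_ms = 1))
  # expected edges = p * n * (n-1) = 495
  expect_lt(abs(e100 - 495), 3 * sqrt(495))
  e200 <- count_edges(gen_izhikevich_net(n = 200, p_connect = 0.05, seed = 2,
                                         duration_ms = 1))
  e400 <- count_edges(gen_izhikevich_net(n = 400, p_connect = 0.05, seed = 2,
                                         duration_ms = 1))
  expect_gt(e400 / e200, 3.5)
  expect_lt(e400 / e200, 4.5)
  # n = 1: no recurrent synapses
  m1 <- gen_izhikevich_net(n = 1, p_connect = 0.5, duration_ms = 1)
  expect_length(m1$networks$net$projections, 0L)
})

test_that("the gap ring is electrically closed with the protocol input count", {
  m <- gen_gap_ring(n = 4, duration_ms = 1)
  ep <- m$networks$net$electrical_projections[[1]]
  expect_identical(nrow(ep$connections), 4L)
  # per-cell input table length is 100
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1)
  for (it in ts$items) {
    tot <- 0L
    for (kname in grep("^input:", names(it$k), value = TRUE)) {
      tot <- tot + it$k[[kname]]$n
    }
    expect_identical(tot, 100L)
  }
})

test_that("gap junctions propagate depolarization to neighbours within 5 ms", {
  # silence the Poisson drive and depolarize cell 0 with a strong pulse
  m <- gen_gap_ring(n = 3, n_compartments = 3, n_inputs = 1, rate_hz = 0,
                    duration_ms = 20)
  xml <- attr(m, "xml")
  xml <- sub('</inputList>',
             paste0('</inputList>',
                    '<inputList id="probe_in" component="kick" population="ring">',
                    '<input id="0" target="ring[0]" segmentId="0" fractionAlong="0.5"/>',
                    '</inputList>'), xml)
  xml <- sub('<network id="net">',
             paste0('<pulseGenerator id="kick" delay="1ms" duration="19ms" amplitude="0.5nA"/>',
                    '<network id="net">'), xml)
  m2 <- load_fixture_sim(xml)
  rec <- reference_simulate(m2, fp64 = TRUE)
  # neighbour voltage (column 2) rises above rest within 5 ms of the kick
  i5ms <- which(rec$time >= 0.006)[1]
  baseline <- rec$waveforms[1, 2]
  expect_gt(max(rec$waveforms[1:i5ms, 2]) - baseline, 1e-5)
})

test_that("all fixtures parse cleanly within the supported subset", {
  fixtures <- list(gen_hh_soma(), gen_big_cell(n_comp = 10),
                   gen_custom_lif_net(n = 2, duration_ms = 1))
  for (m in fixtures) {
    expect_s3_class(m, "model_document")
    expect_s3_class(attr(m, "simulation"), "simulation_spec")
  }
})
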