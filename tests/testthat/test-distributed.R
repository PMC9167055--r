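test_that("partitioning is contiguous, covering and balanced", {
  expect_identical(partition_neurons(10, 3),
                   list(c(0L, 4L), c(4L, 7L), c(7L, 10L)))
  p58 <- partition_neurons(5, 8)
  sizes <- vapply(p58, function(r) r[2] - r[1], numeric(1))
  expect_identical(sizes, c(rep(1, 5), rep(0, 3)))
  p02 <- partition_neurons(0, 2)
  expect_true(all(vapply(p02, function(r) r[1] == r[2], logical(1))))
})

test_that("send lists follow the four-case analysis", {
  # two izhikevich cells, one event synapse 0 -> 1, two workers
  m <- load_fixture_sim(two_cell_event_xml())
  part <- partition_neurons(2, 2)
  sl1 <- build_send_lists(m, part, 1)   # owns neuron 0 (the pre side)
  sl2 <- build_send_lists(m, part, 2)   # owns neuron 1 (the post side)
  expect_length(sl1, 0L)                # pre-only side requests nothing
  expect_length(sl2, 1L)
  expect_identical(sl2[["1"]][[1]]$payload, "spike")
  # gap junction: both sides list the peer voltage
  mg <- gen_gap_ring(n = 2, n_compartments = 3, n_inputs = 2, duration_ms = 1)
  pg <- partition_neurons(2, 2)
  g1 <- build_send_lists(mg, pg, 1); g2 <- build_send_lists(mg, pg, 2)
  expect_identical(g1[["2"]][[1]]$payload, "v")
  expect_identical(g2[["1"]][[1]]$payload, "v")
  # all synapses local -> all send lists empty
  all_local <- build_send_lists(m, partition_neurons(2, 1), 1)
  expect_length(all_local, 0L)
})

test_that("the exchange protocol sends one request/ack per communicating pair", {
  mk <- function(pairs, W) {
    # pairs: list of c(requester, owner)
    sls <- lapply(seq_len(W), function(w) list())
    for (p in pairs) {
      sls[[p[1]]][[as.character(p[2])]] <-
        list(list(population = "x", instance = 0L, segment = 0L,
                  fraction = 0.5, payload = "spike"))
    }
    sls
  }
  one <- exchange_send_lists(mk(list(c(1, 3)), 3))
  expect_identical(one$requests, 1L); expect_identical(one$acks, 1L)
  none <- exchange_send_lists(mk(list(), 4))
  expect_identical(none$requests, 0L); expect_identical(none$acks, 0L)
  ring <- exchange_send_lists(mk(list(c(1, 2), c(2, 3), c(3, 1)), 3))
  expect_identical(ring$requests, 3L); expect_identical(ring$acks, 3L)
  expect_identical(ring$out[[2]][["1"]][[1]]$payload, "spike")
})

test_that("message framing matches the declared layout", {
  # 2 continuous entries + fired {1,3} of 5 declared: payload 2 f32 + 2 i32
  msg <- pack_message(c(1.5, -2.25), c(1L, 3L))
  expect_identical(length(msg), 4L + 16L)
  expect_identical(readBin(msg[1:4], "integer", size = 4, endian = "little"),
                   16L)
  up <- unpack_message(msg, n_continuous = 2, n_event_entries = 5)
  expect_identical(up$values, c(1.5, -2.25))  # exactly f32-representable
  expect_identical(up$fired, c(1L, 3L))
  # no spikes: header = 4 * continuous
  msg2 <- pack_message(c(1, 2, 3), integer(0))
  expect_identical(readBin(msg2[1:4], "integer", size = 4, endian = "little"),
                   12L)
  expect_error(unpack_message(msg[1:10], 2, 5), class = "FrameLengthMismatch")
})

test_that("random payloads round-trip bitwise at the f64 wire width", {
  set.seed(5)
  for (rep in 1:50) {
    nv <- sample(0:6, 1)
    ne <- sample(0:6, 1)
    values <- rnorm(nv)
    fired <- sort(sample(0:9, ne))
    msg <- pack_message(values, fired, size = 8L)
    up <- unpack_message(msg, nv, n_event_entries = 10, size = 8L)
    expect_identical(up$values, values)
    expect_identical(up$fired, as.integer(fired))
  }
})

test_that("mirrors are only installed for actual remote dependencies", {
  # fully local model: no remote needs, no mirrors
  m <- gen_izhikevich_net(n = 4, p_connect = 0.5, seed = 1, duration_ms = 1)
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1)
  expect_length(ts$remote_needs, 0L)
  expect_length(install_mirrors(ts, list()), 0L)
})

test_that("remote graded sentinels are resolved by mirror installation", {
  mg <- gen_gap_ring(n = 2, n_compartments = 3, n_inputs = 2, duration_ms = 1)
  an <- flatbrain:::fb_analyze(mg, network = "net")
  part <- partition_neurons(2, 2)
  ts <- allocate_tables(an, seed = 1, items = 0L)
  expect_length(ts$remote_needs, 1L)
  sl <- build_send_lists(an, part, 1)
  mir <- install_mirrors(ts, sl)
  expect_length(mir, 1L)
  expect_identical(mir[["2"]]$n_graded, 1L)
  # the gap ref table no longer holds a sentinel
  it <- ts$items[[1]]
  gk <- it$k[[grep("gap:", names(it$k))[1]]]
  expect_false(any(ts[[gk$cols$ref$binding]] == flatbrain:::fb_sentinel_ref()))
})

test_that("more workers than neurons still runs and matches", {
  m <- gen_custom_lif_net(n = 3, duration_ms = 30)
  base <- run_simulation(m, fp64 = TRUE)
  d <- run_distributed(m, workers = 6, fp64 = TRUE)
  expect_identical(base$waveforms, d$waveforms)
  expect_identical(base$spikes, d$spikes)
})

test_that("message volume scales with the cut size", {
  mg <- gen_gap_ring(n = 4, n_compartments = 3, n_inputs = 2, duration_ms = 1)
  part <- partition_neurons(4, 2)
  # ring 0-1-2-3-0 cut into {0,1} and {2,3}: edges 1-2 and 3-0 cross, each
  # contributing one peer-voltage dependency in each direction
  sl1 <- build_send_lists(mg, part, 1)
  sl2 <- build_send_lists(mg, part, 2)
  n1 <- sum(vapply(sl1, length, integer(1)))
  n2 <- sum(vapply(sl2, length, integer(1)))
  expect_identical(n1, 2L)
  expect_identical(n2, 2L)
  # per-step payload bytes for worker 1's incoming mirror traffic
  msg <- pack_message(numeric(n1), integer(0))
  expect_identical(length(msg) - 4L, 4L * n1)
})
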