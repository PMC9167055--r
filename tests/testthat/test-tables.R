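test_that("table refs pack and unpack losslessly", {
  expect_identical(pack_ref(2, 5), 2 * 2^32 + 5)
  expect_identical(pack_ref(0, 0), 0)
  u <- unpack_ref(pack_ref(2, 5))
  expect_identical(u$serial, 2); expect_identical(u$offset, 5)
  # sentinel is exactly representable
  s <- flatbrain:::fb_sentinel_ref()
  us <- unpack_ref(s)
  expect_identical(us$serial, 2^31 - 1); expect_identical(us$offset, 0)
  expect_error(pack_ref(1, 2^32), class = "OffsetOverflow")
  expect_error(pack_ref(2^31, 0), class = "OffsetOverflow")
})

test_that("random (serial, offset) pairs round-trip", {
  set.seed(7)
  serial <- sample(0:(2^20 - 1), 1e4, replace = TRUE)
  offset <- sample(0:(2^31 - 1), 1e4, replace = TRUE)
  r <- serial * 2^32 + offset
  u <- unpack_ref(r)
  expect_identical(u$serial, as.numeric(serial))
  expect_identical(u$offset, as.numeric(offset))
})

test_that("identical point neurons share one contiguous state table", {
  m <- gen_izhikevich_net(n = 5, p_connect = 0, duration_ms = 1)
  ne <- 4L  # 80% of 5
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1)
  # izhikevichCell has 2 state vars: exc slice length 2*4, inh 2*1
  expect_identical(length(ts$T2A), 10L)
  expect_identical(ts$T2A, ts$T2B)  # buffers equal after initialization
  # slices are a disjoint gapless cover
  offs <- vapply(ts$items, function(it) it$sf, numeric(1))
  expect_identical(sort(offs), c(0, 2, 4, 6, 8))
})

test_that("a neuron with no synapses keeps its kind tables at length zero", {
  m <- gen_izhikevich_net(n = 3, p_connect = 0, duration_ms = 1)
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1)
  it <- ts$items[[1]]
  # the drive input kind exists; no recurrent synapse kind tables appear
  # (p = 0 means no projections at all), and input tables have one entry
  expect_true(length(it$k) >= 1L)
  drive <- it$k[[grep("input:", names(it$k))[1]]]
  expect_identical(drive$n, 1L)
})

test_that("state slot totals match an independent count", {
  n <- 4L
  m <- gen_ball_and_stick_net(n = n, p_connect = 0.5, seed = 1,
                              duration_ms = 1)
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1)
  # per cell: 4 v slots + soma gates m,h,n = 3  => 7 f32 scalar states
  expect_identical(length(ts$T2A), n * 7L)
  # synapse state slots: each connection adds A and B (expTwoSynapse)
  edges <- sum(vapply(m$networks$net$projections,
                      function(p) nrow(p$connections), integer(1)))
  syn_state_len <- 0L
  for (it in ts$items) {
    for (kname in grep("^syn:", names(it$k), value = TRUE)) {
      kk <- it$k[[kname]]
      syn_state_len <- syn_state_len + kk$n
    }
  }
  expect_identical(syn_state_len, edges)
})

test_that("appended entries carry overrides and defaults", {
  m <- load_fixture_sim(two_cell_event_xml())
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1)
  it2 <- ts$items[[2]]
  kk <- it2$k[[grep("^syn:", names(it2$k))[1]]]
  expect_identical(kk$n, 1L)
  expect_identical(ts[[kk$cols$w$binding]], 1.0)      # weight from document
  expect_identical(ts[[kk$cols$dl$binding]], 0.0)     # delay 0 s
  expect_identical(ts[[paste0(kk$cols$fl$binding, "A")]], 0.0)
})

test_that("reference redirection moves reads without touching code", {
  m <- gen_gap_ring(n = 3, n_compartments = 3, n_inputs = 2, duration_ms = 1)
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1)
  it <- ts$items[[1]]
  gk <- it$k[[grep("gap:", names(it$k))[1]]]
  refs <- ts[[gk$cols$ref$binding]]
  expect_true(length(refs) >= 1L)
  v_direct <- flatbrain:::fb_deref(ts, refs[1], "A")
  # redirect the first ref to a fresh mirror slot holding a marker value
  s <- ts$next_serial; ts$next_serial <- s + 1
  ts[[paste0("T", s, "A")]] <- c(42)
  ts[[paste0("T", s, "B")]] <- c(42)
  ts$meta[[as.character(s)]] <- list(serial = s, binding = paste0("T", s),
                                     type = "f32", mut = "state",
                                     owner = "test mirror", role = "mirror")
  redirect_refs(ts, stats::setNames(pack_ref(s, 0), as.character(refs[1])))
  refs2 <- ts[[gk$cols$ref$binding]]
  expect_identical(flatbrain:::fb_deref(ts, refs2[1], "A"), 42)
  # empty mapping leaves tables unchanged
  before <- ts[[gk$cols$ref$binding]]
  redirect_refs(ts, stats::setNames(numeric(0), character(0)))
  expect_identical(ts[[gk$cols$ref$binding]], before)
})

test_that("reading a sentinel in debug mode traps", {
  m <- gen_gap_ring(n = 3, n_compartments = 3, n_inputs = 2, duration_ms = 1)
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1)
  expect_error(flatbrain:::fb_deref(ts, flatbrain:::fb_sentinel_ref(), "A"),
               class = "DanglingSentinel")
})

test_that("probe-path resolution is injective over somatic voltage slots", {
  m <- gen_ball_and_stick_net(n = 4, p_connect = 0, duration_ms = 1)
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1)
  refs <- vapply(0:3, function(i) {
    flatbrain:::fb_resolve_path(ts, "pop", i, 0L, "v")
  }, numeric(1))
  expect_identical(anyDuplicated(refs), 0L)
})
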