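test_that("deduplication partitions compartments by structural profile", {
  m <- gen_big_cell(n_comp = 319)
  an <- flatbrain:::fb_analyze(m, network = "net")
  tp <- an$types$bigcell
  expect_identical(tp$n_comp, 319L)
  expect_length(tp$groups, 3L)  # soma, passive-odd, K-even profiles
  members <- unlist(lapply(tp$groups, `[[`, "members"))
  expect_identical(sort(members), 0:318)       # disjoint cover
  expect_identical(anyDuplicated(members), 0L)
  sizes <- vapply(tp$groups, function(g) length(g$members), integer(1))
  expect_identical(sum(sizes), 319L)
})

test_that("constants are data, not structure: differing gbar stays one group", {
  # in the big cell, all odd compartments share a group although their areas
  # (hence absolute conductances) differ
  m <- gen_big_cell(n_comp = 21)
  an <- flatbrain:::fb_analyze(m, network = "net")
  tp <- an$types$bigcell
  odd_group <- NULL
  for (g in tp$groups) if (1L %in% g$members) odd_group <- g
  gbars <- vapply(odd_group$members, function(ci) {
    tp$comps[[ci + 1L]]$mechanisms[[1]]$gbar
  }, numeric(1))
  expect_gt(length(unique(gbars)), 1L)  # constants differ within the group
})

test_that("an all-passive chain collapses to one dedup group", {
  m <- load_fixture_sim(passive_cell_xml())
  comps <- discretize(m$cell_types$pcell, m)
  comps <- lapply(comps, function(c) {
    c$syn_kinds <- character(0); c$input_kinds <- character(0); c
  })
  groups <- deduplicate(comps)
  expect_length(groups, 1L)
})

test_that("attachment resolution scopes kinds to the compartments hit", {
  m <- gen_ball_and_stick_net(n = 3, p_connect = 1, seed = 1, duration_ms = 1)
  at <- resolve_attachments(m$networks$net, m$cell_types, m)
  # ampa synapses project onto somata (segment 0) only
  expect_true("ampa" %in% at$bscell$syn[["0"]])
  expect_false(any(vapply(c("1", "2"), function(k) {
    "ampa" %in% at$bscell$syn[[k]]
  }, logical(1))))
  # the Poisson drive sits on the dendrite tip
  expect_true("drive" %in% at$bscell$input[["3"]])
})

test_that("gap junctions register a peer-voltage kind on both endpoint types", {
  m <- gen_gap_ring(n = 3, n_compartments = 3, n_inputs = 2, duration_ms = 1)
  at <- resolve_attachments(m$networks$net, m$cell_types, m)
  tipkinds <- at$gcell$syn[["2"]]
  expect_true(any(startsWith(tipkinds, "gap:")))
  an <- flatbrain:::fb_analyze(m, network = "net")
  gk <- Filter(function(k) k$role == "gap", an$types$gcell$syn_kinds)
  expect_length(gk, 1L)
  expect_true("vpeer" %in% names(gk[[1]]$dynamics$requirements))
})

test_that("the work plan enumerates neurons gaplessly in document order", {
  m <- gen_izhikevich_net(n = 5, p_connect = 0, duration_ms = 1)
  plan <- build_work_plan(m)
  expect_identical(plan$work_items$idx, 0:4)
  expect_identical(unname(plan$pop_offset["exc"]), 0L)
  # heterogeneous network: two kernel type ids
  expect_length(plan$types, 2L)
})

test_that("flat and loop forms switch at the K threshold", {
  m <- gen_ball_and_stick_net(n = 1, p_connect = 0, duration_ms = 1)
  an8 <- flatbrain:::fb_analyze(m, network = "net", K = 8L)
  an2 <- flatbrain:::fb_analyze(m, network = "net", K = 2L)
  expect_identical(an8$types$bscell$nsig$form, "flat")
  expect_identical(an2$types$bscell$nsig$form, "loop")
})

test_that("flat and loop kernels produce identical trajectories", {
  m <- gen_ball_and_stick_net(n = 2, p_connect = 1, seed = 1, duration_ms = 20)
  flat <- run_simulation(m, fp64 = TRUE, K = 8L)
  loop <- run_simulation(m, fp64 = TRUE, K = 2L)
  expect_identical(flat$waveforms, loop$waveforms)
  expect_identical(flat$spikes, loop$spikes)
})

test_that("loop-form statement count is independent of compartment count", {
  s319 <- emit_kernel(flatbrain:::fb_analyze(gen_big_cell(319), network = "net"),
                      "bigcell")
  s638 <- emit_kernel(flatbrain:::fb_analyze(gen_big_cell(638), network = "net"),
                      "bigcell")
  expect_identical(s319$n_statements, s638$n_statements)
})
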