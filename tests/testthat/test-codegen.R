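test_that("cnexp is chosen for HH gates and forward Euler elsewhere", {
  gate_state <- list(name = "m", gate = TRUE)
  gate_deriv <- quote((inf_m - m) / tau_m)
  expect_identical(choose_integrator(gate_state,
                                     list(kind = "gate", deriv = gate_deriv)),
                   "cnexp")
  syn_state <- list(name = "g", gate = NULL)
  expect_identical(choose_integrator(syn_state,
                                     list(kind = "synapse",
                                          deriv = quote(-g / tau))),
                   "fwd_euler")
  izh_state <- list(name = "v", gate = NULL)
  expect_identical(choose_integrator(izh_state,
                                     list(kind = "cell",
                                          deriv = quote(0.04 * v^2 + 5 * v))),
                   "fwd_euler")
  # a "gate" whose derivative is nonlinear in the state cannot use cnexp
  expect_identical(choose_integrator(gate_state,
                                     list(kind = "gate",
                                          deriv = quote(m^2 - m))),
                   "fwd_euler")
})

test_that("kernel source structure matches the signature", {
  m <- parse_model(tiny_izh_xml())
  ks <- emit_kernel(m, "izh")
  # two forward-Euler update lines, one reset handler, no cable call
  expect_identical(length(gregexpr("dt \\* \\(", ks$source)[[1]]), 2L)
  expect_true(grepl("if (", ks$source, fixed = TRUE))       # reset condition
  expect_false(grepl("hines_solve", ks$source))
  # HH soma: cnexp updates for the gates, voltage via the cable path
  mh <- gen_hh_soma()
  ksh <- emit_kernel(flatbrain:::fb_analyze(mh, network = "net"), "hhcell")
  expect_identical(length(gregexpr("exp\\(-dt / ", ksh$source)[[1]]), 3L)
  expect_true(grepl("hines_solve", ksh$source))
})

test_that("emission is reproducible and loading is cached by hash", {
  m <- parse_model(tiny_izh_xml())
  k1 <- emit_kernel(m, "izh"); k2 <- emit_kernel(m, "izh")
  expect_identical(k1$source, k2$source)
  expect_identical(k1$hash, k2$hash)
  f1 <- load_kernel(k1); f2 <- load_kernel(k2)
  expect_identical(f1, f2)
})

test_that("corrupted kernel source raises GenerationBug with an excerpt", {
  m <- parse_model(tiny_izh_xml())
  ks <- emit_kernel(m, "izh")
  ks$source <- paste0(ks$source, "\n)unbalanced(")
  ks$hash <- "corrupted"
  err <- tryCatch(load_kernel(ks), error = function(e) e)
  expect_s3_class(err, "GenerationBug")
  expect_match(conditionMessage(err), "function")
})

test_that("one generated step of a passive compartment matches the hand oracle", {
  # backward-Euler step: v' = (C/dt * v + g*E + I) / (C/dt + g)
  m <- load_fixture_sim(passive_cell_xml(amplitude = "0.5nA",
                                         duration_ms = 0.025))
  rec <- run_simulation(m, fp64 = TRUE)
  pp <- passive_params()
  dtt <- 2.5e-5
  v0 <- -0.065
  Cdt <- pp$C / dtt
  v1 <- (Cdt * v0 + pp$g * pp$E + 0.5e-9) / (Cdt + pp$g)
  expect_equal(rec$waveforms[2, 1], v1, tolerance = 1e-12)
})

test_that("kernels write only their own slots (checksum guard)", {
  m <- gen_izhikevich_net(n = 4, p_connect = 0, duration_ms = 1)
  an <- flatbrain:::fb_analyze(m, network = "net")
  ts <- allocate_tables(an, seed = 1, fp64 = TRUE)
  kern <- load_kernel(emit_kernel(an, "rs"))
  it2 <- ts$items[[2]]
  before_A <- ts$T2A
  before_B <- ts$T2B
  kern(ts, it2, 0, 2.5e-5, 0L)
  # read buffer untouched
  expect_identical(ts$T2A, before_A)
  # write buffer touched only within item 2's slice
  lay <- ts$layouts[[it2$type]]
  own <- it2$sf + seq_len(lay$sf_len)
  changed <- which(ts$T2B != before_B)
  expect_true(all(changed %in% own))
})
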