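test_that("a leaky integrator ComponentType parses into a DynamicsSpec", {
  ct <- parse_dynamics(paste0(
    '<ComponentType name="lif">',
    '<Constant name="rest" dimension="voltage" value="-0.065"/>',
    '<Constant name="tau" dimension="time" value="0.01"/>',
    '<Exposure name="v"/>',
    '<Dynamics><StateVariable name="v" dimension="voltage"/>',
    '<TimeDerivative variable="v" value="(rest - v)/tau"/></Dynamics>',
    "</ComponentType>"))
  expect_identical(names(ct$state_vars), "v")
  expect_length(ct$time_derivatives, 1L)
  expect_true("v" %in% names(ct$exposures))
  expect_setequal(flatbrain:::fb_expr_vars(ct$time_derivatives$v),
                  c("rest", "v", "tau"))
})

test_that("derived-variable cycles and unknown functions are rejected", {
  expect_error(parse_dynamics(paste0(
    '<ComponentType name="x"><Dynamics>',
    '<DerivedVariable name="a" value="b+1"/>',
    '<DerivedVariable name="b" value="a+1"/>',
    "</Dynamics></ComponentType>")), class = "CyclicDerivedVariables")
  expect_error(parse_dynamics(paste0(
    '<ComponentType name="x"><Dynamics>',
    '<DerivedVariable name="a" value="frobnicate(3)"/>',
    "</Dynamics></ComponentType>")), class = "UnknownFunction")
  expect_error(parse_dynamics(paste0(
    '<ComponentType name="x"><Dynamics>',
    '<KineticScheme name="ks"/>',
    "</Dynamics></ComponentType>")), class = "UnsupportedLemsFeature")
})

test_that("the exponential-conductance synapse template matches the standard form", {
  dyn <- flatbrain:::fb_builtin_dynamics("expOneSynapse", list(
    id = "s", gbase = "1nS", erev = "0mV", tauDecay = "5ms"))
  expect_length(dyn$on_events, 1L)
  expect_named(dyn$on_events[["in"]]$assignments, "g")
  expect_length(dyn$time_derivatives, 1L)
  # dg/dt = -g/tau and the OnEvent increments g by weight * gbase
  env <- new.env()
  env$g <- 2e-9; env$tauDecay <- 5e-3; env$weight <- 3; env$gbase <- 1e-9
  expect_equal(eval(dyn$time_derivatives$g, env), -2e-9 / 5e-3)
  expect_equal(eval(dyn$on_events[["in"]]$assignments$g, env), 2e-9 + 3e-9)
  # i = g*(erev - v)
  env$erev <- 0; env$v <- -0.065
  expect_equal(eval(dyn$derived_vars$i, env), 2e-9 * 0.065)
})

test_that("LEMS dotted comparison operators parse", {
  e <- flatbrain:::fb_parse_expr("v .gt. thresh .and. w .leq. 2")
  env <- list(v = 3, thresh = 1, w = 2)
  expect_true(eval(e, env))
})

test_that("ln maps to natural log and log to log10", {
  expect_equal(eval(flatbrain:::fb_parse_expr("ln(exp(2))")), 2)
  expect_equal(eval(flatbrain:::fb_parse_expr("log(100)")), 2)
})
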