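test_that("quantity strings convert to SI", {
  expect_equal(as.numeric(to_si("10 mV")), 0.010)
  expect_equal(as.numeric(to_si("0.3 mS_per_cm2")), 3.0)
  expect_equal(as.numeric(to_si("-20mV")), -0.020)  # no-space dialect
  expect_equal(as.numeric(to_si("2.5e-2 ms")), 2.5e-5)
  expect_equal(as.numeric(to_si("1 uF_per_cm2")), 0.01)
  expect_equal(as.numeric(to_si("100 kohm_cm")), 1000)
  expect_identical(attr(to_si("5 nA"), "dimension"), "current")
})

test_that("the unit table is closed", {
  expect_error(to_si("3 parsec"), class = "UnknownUnit")
  expect_error(to_si("not a number"), class = "UnknownUnit")
  expect_error(to_si("10 mV", expect_dim = "time"), class = "DimensionMismatch")
})

test_that("print/parse round trip preserves 6 significant digits", {
  vals <- c(1.234567e-3, 9.87654e2, 3.14159e-9, 6.02214e-2)
  for (v in vals) {
    txt <- flatbrain:::fb_format_quantity(v, "V")
    back <- as.vector(to_si(txt))
    expect_equal(back, v, tolerance = 5e-6)  # 6 significant digits
  }
})
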