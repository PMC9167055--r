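test_that("spike detection counts upward crossings with the stated tie rule", {
  dt <- 1e-3
  flat <- rep(-0.065, 100)
  expect_length(detect_spikes(flat, dt)$times, 0L)
  two <- c(rep(-0.065, 10), 0.02, rep(-0.065, 10), 0.02, -0.065)
  expect_length(detect_spikes(two, dt)$times, 2L)
  # hovering exactly at threshold then rising: one spike, on the right sample
  hover <- c(-0.065, -0.020, -0.020, 0.030, -0.065)
  st <- detect_spikes(hover, dt)
  expect_length(st$times, 1L)
  expect_equal(st$times, 1 * dt)  # first sample at/above threshold
})

test_that("similarity metric evaluates the printed formula", {
  x <- c(0, 1, 2)
  expect_identical(nmldb_similarity(x, x), 1)
  expect_equal(nmldb_similarity(x, c(1, 1, 1)), 2 / 3)
  expect_error(nmldb_similarity(c(1, 1, 1), x), class = "DegenerateRange")
  # similarity falls monotonically as the mean discrepancy grows
  s <- vapply(c(0.1, 0.5, 1), function(eps) {
    nmldb_similarity(x, x + eps)
  }, numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("train statistics: regular, empty and Poisson trains", {
  reg <- seq(0.1, 1.0, by = 0.1)
  st <- train_statistics(reg, duration = 1)
  expect_equal(st$rate, 10)
  expect_equal(st$mean_isi, 0.1)
  expect_equal(st$lv, 0)
  empty <- train_statistics(numeric(0), duration = 1)
  expect_equal(empty$rate, 0)
  expect_true(is.na(empty$mean_isi) && is.na(empty$lv))
  # LV of a long Poisson train approaches 1
  set.seed(1)
  pois <- cumsum(stats::rexp(1e4, rate = 100))
  stp <- train_statistics(pois, duration = max(pois))
  expect_lt(abs(stp$lv - 1), 0.05)
})

test_that("ISI percent difference has the documented sign convention", {
  a <- seq(0.1, 1.0, by = 0.1)
  expect_equal(isi_pct_diff(a, a), 0)
  expect_equal(isi_pct_diff(a, a[1] + (a - a[1]) * 1.025), 2.5,
               tolerance = 1e-9)
  expect_error(isi_pct_diff(a, 0.5), class = "InsufficientSpikes")
})

test_that("binned correlations and the waveform spectrum behave", {
  mk <- function(times) structure(list(times = times, duration = 1),
                                  class = "spike_train")
  a <- mk(seq(0.05, 0.95, by = 0.05))
  cm <- correlation_metrics(list(a, a))
  expect_equal(cm$cc[1, 2], 1)
  expect_equal(cm$rc[1, 2], 1)
  # k identical waveforms: correlation matrix has rank 1, spectrum {k, 0...}
  w <- matrix(rep(sin(seq(0, 10, length.out = 200)), 4), ncol = 4)
  cm2 <- correlation_metrics(list(a, a), waveforms = w)
  expect_equal(cm2$eigenvalues[1], 4, tolerance = 1e-10)
  expect_equal(cm2$eigenvalues[-1], rep(0, 3), tolerance = 1e-10)
  # independent Poisson trains decorrelate within sampling error
  set.seed(2)
  long <- lapply(1:2, function(i) {
    t <- cumsum(stats::rexp(2000, rate = 20))
    structure(list(times = t[t < 100], duration = 100), class = "spike_train")
  })
  cml <- correlation_metrics(long, bin_small = 0.002)
  nbins <- 100 / 0.002
  expect_lt(abs(cml$cc[1, 2]), 3 / sqrt(nbins))
  # zero-variance units get NA correlations
  none <- mk(numeric(0))
  cmz <- correlation_metrics(list(a, none))
  expect_true(is.na(cmz$cc[1, 2]))
})

test_that("effect size evaluates Cohen's d and the printed CI", {
  set.seed(3)
  x <- rnorm(45)
  # identical samples: d = 0, the CI half-width reduces to 1.96*sqrt(2/45)
  es0 <- effect_size(x, x)
  expect_equal(es0$d, 0)
  expect_equal(es0$ci_high, 1.96 * sqrt(2 / 45), tolerance = 1e-12)
  expect_equal(es0$ci_high, 0.413218, tolerance = 1e-4)
  # antisymmetry and symmetric width under swap
  y <- rnorm(30, mean = 0.4)
  e1 <- effect_size(x, y); e2 <- effect_size(y, x)
  expect_equal(e1$d, -e2$d)
  expect_equal(e1$ci_high - e1$ci_low, e2$ci_high - e2$ci_low)
  # samples shifted by one SD: d approaches 1 for large N
  set.seed(4)
  big1 <- rnorm(2e4); big2 <- rnorm(2e4, mean = -1)
  expect_lt(abs(effect_size(big1, big2)$d - 1), 0.05)
  expect_error(effect_size(c(1, 1), c(1, 1)), class = "ZeroPooledVariance")
  # tidy() view
  td <- tidy(es0)
  expect_identical(td$n1, 45L)
})

test_that("network statistics summarize a recording per unit", {
  m <- gen_izhikevich_net(n = 6, p_connect = 0.2, seed = 3, duration_ms = 50)
  rec <- run_simulation(m)
  ns <- network_statistics(rec)
  expect_true(all(c("unit", "rate", "mean_isi", "lv") %in% names(ns)))
  expect_true(all(ns$rate >= 0))
})
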