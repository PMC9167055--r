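# Cross-simulator validation statistics.
#
# The waveform-level comparison uses the NeuroML-DB similarity metric
# 1 - mean(|x - xhat|) / (max(x) - min(x)) and the per-cent difference in
# mean inter-spike interval at a -20 mV spike threshold. Network activity is
# summarized per unit by firing rate, mean ISI and local variation, by
# pairwise Pearson correlations of binned spike counts at a small and a
# large bin (CC and RC), by the eigenvalue spectrum of the waveform
# correlation matrix, and by Cohen's d with its 95% confidence interval
# between two samples of any of these statistics.

#' Detect spikes by upward threshold crossing
#'
#' One spike per upward crossing: sample i spikes when
#' `x[i-1] < threshold <= x[i]` (a trace sitting exactly at the threshold
#' and then rising counts once, on the right sample). Spike time is
#' `i * dt` with 0-based sample indexing.
#'
#' @param x numeric waveform (volts).
#' @param dt sample interval (seconds).
#' @param threshold spike threshold in volts (default -20 mV).
#' @param duration observation duration; defaults to the waveform extent.
#' @return a `spike_train`: list with `times` (seconds, strictly
#'   increasing) and `duration`.
#' @export
detect_spikes <- function(x, dt, threshold = -0.020, duration = NULL) {
  stopifnot(all(is.finite(x)))
  n <- length(x)
  idx <- which(x[-1] >= threshold & x[-n] < threshold)
  times <- idx * dt
  structure(list(times = times,
                 duration = duration %||% ((n - 1) * dt)),
            class = "spike_train")
}

#' NeuroML-DB waveform similarity
#'
#' `1 - mean(|x - xhat|) / (max(x) - min(x))`, where `x` is the reference
#' waveform and `xhat` the tested one. Equals 1 exactly when the waveforms
#' are identical; decreases as the mean absolute discrepancy grows. A
#' constant reference has no range and raises `DegenerateRange`.
#'
#' @param x reference waveform.
#' @param xhat tested waveform (same length and sampling).
#' @return the similarity (a real number, at most 1).
#' @export
nmldb_similarity <- function(x, xhat) {
  if (length(x) != length(xhat)) {
    fb_abort("DegenerateRange", "waveforms must have equal length")
  }
  if (length(x) < 2L) fb_abort("DegenerateRange", "need at least 2 samples")
  rng <- max(x) - min(x)
  if (rng == 0) fb_abort("DegenerateRange", "reference waveform is constant")
  1 - mean(abs(x - xhat)) / rng
}

#' Per-unit spike-train statistics
#'
#' Firing rate is spike count over observation duration (defined for any
#' train, including empty ones); mean inter-spike interval needs at least
#' two spikes and local variation at least three (otherwise NA). Local
#' variation is `3/(n-1) * sum(((ISI_i - ISI_{i+1}) / (ISI_i +
#' ISI_{i+1}))^2)` over the n ISIs: 0 for a perfectly regular train, near 1
#' for a Poisson train.
#'
#' @param train a `spike_train` from [detect_spikes()], or a numeric vector
#'   of spike times (then `duration` must be given).
#' @param duration observation duration in seconds.
#' @return a one-row tibble: `n_spikes`, `rate`, `mean_isi`, `lv`.
#' @export
train_statistics <- function(train, duration = NULL) {
  if (inherits(train, "spike_train")) {
    times <- train$times; duration <- duration %||% train$duration
  } else {
    times <- as.numeric(train)
  }
  if (is.null(duration)) fb_abort("DegenerateRange", "duration required")
  n <- length(times)
  rate <- n / duration
  isi <- diff(times)
  mean_isi <- if (n >= 2L) mean(isi) else NA_real_
  lv <- if (n >= 3L) {
    m <- length(isi)
    3 / (m - 1) * sum(((isi[-m] - isi[-1]) / (isi[-m] + isi[-1]))^2)
  } else NA_real_
  tibble::tibble(n_spikes = n, rate = rate, mean_isi = mean_isi, lv = lv)
}

#' Per-cent difference in mean inter-spike interval
#'
#' `100 * (meanISI_test - meanISI_ref) / meanISI_ref`: positive when the
#' tested simulator fires slower than the reference.
#'
#' @param ref,test `spike_train`s (or numeric spike-time vectors) with at
#'   least two spikes each.
#' @return the signed percentage.
#' @export
isi_pct_diff <- function(ref, test) {
  tr <- if (inherits(ref, "spike_train")) ref$times else as.numeric(ref)
  tt <- if (inherits(test, "spike_train")) test$times else as.numeric(test)
  if (length(tr) < 2L || length(tt) < 2L) {
    fb_abort("InsufficientSpikes",
             "both trains need at least two spikes for an ISI")
  }
  100 * (mean(diff(tt)) - mean(diff(tr))) / mean(diff(tr))
}

#' Binned spike-train correlations and waveform correlation spectrum
#'
#' CC and RC are the Pearson correlation matrices of binned spike counts at
#' a small (default 2 ms) and large (default 100 ms) temporal bin; the
#' eigenvalues are the descending spectrum of the Pearson correlation matrix
#' of the raw waveforms (when given). Units with zero variance get NA
#' correlations.
#'
#' @param trains list of `spike_train`s (>= 2), sharing a duration.
#' @param waveforms optional matrix (sample x unit) of raw waveforms for the
#'   eigenvalue spectrum.
#' @param bin_small,bin_large bin widths in seconds.
#' @return list with `cc` and `rc` (correlation matrices), `eigenvalues`
#'   (descending, NULL without waveforms).
#' @export
correlation_metrics <- function(trains, waveforms = NULL,
                                bin_small = 0.002, bin_large = 0.1) {
  stopifnot(length(trains) >= 2L)
  duration <- trains[[1]]$duration
  bin_counts <- function(bin) {
    nb <- max(1L, as.integer(floor(duration / bin + 1e-9)))
    sapply(trains, function(tr) {
      idx <- pmin(nb, floor(tr$times / bin) + 1L)
      tabulate(idx, nbins = nb)
    })
  }
  safe_cor <- function(m) {
    sds <- apply(m, 2, stats::sd)
    r <- suppressWarnings(stats::cor(m))
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
    diag(r) <- ifelse(sds == 0, NA_real_, 1)
    r
  }
  cc <- safe_cor(bin_counts(bin_small))
  rc <- safe_cor(bin_counts(bin_large))
  ev <- NULL
  if (!is.null(waveforms)) {
    cw <- suppressWarnings(stats::cor(waveforms))
    cw[!is.finite(cw)] <- 0
    ev <- sort(eigen(cw, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  }
  list(cc = cc, rc = rc, eigenvalues = ev)
}

#' Cohen's d with its 95% confidence interval
#'
#' The standardized mean difference `(mean(x1) - mean(x2)) / s_pooled` with
#' `s_pooled^2 = ((N1-1) s1^2 + (N2-1) s2^2) / (N1+N2-2)`, and the
#' symmetric 95% confidence half-width
#' `1.96 * sqrt((N1+N2)/(N1*N2) + d^2 / (2*(N1+N2-2)))`.
#'
#' @param sample1,sample2 numeric samples (N1, N2 >= 2).
#' @return an `effect_size_report`: list with `d`, `n1`, `n2`, `ci_low`,
#'   `ci_high`.
#' @export
effect_size <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2L || n2 < 2L || n1 + n2 <= 2L) {
    fb_abort("ZeroPooledVariance", "need N1, N2 >= 2")
  }
  s2p <- ((n1 - 1) * stats::var(sample1) + (n2 - 1) * stats::var(sample2)) /
    (n1 + n2 - 2)
  if (s2p == 0) fb_abort("ZeroPooledVariance", "pooled variance is zero")
  d <- (mean(sample1) - mean(sample2)) / sqrt(s2p)
  half <- 1.96 * sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  structure(list(d = d, n1 = n1, n2 = n2,
                 ci_low = d - half, ci_high = d + half),
            class = "effect_size_report")
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf("Cohen's d = %.4f  (95%% CI %.4f .. %.4f; N1 = %d, N2 = %d)\n",
              x$d, x$ci_low, x$ci_high, x$n1, x$n2))
  invisible(x)
}

#' Tidy an effect-size report
#'
#' @param x an `effect_size_report`.
#' @param ... unused.
#' @return a one-row tibble with `d`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
tidy.effect_size_report <- function(x, ...) {
  tibble::tibble(d = x$d, ci_low = x$ci_low, ci_high = x$ci_high,
                 n1 = x$n1, n2 = x$n2)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Network-activity summary of a recording
#'
#' Per-unit firing rate, mean ISI and local variation for every spike
#' source in a recording.
#'
#' @param rec an `fb_recording`.
#' @param duration observation duration (defaults to the recording's).
#' @return a tibble with one row per unit.
#' @export
network_statistics <- function(rec, duration = NULL) {
  duration <- duration %||% (rec$steps * rec$dt)
  units <- sort(unique(rec$spikes$neuron))
  rows <- lapply(units, function(u) {
    st <- structure(list(times = rec$spikes$time[rec$spikes$neuron == u],
                         duration = duration), class = "spike_train")
    cbind(tibble::tibble(unit = u), train_statistics(st))
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(unit = integer(0), n_spikes = integer(0),
                          rate = double(0), mean_isi = double(0),
                          lv = double(0)))
  }
  do.call(rbind, rows)
}
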