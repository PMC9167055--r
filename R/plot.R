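# Plotting helpers (ggplot2, suggested dependency).

#' Plot recorded membrane-potential traces
#'
#' @param rec an `fb_recording`.
#' @param units_mV plot voltages in mV (default) instead of volts.
#' @return a ggplot object.
#' @export
plot_traces <- function(rec, units_mV = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    fb_abort("IOFailure", "ggplot2 is required for plotting")
  }
  np <- ncol(rec$waveforms)
  d <- data.frame(
    time = rep(rec$time * 1000, np),
    v = as.vector(rec$waveforms) * (if (units_mV) 1000 else 1),
    probe = rep(rec$probe_paths %||% paste0("probe", seq_len(np)),
                each = length(rec$time)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$v,
                                  colour = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)",
                  y = if (units_mV) "membrane potential (mV)" else "V (V)") +
    ggplot2::theme_minimal()
}

#' Raster plot of recorded spikes
#'
#' @param rec an `fb_recording`.
#' @return a ggplot object.
#' @export
plot_raster <- function(rec) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    fb_abort("IOFailure", "ggplot2 is required for plotting")
  }
  d <- data.frame(time = rec$spikes$time * 1000, neuron = rec$spikes$neuron)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' @export
print.fb_recording <- function(x, ...) {
  cat(sprintf(
    "<recording: %d steps of %g ms, %d probe(s), %d spike(s) from %d unit(s)>\n",
    x$steps, x$dt * 1000, ncol(x$waveforms), nrow(x$spikes),
    length(unique(x$spikes$neuron))))
  invisible(x)
}

#' Summary statistics of a recording
#'
#' @param object an `fb_recording`.
#' @param ... unused.
#' @return a one-row tibble: steps, dt, probes, total spikes, active units.
#' @export
glance.fb_recording <- function(object, ...) {
  tibble::tibble(steps = object$steps, dt = object$dt,
                 n_probes = ncol(object$waveforms),
                 n_spikes = nrow(object$spikes),
                 n_active_units = length(unique(object$spikes$neuron)))
}

#' @export
glance <- function(x, ...) UseMethod("glance")
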