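# The time-driven simulation engine.
#
# Per step: due spike events are applied to the read-side flag tables, every
# work item's kernel runs exactly once (in any order — results are
# order-independent by the double-buffering contract), write-side f32 state
# is rounded to single precision unless fp64 is on, recorded probes are
# sampled from the write buffers, newly fired spikes are routed (arrival
# step = emission step + max(1, round(delay/dt))), and the buffers swap.
# The first recorded row is the initial state at t = 0.

#' Apply due spike events to the read-side flag tables
#'
#' Executes all due event deliveries in their fixed (source neuron, synapse
#' entry) order by incrementing the pending-count flag of each target
#' synapse entry. Kernels consume the flags during the step and clear them
#' in the write buffer.
#'
#' @param ts table set.
#' @param events list of deliveries, each `list(tbl, off)` (flag table
#'   binding base name and 1-based offset).
#' @return invisibly the number of applied deliveries.
#' @export
apply_events <- function(ts, events) {
  if (is.null(events) || length(events) == 0L) return(invisible(0L))
  for (ev in events) {
    nm <- paste0(ev$tbl, "A")
    v <- ts[[nm]]
    v[ev$off] <- v[ev$off] + 1
    ts[[nm]] <- v
  }
  invisible(length(events))
}

#' @keywords internal
#' Resolve the probe list of a simulation spec against a table set.
#' Returns list of list(binding, off) in output-file order.
fb_resolve_probes <- function(ts, spec) {
  probes <- list()
  for (of in spec$output_files) {
    for (p in of$probes) {
      pp <- fb_parse_probe(p)
      ref <- fb_resolve_path(ts, pp$population, pp$index, pp$segment, pp$var)
      u <- unpack_ref(ref)
      m <- ts$meta[[as.character(u$serial)]]
      probes[[length(probes) + 1L]] <- list(binding = m$binding,
                                            off = u$offset + 1L, path = p)
    }
  }
  probes
}

#' @keywords internal
#' Event-selection sources resolved to global item indices, per event file.
fb_resolve_event_sources <- function(ts, spec) {
  an <- ts$analysis
  lapply(spec$event_files, function(ef) {
    vapply(ef$sources, function(s) {
      ep <- fb_parse_endpoint(s)
      an$plan$pop_offset[[ep$population]] + ep$index
    }, numeric(1))
  })
}

#' @keywords internal
#' One engine step over the given items. `pending_env` holds future event
#' deliveries keyed by step. Returns nothing; mutates ts.
fb_engine_step <- function(ts, kernels, step, dt, items_order, pending_env,
                           steps_total) {
  t <- step * dt
  apply_events(ts, get0(as.character(step), envir = pending_env))
  if (!is.null(get0(as.character(step), envir = pending_env))) {
    rm(list = as.character(step), envir = pending_env)
  }
  for (i in items_order) {
    it <- ts$items[[i]]
    kernels[[it$type]](ts, it, t, dt, step)
  }
  if (!ts$fp64) fb_round_state_tables(ts, side = "B")
  if (any(!is.finite(ts$T2B))) {
    bad <- which(!is.finite(ts$T2B))[1]
    fb_abort("NumericalBlowup", sprintf(
      "non-finite state at step %d (f32 state slot %d)", step, bad))
  }
  invisible(NULL)
}

#' @keywords internal
#' Scan write-side spike flags in neuron order; schedule local deliveries and
#' return the global indices of items that fired.
fb_scan_spikes <- function(ts, step, dt, pending_env, steps_total) {
  fired <- integer(0)
  for (i in seq_along(ts$items)) {
    it <- ts$items[[i]]
    if (is.null(it)) next
    if (ts$T4B[it$si + 1L] > 0) {
      fired <- c(fired, it$idx)
      for (r in ts$routing[[it$idx + 1L]]) {
        a <- step + max(1L, as.integer(round(r$delay / dt)))
        if (a < steps_total) {
          key <- as.character(a)
          cur <- get0(key, envir = pending_env)
          assign(key, c(cur, list(list(tbl = r$tbl, off = r$off))),
                 envir = pending_env)
        }
      }
    }
  }
  fired
}

#' Run a simulation
#'
#' Executes `round(duration/dt)` time steps of the model under the given
#' simulation spec and returns the recording: a time axis (the initial state
#' at t = 0 plus one row per step), the probed waveforms, and the spike
#' events of the selected sources. Identical (model, spec, seed, workers)
#' inputs produce bitwise-identical recordings.
#'
#' @param model a `model_document` (or the list returned by
#'   [load_simulation()], in which case `spec` is taken from it).
#' @param spec a `simulation_spec`; optional if `model` carries one.
#' @param workers number of emulated workers; `workers > 1` delegates to
#'   [run_distributed()].
#' @param fp64 keep state in double precision (default FALSE: f32 state,
#'   f64 time, matching the engine's mixed-precision design).
#' @param K flattening threshold for neuron-signature generation.
#' @param exec_order optional permutation of work items (1-based positions)
#'   used to demonstrate order-independence of a step; results do not depend
#'   on it.
#' @return an `fb_recording`: list with `time`, `waveforms` (matrix),
#'   `events` (data.frame `file`, `source`, `time`), `spikes` (data.frame
#'   `neuron`, `step`, `time`), `probe_paths`.
#' @export
run_simulation <- function(model, spec = NULL, workers = 1L, fp64 = FALSE,
                           K = 8L, exec_order = NULL) {
  if (is.list(model) && !inherits(model, "model_document") &&
      !is.null(model$model)) {
    spec <- model$spec; model <- model$model
  }
  if (is.null(spec)) spec <- attr(model, "simulation")
  if (is.null(spec)) fb_abort("MissingSimulation", "no simulation spec given")
  if (workers > 1L) {
    return(run_distributed(model, spec, workers = workers, fp64 = fp64, K = K))
  }
  an <- fb_analyze(model, network = spec$target, K = K)
  ts <- allocate_tables(an, seed = spec$seed, fp64 = fp64)
  kernels <- list()
  for (tid in names(an$types)) {
    kernels[[tid]] <- load_kernel(emit_kernel(an, tid))
  }
  fb_run_loop(ts, kernels, spec, exec_order = exec_order)
}

#' @keywords internal
fb_run_loop <- function(ts, kernels, spec, exec_order = NULL) {
  dt <- spec$dt
  steps <- as.integer(round(spec$duration / dt))
  probes <- fb_resolve_probes(ts, spec)
  ev_sources <- fb_resolve_event_sources(ts, spec)
  items_order <- which(!vapply(ts$items, is.null, logical(1)))
  if (!is.null(exec_order)) items_order <- items_order[exec_order]
  pending <- new.env(parent = emptyenv())

  np <- length(probes)
  wf <- matrix(0, nrow = steps + 1L, ncol = np)
  time <- (0:steps) * dt
  read_probes <- function(side) {
    vapply(probes, function(p) ts[[paste0(p$binding, side)]][p$off],
           numeric(1))
  }
  if (np > 0L) wf[1L, ] <- read_probes("A")
  spikes_n <- integer(0); spikes_s <- integer(0)
  ev_file <- integer(0); ev_src <- integer(0); ev_t <- double(0)

  for (k in 0:(steps - 1L)) {
    fb_engine_step(ts, kernels, k, dt, items_order, pending, steps)
    fired <- fb_scan_spikes(ts, k, dt, pending, steps)
    if (length(fired) > 0L) {
      spikes_n <- c(spikes_n, fired)
      spikes_s <- c(spikes_s, rep.int(k + 1L, length(fired)))
      for (fi in seq_along(ev_sources)) {
        hit <- which(ev_sources[[fi]] %in% fired)
        if (length(hit) > 0L) {
          ev_file <- c(ev_file, rep.int(fi, length(hit)))
          ev_src <- c(ev_src, hit - 1L)
          ev_t <- c(ev_t, rep.int((k + 1L) * dt, length(hit)))
        }
      }
    }
    if (np > 0L) wf[k + 2L, ] <- read_probes("B")
    fb_swap_buffers(ts)
  }
  structure(list(
    time = time,
    waveforms = wf,
    events = data.frame(file = ev_file, source = ev_src, time = ev_t),
    spikes = data.frame(neuron = spikes_n, step = spikes_s,
                        time = spikes_s * dt),
    probe_paths = vapply(probes, `[[`, character(1), "path"),
    dt = dt, steps = steps
  ), class = "fb_recording")
}

#' @keywords internal
#' Binding-name pairs of all double-buffered tables, cached on the table set.
fb_state_pairs <- function(ts) {
  if (!is.null(ts$state_pairs)) return(ts$state_pairs)
  pairs <- list()
  for (s in names(ts$meta)) {
    m <- ts$meta[[s]]
    if (m$mut == "state") {
      a <- paste0(m$binding, "A")
      if (!is.null(ts[[a]])) {
        pairs[[length(pairs) + 1L]] <- c(a, paste0(m$binding, "B"),
                                         m$type)
      }
    }
  }
  ts$state_pairs <- pairs
  pairs
}

#' @keywords internal
fb_swap_buffers <- function(ts) {
  for (p in fb_state_pairs(ts)) {
    tmp <- ts[[p[1]]]; ts[[p[1]]] <- ts[[p[2]]]; ts[[p[2]]] <- tmp
  }
  invisible(ts)
}
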