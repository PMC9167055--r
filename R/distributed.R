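# Emulated multi-worker simulation.
#
# Neurons are split into contiguous ranges, one per worker; each worker
# instantiates only its own range. Cross-worker data dependencies are
# gathered as symbolic send lists (population, instance, segment,
# fractionAlong, payload kind), exchanged over an in-process request/ack
# protocol, and realized as mirror buffers (for graded dependencies such as
# gap-junction peer voltages) and spike-recipient structures (for event
# synapses). At run time each step begins by packing one framed message per
# communicating pair — a fixed-size part with the requested state values and
# a variable-size part with the indices of newly fired event sources —
# delivering it, and unpacking into mirrors and pending events before any
# kernel runs. Because messages only relocate reads of previous-step values,
# recordings are bitwise-identical to the single-worker run for every worker
# count.

#' Partition neurons over workers
#'
#' Contiguous ranges covering 0..N, sizes differing by at most one; the
#' first `N %% W` ranges get the extra neuron.
#'
#' @param N neuron count (>= 0).
#' @param W worker count (>= 1).
#' @return list of `c(lo, hi)` half-open 0-based ranges, one per worker.
#' @export
partition_neurons <- function(N, W) {
  stopifnot(N >= 0, W >= 1)
  base <- as.integer(N) %/% as.integer(W)
  extra <- as.integer(N) %% as.integer(W)
  out <- vector("list", W)
  lo <- 0L
  for (w in seq_len(W)) {
    size <- base + as.integer(w <= extra)
    out[[w]] <- c(lo, lo + size)
    lo <- lo + size
  }
  out
}

#' @keywords internal
fb_owner_of <- function(part, idx) {
  for (w in seq_along(part)) {
    if (idx >= part[[w]][1] && idx < part[[w]][2]) return(w)
  }
  NA_integer_
}

#' @keywords internal
#' Canonical ordering of symbolic send-list entries: lexicographic by
#' (population, instance, segment, payload). Defines wire indices.
fb_normalize_entries <- function(entries) {
  if (length(entries) == 0L) return(list())
  keys <- vapply(entries, function(e) {
    sprintf("%s|%012d|%012d|%s", e$population, e$instance, e$segment, e$payload)
  }, character(1))
  uk <- sort(unique(keys))
  lapply(uk, function(k) {
    e <- entries[[match(k, keys)]]
    list(population = e$population, instance = e$instance,
         segment = e$segment, fraction = e$fraction, payload = e$payload)
  })
}

#' Build the symbolic send lists of one worker
#'
#' Scans the network's connection lists under the four-case rule: purely
#' local connections are ignored here (they are instantiated normally),
#' purely remote ones are skipped, and any connection whose local side needs
#' remote information adds that remote location — (population, instance,
#' segment, fractionAlong, payload kind) — to the send list addressed to the
#' owning peer. Event synapses request the remote spike port; gap junctions
#' request the remote membrane voltage (both directions).
#'
#' @param analysis analysis object (or `model_document`).
#' @param part partition from [partition_neurons()].
#' @param worker 1-based worker id.
#' @return named list: peer id (as character) -> list of unique, ordered
#'   symbolic entries.
#' @export
build_send_lists <- function(analysis, part, worker) {
  if (inherits(analysis, "model_document")) analysis <- fb_analyze(analysis)
  an <- analysis
  net <- an$net
  po <- an$plan$pop_offset
  rng <- part[[worker]]
  is_local <- function(idx) idx >= rng[1] && idx < rng[2]
  needs <- list()
  note <- function(owner_idx, entry) {
    peer <- fb_owner_of(part, owner_idx)
    key <- as.character(peer)
    needs[[key]] <<- c(needs[[key]], list(entry))
  }
  for (pr in net$projections) {
    pre0 <- po[[pr$presynaptic]]; post0 <- po[[pr$postsynaptic]]
    cd <- pr$connections
    for (k in seq_len(nrow(cd))) {
      src <- pre0 + cd$pre_cell[k]; dst <- post0 + cd$post_cell[k]
      if (is_local(dst) && !is_local(src)) {
        note(src, list(population = pr$presynaptic,
                       instance = cd$pre_cell[k],
                       segment = cd$pre_segment[k],
                       fraction = cd$pre_fraction[k], payload = "spike"))
      }
    }
  }
  for (pr in net$electrical_projections) {
    pre0 <- po[[pr$presynaptic]]; post0 <- po[[pr$postsynaptic]]
    cd <- pr$connections
    for (k in seq_len(nrow(cd))) {
      a_idx <- pre0 + cd$pre_cell[k]; b_idx <- post0 + cd$post_cell[k]
      if (is_local(a_idx) && !is_local(b_idx)) {
        note(b_idx, list(population = pr$postsynaptic,
                         instance = cd$post_cell[k],
                         segment = cd$post_segment[k],
                         fraction = cd$post_fraction[k], payload = "v"))
      }
      if (is_local(b_idx) && !is_local(a_idx)) {
        note(a_idx, list(population = pr$presynaptic,
                         instance = cd$pre_cell[k],
                         segment = cd$pre_segment[k],
                         fraction = cd$pre_fraction[k], payload = "v"))
      }
    }
  }
  lapply(needs, fb_normalize_entries)
}

#' Exchange send lists between workers (request/ack protocol)
#'
#' Emulates the setup-time protocol over an in-process transport: each
#' worker sends one request per peer it needs data from, carrying its send
#' list; the peer acknowledges; workers poll until every request has been
#' acknowledged. Workers with no mutual dependency exchange nothing.
#'
#' @param send_lists per-worker result of [build_send_lists()] (a list of
#'   length W).
#' @param max_rounds deadlock guard; exceeded rounds raise `Timeout`.
#' @return list with `out` (per sender: requester id -> entries it must
#'   serve), `requests`, `acks` (message counts).
#' @export
exchange_send_lists <- function(send_lists, max_rounds = 1000L) {
  W <- length(send_lists)
  inbox <- lapply(seq_len(W), function(i) list())
  out <- lapply(seq_len(W), function(i) list())
  awaiting <- integer(W)
  requests <- 0L; acks <- 0L
  # post all requests
  for (w in seq_len(W)) {
    for (peer in names(send_lists[[w]])) {
      if (length(send_lists[[w]][[peer]]) == 0L) next
      p <- as.integer(peer)
      inbox[[p]] <- c(inbox[[p]], list(list(kind = "req", from = w,
                                            entries = send_lists[[w]][[peer]])))
      awaiting[w] <- awaiting[w] + 1L
      requests <- requests + 1L
    }
  }
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds) fb_abort("Timeout", "send-list exchange stalled")
    progressed <- FALSE
    for (w in seq_len(W)) {
      while (length(inbox[[w]]) > 0L) {
        msg <- inbox[[w]][[1]]
        inbox[[w]] <- inbox[[w]][-1]
        progressed <- TRUE
        if (msg$kind == "req") {
          out[[w]][[as.character(msg$from)]] <- msg$entries
          inbox[[msg$from]] <- c(inbox[[msg$from]],
                                 list(list(kind = "ack", from = w)))
          acks <- acks + 1L
        } else {
          awaiting[w] <- awaiting[w] - 1L
        }
      }
    }
    # completion poll: all acknowledgements received everywhere
    if (all(awaiting == 0L) && all(vapply(inbox, length, integer(1)) == 0L)) {
      break
    }
    if (!progressed) fb_abort("Timeout", "send-list exchange made no progress")
  }
  list(out = out, requests = requests, acks = acks)
}

#' Install mirror buffers for incoming remote state
#'
#' Allocates one mirror (double-buffered f32 state) table per sending peer,
#' sized by the number of graded entries in the send list addressed to that
#' peer, and resolves the tracked sentinel references of the local synapse
#' instances to the mirror slots. Raises `DanglingSentinel` if any tracked
#' reference is left unresolved.
#'
#' @param ts the worker's table set.
#' @param incoming named list: peer id -> normalized symbolic entries this
#'   worker requested from the peer.
#' @return named list: peer id -> list(binding, serial, n_graded,
#'   graded_keys) describing the mirror layout.
#' @export
install_mirrors <- function(ts, incoming) {
  # index the tracked sentinel cells by symbolic location
  tracked <- list()
  for (owner in names(ts$remote_needs)) {
    for (e in ts$remote_needs[[owner]]) {
      key <- sprintf("%s|%012d|%012d|%s", e$population, e$instance,
                     e$segment, e$payload)
      tracked[[key]] <- c(tracked[[key]], list(e))
    }
  }
  mirrors <- list()
  for (peer in names(incoming)) {
    entries <- incoming[[peer]]
    graded <- Filter(function(e) e$payload != "spike", entries)
    recip <- list()
    s <- ts$next_serial; ts$next_serial <- s + 1
    binding <- paste0("T", s)
    ts[[paste0(binding, "A")]] <- numeric(length(graded))
    ts[[paste0(binding, "B")]] <- numeric(length(graded))
    ts$meta[[as.character(s)]] <- list(serial = s, binding = binding,
                                       type = "f32", mut = "state",
                                       owner = sprintf("mirror from peer %s", peer),
                                       role = "mirror")
    ts$state_pairs <- NULL  # invalidate the swap cache
    gi <- 0L
    ev_recips <- list()
    ei <- 0L
    for (e in entries) {
      key <- sprintf("%s|%012d|%012d|%s", e$population, e$instance,
                     e$segment, e$payload)
      if (e$payload == "spike") {
        ei <- ei + 1L
        ev_recips[[ei]] <- lapply(tracked[[key]], function(tr) {
          list(tbl = tr$tbl, off = tr$off, delay = tr$delay)
        })
      } else {
        gi <- gi + 1L
        mref <- pack_ref(s, gi - 1L)
        for (tr in tracked[[key]]) {
          col <- ts[[tr$tbl]]
          if (col[tr$off] != fb_sentinel_ref()) {
            fb_abort("DanglingSentinel",
                     "tracked reference already resolved or corrupted")
          }
          col[tr$off] <- mref
          ts[[tr$tbl]] <- col
        }
      }
      tracked[[key]] <- NULL
    }
    mirrors[[peer]] <- list(binding = binding, serial = s,
                            n_graded = length(graded),
                            event_recipients = ev_recips)
  }
  # every tracked sentinel must have been resolved by some peer's mirror
  for (key in names(tracked)) {
    if (!is.null(tracked[[key]]) &&
        any(vapply(tracked[[key]], function(e) e$payload != "spike", logical(1)))) {
      fb_abort("DanglingSentinel",
               sprintf("no mirror resolves tracked location %s", key))
    }
  }
  mirrors
}

#' Pack a per-step message
#'
#' Frames the per-step data for one receiving peer: a u32 header with the
#' payload byte length, a fixed-size part with the requested state values in
#' send-list order, and a variable-size part with the (strictly increasing,
#' 0-based) indices of the event entries that fired. Little-endian
#' throughout.
#'
#' @param values numeric vector of continuous values.
#' @param fired integer vector of fired event-entry indices.
#' @param size bytes per continuous value (4 = f32 wire format; the runtime
#'   uses 8 in double-precision mode so that mirrored values keep working
#'   precision).
#' @return a raw vector (header + payload).
#' @export
pack_message <- function(values, fired, size = 4L) {
  payload <- c(
    writeBin(as.numeric(values), raw(), size = size, endian = "little"),
    writeBin(as.integer(fired), raw(), size = 4L, endian = "little"))
  c(writeBin(length(payload), raw(), size = 4L, endian = "little"), payload)
}

#' Unpack a per-step message
#'
#' @param msg raw vector from [pack_message()].
#' @param n_continuous number of continuous entries expected.
#' @param n_event_entries number of declared event entries (fired indices
#'   must be < this).
#' @param size bytes per continuous value (match the packer).
#' @return list with `values` and `fired`.
#' @export
unpack_message <- function(msg, n_continuous, n_event_entries = Inf,
                           size = 4L) {
  if (length(msg) < 4L) fb_abort("FrameLengthMismatch", "short header")
  plen <- readBin(msg[1:4], "integer", size = 4L, endian = "little")
  if (length(msg) != 4L + plen) {
    fb_abort("FrameLengthMismatch", sprintf(
      "header says %d payload bytes, got %d", plen, length(msg) - 4L))
  }
  nv_bytes <- n_continuous * size
  if (plen < nv_bytes || (plen - nv_bytes) %% 4L != 0L) {
    fb_abort("FrameLengthMismatch", "payload does not match declared layout")
  }
  values <- if (n_continuous > 0L)
    readBin(msg[4L + seq_len(nv_bytes)], "numeric", n = n_continuous,
            size = size, endian = "little")
  else numeric(0)
  nf <- (plen - nv_bytes) %/% 4L
  fired <- if (nf > 0L)
    readBin(msg[4L + nv_bytes + seq_len(4L * nf)], "integer", n = nf,
            size = 4L, endian = "little")
  else integer(0)
  if (any(diff(fired) <= 0L) || any(fired < 0L) ||
      any(fired >= n_event_entries)) {
    fb_abort("FrameLengthMismatch", "fired indices invalid")
  }
  list(values = values, fired = fired)
}

#' Run a simulation over emulated workers
#'
#' Partitions the network, instantiates each worker's share, exchanges send
#' lists, installs mirrors, and runs the time loop with per-step framed
#' messaging. The merged recording is bitwise-identical to
#' `run_simulation(..., workers = 1)` for every worker count: communication
#' only relocates reads of previous-step values.
#'
#' @param model a `model_document` (fixtures carry their spec).
#' @param spec a `simulation_spec`.
#' @param workers worker count W >= 1.
#' @param fp64 double-precision state (also widens the message wire format
#'   to f64 so mirrors keep working precision).
#' @param K flattening threshold.
#' @return an `fb_recording`.
#' @export
run_distributed <- function(model, spec = NULL, workers = 2L, fp64 = FALSE,
                            K = 8L) {
  if (is.null(spec)) spec <- attr(model, "simulation")
  if (is.null(spec)) fb_abort("MissingSimulation", "no simulation spec given")
  an <- fb_analyze(model, network = spec$target, K = K)
  N <- nrow(an$plan$work_items)
  W <- as.integer(workers)
  part <- partition_neurons(N, W)
  dt <- spec$dt
  steps <- as.integer(round(spec$duration / dt))
  wire <- if (fp64) 8L else 4L

  kernels <- list()
  for (tid in names(an$types)) kernels[[tid]] <- load_kernel(emit_kernel(an, tid))

  wks <- vector("list", W)
  for (w in seq_len(W)) {
    rng <- part[[w]]
    items <- if (rng[2] > rng[1]) rng[1]:(rng[2] - 1L) else integer(0)
    ts <- allocate_tables(an, seed = spec$seed, fp64 = fp64, items = items)
    wks[[w]] <- list(id = w, range = rng, ts = ts,
                     pending = new.env(parent = emptyenv()))
  }

  # symbolic send lists + exchange + mirrors
  send_lists <- lapply(seq_len(W), function(w) build_send_lists(an, part, w))
  ex <- exchange_send_lists(send_lists)
  # sender-side resolution: what worker w must send to requester r
  for (w in seq_len(W)) {
    outgoing <- list()
    for (r in names(ex$out[[w]])) {
      entries <- ex$out[[w]][[r]]
      graded_refs <- numeric(0)
      ev_items <- numeric(0)
      for (e in entries) {
        if (e$payload == "spike") {
          ev_items <- c(ev_items,
                        an$plan$pop_offset[[e$population]] + e$instance)
        } else {
          graded_refs <- c(graded_refs,
                           fb_resolve_path(wks[[w]]$ts, e$population,
                                           e$instance, e$segment, "v"))
        }
      }
      outgoing[[r]] <- list(graded_refs = graded_refs, ev_items = ev_items)
    }
    wks[[w]]$outgoing <- outgoing
  }
  for (w in seq_len(W)) {
    wks[[w]]$mirrors <- install_mirrors(wks[[w]]$ts, send_lists[[w]])
  }

  # probes and event sources, with owners
  probes <- list()
  for (of in spec$output_files) {
    for (pstr in of$probes) {
      pp <- fb_parse_probe(pstr)
      gidx <- an$plan$pop_offset[[pp$population]] + pp$index
      w <- fb_owner_of(part, gidx)
      ref <- fb_resolve_path(wks[[w]]$ts, pp$population, pp$index,
                             pp$segment, pp$var)
      u <- unpack_ref(ref)
      m <- wks[[w]]$ts$meta[[as.character(u$serial)]]
      probes[[length(probes) + 1L]] <- list(worker = w, binding = m$binding,
                                            off = u$offset + 1L, path = pstr)
    }
  }
  ev_sources <- lapply(spec$event_files, function(ef) {
    vapply(ef$sources, function(s) {
      ep <- fb_parse_endpoint(s)
      an$plan$pop_offset[[ep$population]] + ep$index
    }, numeric(1))
  })

  np <- length(probes)
  wf <- matrix(0, nrow = steps + 1L, ncol = np)
  time <- (0:steps) * dt
  read_probe <- function(p, side) {
    wks[[p$worker]]$ts[[paste0(p$binding, side)]][p$off]
  }
  if (np > 0L) wf[1L, ] <- vapply(probes, read_probe, numeric(1), side = "A")

  spike_item <- function(ts, gidx) ts$items[[gidx + 1L]]
  fired_by_step <- vector("list", steps)

  for (k in 0:(steps - 1L)) {
    # 1. pack and deliver messages (values and spikes of the previous step)
    if (W > 1L) {
      for (w in seq_len(W)) {
        tsw <- wks[[w]]$ts
        for (r in names(wks[[w]]$outgoing)) {
          og <- wks[[w]]$outgoing[[r]]
          values <- if (length(og$graded_refs) > 0L)
            fb_deref(tsw, og$graded_refs, "A") else numeric(0)
          fired <- integer(0)
          if (length(og$ev_items) > 0L) {
            sp <- vapply(og$ev_items, function(gi) {
              it <- spike_item(tsw, gi)
              tsw$T4A[it$si + 1L] > 0
            }, logical(1))
            fired <- which(sp) - 1L
          }
          msg <- pack_message(values, fired, size = wire)
          # 2. receiver unpacks into mirrors and pending events
          rw <- as.integer(r)
          mir <- wks[[rw]]$mirrors[[as.character(w)]]
          up <- unpack_message(msg, n_continuous = length(values),
                               n_event_entries = length(mir$event_recipients),
                               size = wire)
          if (mir$n_graded > 0L) {
            wks[[rw]]$ts[[paste0(mir$binding, "A")]] <- up$values
          }
          for (fi in up$fired) {
            for (tr in mir$event_recipients[[fi + 1L]]) {
              a <- (k - 1L) + max(1L, as.integer(round(tr$delay / dt)))
              if (a >= k && a < steps) {
                ky <- as.character(a)
                pend <- wks[[rw]]$pending
                assign(ky, c(get0(ky, envir = pend),
                             list(list(tbl = tr$tbl, off = tr$off))),
                       envir = pend)
              }
            }
          }
        }
      }
    }
    # 3. compute: all workers advance their own items
    step_fired <- integer(0)
    for (w in seq_len(W)) {
      tsw <- wks[[w]]$ts
      items_order <- which(!vapply(tsw$items, is.null, logical(1)))
      fb_engine_step(tsw, kernels, k, dt, items_order, wks[[w]]$pending, steps)
      step_fired <- c(step_fired, fb_scan_spikes(tsw, k, dt, wks[[w]]$pending,
                                                 steps))
    }
    fired_by_step[[k + 1L]] <- step_fired  # worker order = ascending ranges
    if (np > 0L) wf[k + 2L, ] <- vapply(probes, read_probe, numeric(1),
                                        side = "B")
    for (w in seq_len(W)) fb_swap_buffers(wks[[w]]$ts)
  }

  # merge spikes/events exactly as the single-worker loop records them
  spikes_n <- integer(0); spikes_s <- integer(0)
  ev_file <- integer(0); ev_src <- integer(0); ev_t <- double(0)
  for (k in 0:(steps - 1L)) {
    fired <- fired_by_step[[k + 1L]]
    if (length(fired) == 0L) next
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
  structure(list(
    time = time, waveforms = wf,
    events = data.frame(file = ev_file, source = ev_src, time = ev_t),
    spikes = data.frame(neuron = spikes_n, step = spikes_s,
                        time = spikes_s * dt),
    probe_paths = vapply(probes, `[[`, character(1), "path"),
    dt = dt, steps = steps
  ), class = "fb_recording")
}
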