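# Flat state tables and table-offset references.
#
# All instantiated model data live in one-dimensional arrays ("tables")
# grouped by numeric type (f32/f64/i64) and mutability (const/state); state
# tables exist in two buffers A (read) and B (write) that the engine swaps
# after every step. Scalar variables of every work item live in contiguous
# slices of the type-reserved tables (serials 1-5); the variable-sized
# synapse/input populations of a work item get one table per (kind, column),
# extended by one entry per instantiated connection. Any value is addressable
# by a packed (table serial, offset) reference.
#
# Table serials: 1 = f32 const, 2 = f32 state, 3 = i64 const, 4 = i64 state,
# 5 = f64 const; per-item kind tables take serials 6 upwards in work-item
# order. The in-memory binding of serial s is `T<s>` (const) or `T<s>A` /
# `T<s>B` (state buffers).

.FB_SENTINEL_SERIAL <- 2^31 - 1

#' Pack a table-offset reference
#'
#' Encodes (serial, offset) into one number: serial in the bits at and above
#' 32, offset in the low 32 bits. The packing must be exactly representable
#' in a double (this holds for all serials below 2^21 with arbitrary offsets,
#' and for the sentinel serial 2^31-1 with offset 0); a non-representable
#' combination or an offset at or above 2^32 raises `OffsetOverflow`.
#'
#' @param serial table serial number (0 <= serial < 2^31).
#' @param offset 0-based element offset (0 <= offset < 2^32).
#' @return packed reference (double).
#' @export
pack_ref <- function(serial, offset) {
  if (any(offset < 0 | offset >= 2^32)) {
    fb_abort("OffsetOverflow", "offset outside [0, 2^32)")
  }
  if (any(serial < 0 | serial >= 2^31)) {
    fb_abort("OffsetOverflow", "serial outside [0, 2^31)")
  }
  r <- serial * 2^32 + offset
  u <- unpack_ref(r)
  if (any(u$serial != serial) || any(u$offset != offset)) {
    fb_abort("OffsetOverflow",
             "(serial, offset) not exactly representable in a double")
  }
  r
}

#' Unpack a table-offset reference
#'
#' @param ref packed reference from [pack_ref()].
#' @return list with `serial` and `offset`.
#' @export
unpack_ref <- function(ref) {
  serial <- floor(ref / 2^32)
  list(serial = serial, offset = ref - serial * 2^32)
}

#' @keywords internal
fb_sentinel_ref <- function() pack_ref(.FB_SENTINEL_SERIAL, 0)

#' @keywords internal
#' Dereference packed refs against the read (A) buffers. Traps on the
#' sentinel when the table set was allocated in debug mode.
fb_deref <- function(TS, refs, side = "A") {
  serial <- floor(refs / 2^32)
  off <- refs - serial * 2^32
  out <- numeric(length(refs))
  for (s in unique(serial)) {
    if (s == .FB_SENTINEL_SERIAL) {
      if (isTRUE(TS$debug_sentinel)) {
        fb_abort("DanglingSentinel", "read of an unresolved sentinel reference")
      }
      out[serial == s] <- 0
      next
    }
    m <- TS$meta[[as.character(s)]]
    nm <- if (m$mut == "state") paste0(m$binding, side) else m$binding
    sel <- serial == s
    out[sel] <- TS[[nm]][off[sel] + 1L]
  }
  out
}

#' Redirect stored table-offset references
#'
#' Rewrites every stored reference equal to a key of `mapping` to the mapped
#' value, across all reference-bearing tables. Kernel code is unchanged:
#' only the instantiated data move.
#'
#' @param ts a table set from [allocate_tables()].
#' @param mapping named numeric vector: names are `format(old_ref, digits=22)`
#'   keys produced by [pack_ref()]; simplest is to pass
#'   `stats::setNames(new_refs, as.character(old_refs))`.
#' @return invisibly, the number of rewritten entries.
#' @export
redirect_refs <- function(ts, mapping) {
  if (length(mapping) == 0L) return(invisible(0L))
  old <- as.numeric(names(mapping))
  nrw <- 0L
  for (s in names(ts$meta)) {
    m <- ts$meta[[s]]
    if (!identical(m$role, "ref")) next
    v <- ts[[m$binding]]
    idx <- match(v, old)
    hit <- !is.na(idx)
    if (any(hit)) {
      v[hit] <- unname(mapping[idx[hit]])
      ts[[m$binding]] <- v
      nrw <- nrw + sum(hit)
    }
  }
  invisible(nrw)
}

# ---------------------------------------------------------------------------
# layout and allocation
# ---------------------------------------------------------------------------

#' @keywords internal
#' Per-type scalar layout: 0-based offsets within each work item's slices of
#' the f32 const (cf), f32 state (sf) and i64 state (si) tables.
fb_layout_type <- function(tp, doc) {
  if (tp$kind == "point") {
    sig <- tp$comp_sigs[[1]]
    cf <- stats::setNames(seq_along(sig$constants) - 1L,
                          vapply(sig$constants, `[[`, character(1), "name"))
    sf <- stats::setNames(seq_along(sig$states) - 1L,
                          vapply(sig$states, `[[`, character(1), "name"))
    return(list(cf_len = length(cf), sf_len = length(sf), si_len = 1L,
                point_cf = cf, point_sf = sf, groups = NULL))
  }
  cfo <- 1L  # slot 0 = spike threshold
  sfo <- 0L
  groups <- list()
  for (gi in seq_along(tp$groups)) {
    n <- length(tp$groups[[gi]]$members)
    cfl <- list(C = cfo, ga = cfo + n); cfo <- cfo + 2L * n
    sfl <- list(v = sfo); sfo <- sfo + n
    c0 <- tp$comps[[tp$groups[[gi]]$members[1] + 1L]]
    for (m in c0$mechanisms) {
      cfl[[paste0(m$id, "_gbar")]] <- cfo; cfo <- cfo + n
      cfl[[paste0(m$id, "_erev")]] <- cfo; cfo <- cfo + n
      for (g in names(doc$ion_channels[[m$channel]]$gates)) {
        sfl[[paste0(m$id, "_", g)]] <- sfo; sfo <- sfo + n
      }
    }
    groups[[gi]] <- list(n = n, members = tp$groups[[gi]]$members,
                         cf = cfl, sf = sfl)
  }
  list(cf_len = cfo, sf_len = sfo, si_len = 1L, thresh_off = 0L,
       groups = groups)
}

#' @keywords internal
#' Column plan for a synapse/input kind: named list col -> type descriptor.
fb_kind_columns <- function(kind) {
  dyn <- kind$dynamics
  cols <- list()
  if (kind$role == "event") {
    cols$w <- list(type = "f32", mut = "const")
    cols$tc <- list(type = "i64", mut = "const")
    cols$dl <- list(type = "f64", mut = "const")
    for (s in names(dyn$state_vars)) {
      cols[[paste0("st_", s)]] <- list(type = "f32", mut = "state")
    }
    cols$fl <- list(type = "i64", mut = "state")
  } else if (kind$role == "gap") {
    cols$tc <- list(type = "i64", mut = "const")
    cols$ref <- list(type = "i64", mut = "const", role = "ref")
  } else if (kind$role == "pulse") {
    cols$tc <- list(type = "i64", mut = "const")
  } else if (kind$role == "poisson") {
    cols$tc <- list(type = "i64", mut = "const")
    cols$stream <- list(type = "i64", mut = "const")
    for (s in names(dyn$state_vars)) {
      cols[[paste0("st_", s)]] <- list(type = "f32", mut = "state")
    }
  }
  cols
}

#' Instantiate a model into flat tables
#'
#' Allocates the scalar slices and per-item kind tables for every work item
#' of the analysed network, fills constants and initial state (both state
#' buffers equal), instantiates all synapses, gap junctions and inputs, and
#' builds the instance map (symbolic probe path -> table reference) and the
#' spike-recipient routing used for event delivery.
#'
#' @param analysis result of the internal network analysis
#'   (`flatbrain:::fb_analyze`), or a `model_document` (analysed with
#'   defaults).
#' @param seed integer seed for the engine-owned RNG streams.
#' @param fp64 if TRUE state is kept in double precision; otherwise state is
#'   rounded to IEEE single precision after initialization and after every
#'   step.
#' @param items optional integer vector of global work-item indices to
#'   instantiate (0-based); defaults to all. Used by the distributed runtime,
#'   where each worker instantiates only its own contiguous range; synapse
#'   instantiation then follows the local/remote case analysis and leaves
#'   sentinel references for remote graded dependencies.
#' @return a table-set environment.
#' @export
allocate_tables <- function(analysis, seed = 12345L, fp64 = TRUE,
                            items = NULL) {
  if (inherits(analysis, "model_document")) analysis <- fb_analyze(analysis)
  an <- analysis
  wi <- an$plan$work_items
  N <- nrow(wi)
  local_set <- if (is.null(items)) seq_len(N) - 1L else as.integer(items)

  ts <- new.env(parent = emptyenv())
  ts$meta <- list()
  ts$seed <- as.integer(seed)
  ts$fp64 <- isTRUE(fp64)
  ts$debug_sentinel <- TRUE
  ts$analysis <- an
  ts$N <- N
  ts$local_items <- local_set

  layouts <- lapply(an$types, fb_layout_type, doc = an$doc)
  ts$layouts <- layouts

  reg_meta <- function(serial, binding, type, mut, owner, role = "data") {
    ts$meta[[as.character(serial)]] <- list(
      serial = serial, binding = binding, type = type, mut = mut,
      owner = owner, role = role)
  }

  # scalar tables: bases per local item
  cf_len <- 0L; sf_len <- 0L; si_len <- 0L
  items_rec <- vector("list", N)
  for (gidx in local_set) {
    row <- wi[wi$idx == gidx, ]
    lay <- layouts[[row$type]]
    items_rec[[gidx + 1L]] <- list(
      idx = gidx, type = row$type, pop = row$pop, inst = row$inst,
      cf = cf_len, sf = sf_len, si = si_len,
      stream0 = fb_rng_stream(ts$seed, gidx, 0),
      k = list())
    cf_len <- cf_len + lay$cf_len
    sf_len <- sf_len + lay$sf_len
    si_len <- si_len + lay$si_len
  }
  ts$T1 <- numeric(cf_len)
  ts$T2A <- numeric(sf_len); ts$T2B <- numeric(sf_len)
  ts$T3 <- numeric(0)
  ts$T4A <- numeric(si_len); ts$T4B <- numeric(si_len)
  ts$T5 <- numeric(0)
  reg_meta(1, "T1", "f32", "const", "scalars")
  reg_meta(2, "T2", "f32", "state", "scalars")
  reg_meta(3, "T3", "i64", "const", "scalars")
  reg_meta(4, "T4", "i64", "state", "scalars")
  reg_meta(5, "T5", "f64", "const", "scalars")
  ts$next_serial <- 6

  # per-item kind tables (empty; extended per connection)
  for (gidx in local_set) {
    it <- items_rec[[gidx + 1L]]
    tp <- an$types[[it$type]]
    for (key in c(names(tp$syn_kinds), names(tp$input_kinds))) {
      kind <- tp$syn_kinds[[key]] %||% tp$input_kinds[[key]]
      cols <- fb_kind_columns(kind)
      krec <- list(n = 0L, cols = list())
      for (cn in names(cols)) {
        s <- ts$next_serial; ts$next_serial <- s + 1
        binding <- paste0("T", s)
        if (cols[[cn]]$mut == "state") {
          ts[[paste0(binding, "A")]] <- numeric(0)
          ts[[paste0(binding, "B")]] <- numeric(0)
        } else {
          ts[[binding]] <- numeric(0)
        }
        reg_meta(s, binding, cols[[cn]]$type, cols[[cn]]$mut,
                 sprintf("item %d %s %s", gidx, key, cn),
                 cols[[cn]]$role %||% "data")
        krec$cols[[cn]] <- list(serial = s, binding = binding,
                                mut = cols[[cn]]$mut)
      }
      it$k[[key]] <- krec
    }
    items_rec[[gidx + 1L]] <- it
  }
  ts$items <- items_rec

  fb_fill_scalars(ts, an)
  fb_instantiate_connections(ts, an)

  # both buffers equal after initialization; f32 rounding if not fp64
  if (!ts$fp64) fb_round_state_tables(ts)
  for (s in names(ts$meta)) {
    m <- ts$meta[[s]]
    if (m$mut == "state" && m$type %in% c("f32", "i64")) {
      ts[[paste0(m$binding, "B")]] <- ts[[paste0(m$binding, "A")]]
    }
  }
  ts
}

#' @keywords internal
#' Round all f32-typed state tables (given side) to IEEE single precision.
fb_round_state_tables <- function(ts, side = "A") {
  k <- if (side == "A") 1L else 2L
  for (p in fb_state_pairs(ts)) {
    if (p[3] == "f32") {
      ts[[p[k]]] <- fb_round_f32(ts[[p[k]]])
    }
  }
  invisible(ts)
}

#' @keywords internal
fb_round_f32 <- function(x) {
  if (length(x) == 0L) return(x)
  y <- readBin(writeBin(as.vector(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  names(y) <- names(x)
  y
}

#' @keywords internal
#' Fill constants and initial states for all local items.
fb_fill_scalars <- function(ts, an) {
  for (it in ts$items) {
    if (is.null(it)) next
    tp <- an$types[[it$type]]
    lay <- ts$layouts[[it$type]]
    if (tp$kind == "point") {
      sig <- tp$comp_sigs[[1]]
      env <- new.env(parent = fb_math_env())
      for (cst in sig$constants) {
        v <- cst$default
        if (is.na(v)) v <- 0
        ts$T1[it$cf + lay$point_cf[[cst$name]] + 1L] <- v
        assign(cst$name, v, envir = env)
      }
      for (st in sig$states) {
        v0 <- if (is.null(st$init)) 0 else eval(st$init, env)
        ts$T2A[it$sf + lay$point_sf[[st$name]] + 1L] <- v0
        assign(st$name, v0, envir = env)
      }
    } else {
      ts$T1[it$cf + lay$thresh_off + 1L] <- tp$thresh
      for (gi in seq_along(lay$groups)) {
        gl <- lay$groups[[gi]]
        mem <- gl$members
        for (pos in seq_along(mem)) {
          comp <- tp$comps[[mem[pos] + 1L]]
          ts$T1[it$cf + gl$cf$C + pos] <- comp$capacitance
          ts$T1[it$cf + gl$cf$ga + pos] <- comp$g_axial
          ts$T2A[it$sf + gl$sf$v + pos] <- tp$init_v
          for (m in comp$mechanisms) {
            ts$T1[it$cf + gl$cf[[paste0(m$id, "_gbar")]] + pos] <- m$gbar
            ts$T1[it$cf + gl$cf[[paste0(m$id, "_erev")]] + pos] <- m$erev
            ch <- an$doc$ion_channels[[m$channel]]
            for (g in ch$gates) {
              q0 <- fb_gate_steady_state(g, tp$init_v)
              ts$T2A[it$sf + gl$sf[[paste0(m$id, "_", g$name)]] + pos] <- q0
            }
          }
        }
      }
    }
  }
  invisible(ts)
}

#' @keywords internal
#' Steady-state value of a gate at voltage v0 (used for initialization).
fb_gate_steady_state <- function(gate, v0) {
  env <- new.env(parent = fb_math_env())
  assign("v", v0, envir = env)
  if (gate$form == "rates") {
    a <- eval(fb_rate_ast(gate$forward), env)
    b <- eval(fb_rate_ast(gate$reverse), env)
    tau <- 1 / (a + b)
    a * tau
  } else {
    eval(fb_rate_ast(gate$steadyState), env)
  }
}

#' @keywords internal
#' Parent environment for expression evaluation: the math helpers visible to
#' both generated kernels and the interpreter (cached; contents are static).
fb_math_env <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      e <- new.env(parent = baseenv())
      e$H <- H
      e$hh_explinear <- hh_explinear
      cached <<- e
    }
    cached
  }
})

# ---------------------------------------------------------------------------
# synapse / input instantiation
# ---------------------------------------------------------------------------

#' Append one entry to a work item's synapse/input tables
#'
#' Extends every column table of the (item, kind) pair by one entry: the
#' post-side mechanism's state columns start at their initial values, the
#' scalar properties (weight, delay, target compartment) come from the
#' connection with signature defaults where unspecified.
#'
#' @param ts table set.
#' @param item_idx global work-item index (0-based).
#' @param kind_key kind key (e.g. `"syn:ampa@g1"`).
#' @param values named list of column values (`w`, `tc`, `dl`, `ref`,
#'   `stream`, `st_*`, `fl`); missing columns default to 0 (weight to 1).
#' @return the 0-based entry index of the new entry.
#' @export
append_synapse_entry <- function(ts, item_idx, kind_key, values = list()) {
  it <- ts$items[[item_idx + 1L]]
  if (is.null(it)) {
    fb_abort("UnresolvedReference",
             sprintf("work item %d is not instantiated locally", item_idx))
  }
  krec <- it$k[[kind_key]]
  if (is.null(krec)) {
    fb_abort("UnresolvedReference", sprintf(
      "work item %d has no kind '%s'", item_idx, kind_key))
  }
  entry <- krec$n
  for (cn in names(krec$cols)) {
    col <- krec$cols[[cn]]
    val <- values[[cn]]
    if (is.null(val)) val <- if (cn == "w") 1.0 else 0.0
    if (col$mut == "state") {
      ts[[paste0(col$binding, "A")]] <- c(ts[[paste0(col$binding, "A")]], val)
      ts[[paste0(col$binding, "B")]] <- c(ts[[paste0(col$binding, "B")]], val)
    } else {
      ts[[col$binding]] <- c(ts[[col$binding]], val)
    }
  }
  krec$n <- entry + 1L
  it$k[[kind_key]] <- krec
  ts$items[[item_idx + 1L]] <- it
  entry
}

#' @keywords internal
#' Kind key of a synapse id on the group containing compartment `comp` of
#' type plan `tp`.
fb_kind_key_for <- function(tp, comp, kind, what = "syn") {
  for (gi in seq_along(tp$groups)) {
    if (comp %in% tp$groups[[gi]]$members) {
      return(paste0(what, ":", kind, "@g", gi))
    }
  }
  fb_abort("UnresolvedReference",
           sprintf("compartment %d not in any dedup group", comp))
}

#' @keywords internal
#' Packed ref to the voltage slot of (item, compartment).
fb_v_ref <- function(ts, item_idx, comp) {
  it <- ts$items[[item_idx + 1L]]
  lay <- ts$layouts[[it$type]]
  if (is.null(lay$groups)) {
    off <- it$sf + lay$point_sf[["v"]]
  } else {
    gi <- NA_integer_; pos <- NA_integer_
    for (g in seq_along(lay$groups)) {
      p <- match(comp, lay$groups[[g]]$members)
      if (!is.na(p)) { gi <- g; pos <- p; break }
    }
    off <- it$sf + lay$groups[[gi]]$sf$v + pos - 1L
  }
  pack_ref(2, off)
}

#' @keywords internal
#' Instantiate all synaptic connections, gap junctions and inputs for the
#' locally-held work items, following the local/remote case analysis. Fills
#' `ts$routing` (per source neuron: flag-slot refs and delays),
#' `ts$remote_needs` (symbolic send-list entries by owning item) and leaves
#' sentinel refs for remote graded (gap-junction) peers.
fb_instantiate_connections <- function(ts, an) {
  net <- an$net
  po <- an$plan$pop_offset
  is_local <- function(idx) !is.null(ts$items[[idx + 1L]])
  routing <- vector("list", ts$N)   # source idx+1 -> list of targets
  remote_needs <- list()            # key: owner idx; symbolic entries
  pending_gap <- list()             # sentinel fix-up records

  add_route <- function(src, tbl_binding, entry, delay) {
    r <- routing[[src + 1L]]
    routing[[src + 1L]] <<- c(r, list(list(tbl = tbl_binding, off = entry + 1L,
                                           delay = delay)))
  }
  note_need <- function(owner_idx, entry) {
    key <- as.character(owner_idx)
    remote_needs[[key]] <<- c(remote_needs[[key]], list(entry))
  }

  for (pr in net$projections) {
    pre0 <- po[[pr$presynaptic]]; post0 <- po[[pr$postsynaptic]]
    post_type <- net$populations[[pr$postsynaptic]]$component
    tp <- an$types[[post_type]]
    cd <- pr$connections
    for (k in seq_len(nrow(cd))) {
      src <- pre0 + cd$pre_cell[k]
      dst <- post0 + cd$post_cell[k]
      src_local <- is_local(src); dst_local <- is_local(dst)
      if (!dst_local) next  # remote post: peer instantiates (or skip)
      comp <- fb_comp_of_segment(an, post_type, cd$post_segment[k])
      key <- fb_kind_key_for(tp, comp, pr$synapse)
      entry <- append_synapse_entry(ts, dst, key, list(
        w = cd$weight[k], tc = comp, dl = cd$delay[k]))
      flb <- ts$items[[dst + 1L]]$k[[key]]$cols$fl$binding
      if (src_local) {
        add_route(src, flb, entry, cd$delay[k])
      } else {
        # remote pre: request the spike source from its owner
        note_need(src, list(kind = "event",
                            population = pr$presynaptic,
                            instance = cd$pre_cell[k],
                            segment = cd$pre_segment[k],
                            fraction = cd$pre_fraction[k],
                            payload = "spike",
                            tbl = flb, off = entry + 1L,
                            delay = cd$delay[k]))
      }
    }
  }

  for (pr in net$electrical_projections) {
    pre0 <- po[[pr$presynaptic]]; post0 <- po[[pr$postsynaptic]]
    pre_type <- net$populations[[pr$presynaptic]]$component
    post_type <- net$populations[[pr$postsynaptic]]$component
    cd <- pr$connections
    for (k in seq_len(nrow(cd))) {
      a_idx <- pre0 + cd$pre_cell[k]; b_idx <- post0 + cd$post_cell[k]
      sides <- list(
        list(own = a_idx, own_type = pre_type, own_comp_seg = cd$pre_segment[k],
             peer = b_idx, peer_type = post_type,
             peer_seg = cd$post_segment[k], peer_pop = pr$postsynaptic,
             peer_inst = cd$post_cell[k], peer_frac = cd$post_fraction[k]),
        list(own = b_idx, own_type = post_type, own_comp_seg = cd$post_segment[k],
             peer = a_idx, peer_type = pre_type,
             peer_seg = cd$pre_segment[k], peer_pop = pr$presynaptic,
             peer_inst = cd$pre_cell[k], peer_frac = cd$pre_fraction[k]))
      for (sd in sides) {
        if (!is_local(sd$own)) next
        own_tp <- an$types[[sd$own_type]]
        comp <- fb_comp_of_segment(an, sd$own_type, sd$own_comp_seg)
        key <- fb_kind_key_for(own_tp, comp, paste0("gap:", cd$synapse[k]))
        peer_comp <- fb_comp_of_segment(an, sd$peer_type, sd$peer_seg)
        if (is_local(sd$peer)) {
          ref <- fb_v_ref(ts, sd$peer, peer_comp)
          append_synapse_entry(ts, sd$own, key, list(tc = comp, ref = ref))
        } else {
          entry <- append_synapse_entry(ts, sd$own, key, list(
            tc = comp, ref = fb_sentinel_ref()))
          refb <- ts$items[[sd$own + 1L]]$k[[key]]$cols$ref$binding
          note_need(sd$peer, list(kind = "graded",
                                  population = sd$peer_pop,
                                  instance = sd$peer_inst,
                                  segment = sd$peer_seg,
                                  fraction = sd$peer_frac,
                                  payload = "v",
                                  tbl = refb, off = entry + 1L))
        }
      }
    }
  }

  for (il in net$input_lists) {
    base0 <- po[[il$population]]
    tid <- net$populations[[il$population]]$component
    tp <- an$types[[tid]]
    counters <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(il$inputs))) {
      dst <- base0 + il$inputs$target[k]
      # input instance index is counted per item across all of its inputs,
      # in document order, so RNG streams are stable under partitioning
      cnt_key <- as.character(dst)
      cnt <- (get0(cnt_key, envir = counters) %||% 0L) + 1L
      assign(cnt_key, cnt, envir = counters)
      if (!is_local(dst)) next
      comp <- fb_comp_of_segment(an, tid, il$inputs$segment[k])
      key <- fb_kind_key_for(tp, comp, il$component, what = "input")
      stream <- fb_rng_stream(ts$seed, dst, cnt)
      append_synapse_entry(ts, dst, key, list(tc = comp, stream = stream))
    }
  }

  ts$routing <- routing
  ts$remote_needs <- remote_needs
  invisible(ts)
}

#' @keywords internal
fb_comp_of_segment <- function(an, type_id, segment) {
  tp <- an$types[[type_id]]
  if (tp$kind == "point") return(0L)
  for (c in tp$comps) if (c$seg_id == segment) return(c$index)
  fb_abort("UnresolvedReference", sprintf(
    "segment %d not on type '%s'", segment, type_id))
}

#' @keywords internal
#' Resolve a symbolic path to a packed table ref (instance map lookup).
fb_resolve_path <- function(ts, population, instance, segment = 0L,
                            var = "v") {
  an <- ts$analysis
  idx <- an$plan$pop_offset[[population]] + instance
  it <- ts$items[[idx + 1L]]
  if (is.null(it)) {
    fb_abort("UnresolvedReference", sprintf(
      "item %s[%d] is not instantiated locally", population, instance))
  }
  lay <- ts$layouts[[it$type]]
  tp <- an$types[[it$type]]
  if (tp$kind == "point") {
    off <- lay$point_sf[[var]]
    if (is.null(off)) {
      fb_abort("UnresolvedProbePath", sprintf("no state '%s'", var))
    }
    return(pack_ref(2, it$sf + off))
  }
  comp <- fb_comp_of_segment(an, it$type, segment)
  if (var != "v") {
    fb_abort("UnresolvedProbePath",
             "only membrane voltage probes are supported on detailed cells")
  }
  fb_v_ref(ts, idx, comp)
}
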