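# Interpreted reference simulator.
#
# reference_simulate() advances the model by directly interpreting the
# parsed dynamics and compartment structures: no signatures, no flat tables,
# no generated code. It follows the same documented contracts as the engine
# — integrator tags (cnexp for HH gates, forward Euler elsewhere, backward
# Euler cable solve with frozen conductances), the per-step operation order,
# the (kind, entry) ordering of synaptic accumulation, the event arrival
# rule (emission step + max(1, round(delay/dt))) and the counter-based RNG
# streams — so that in double-precision mode its recording is expected to be
# bitwise equal to the engine's. The shared contracts are deliberate: they
# make bitwise equality a meaningful test of the signature/table/codegen
# machinery rather than of arithmetic choices.

#' Reference simulation by direct interpretation
#'
#' @param model a `model_document` (fixtures carry their spec as an
#'   attribute).
#' @param spec a `simulation_spec` (defaults to the model's attached spec).
#' @param fp64 double-precision state (TRUE) or f32-rounded state per step.
#' @return an `fb_recording`, directly comparable with [run_simulation()]'s.
#' @export
reference_simulate <- function(model, spec = NULL, fp64 = FALSE) {
  if (is.null(spec)) spec <- attr(model, "simulation")
  if (is.null(spec)) fb_abort("MissingSimulation", "no simulation spec given")
  doc <- model
  net <- doc$networks[[spec$target]]
  dt <- spec$dt
  steps <- as.integer(round(spec$duration / dt))
  seed <- spec$seed

  # ---- neuron structures (global enumeration in population order)
  pops <- net$populations
  pop_offset <- integer(0); idx <- 0L
  for (p in pops) { pop_offset[p$id] <- idx; idx <- idx + p$size }
  N <- idx
  items <- vector("list", N)
  i <- 0L
  for (p in pops) {
    ct <- doc$cell_types[[p$component]]
    for (k in seq_len(p$size)) {
      if (ct$kind == "morph") {
        comps <- discretize(ct, doc)
        nC <- length(comps)
        gates <- list()  # per comp: per mech: named gate values
        v <- rep(ct$init_v, nC)
        for (ci in seq_len(nC)) {
          for (m in comps[[ci]]$mechanisms) {
            ch <- doc$ion_channels[[m$channel]]
            gv <- vapply(ch$gates, fb_gate_steady_state, numeric(1),
                         v0 = ct$init_v)
            gates[[paste0(ci, ".", m$id)]] <- gv
          }
        }
        items[[i + 1L]] <- list(
          idx = i, kind = "morph", type = p$component, comps = comps,
          nC = nC, v = v, gates = gates, thresh = ct$spike_thresh,
          channels = doc$ion_channels,
          stream0 = fb_rng_stream(seed, i, 0), kinds = list())
      } else {
        dyn <- ct$dynamics
        env <- new.env(parent = fb_math_env())
        for (pn in names(dyn$parameters)) {
          val <- dyn$parameters[[pn]]$value
          assign(pn, if (is.na(val)) 0 else val, envir = env)
        }
        states <- numeric(0)
        for (sn in names(dyn$state_vars)) {
          init <- dyn$state_vars[[sn]]$init
          os <- NULL
          for (o in dyn$on_start) if (o$var == sn) os <- o$expr
          if (!is.null(os)) init <- os
          v0 <- if (is.null(init)) 0 else eval(init, env)
          states[sn] <- v0
          assign(sn, v0, envir = env)
        }
        items[[i + 1L]] <- list(
          idx = i, kind = "point", type = p$component, dynamics = dyn,
          states = states,
          params = mget(names(dyn$parameters), envir = env),
          stream0 = fb_rng_stream(seed, i, 0), kinds = list())
      }
      i <- i + 1L
    }
  }

  # ---- kind enumeration per item (same keys and order as the engine)
  an_kinds <- list()  # per type: list(syn = keys, input = keys, reg)
  attach <- resolve_attachments(net, doc$cell_types, doc)
  for (p in pops) {
    tid <- p$component
    if (!is.null(an_kinds[[tid]])) next
    ct <- doc$cell_types[[tid]]
    at <- attach[[tid]] %||% list(syn = list(), input = list())
    if (ct$kind == "morph") {
      comps <- items[[pop_offset[[p$id]] + 1L]]$comps
      for (ci in seq_along(comps)) {
        key <- as.character(comps[[ci]]$index)
        comps[[ci]]$syn_kinds <- sort(unlist(at$syn[[key]]) %||% character(0))
        comps[[ci]]$input_kinds <- sort(unlist(at$input[[key]]) %||% character(0))
      }
      groups <- deduplicate(comps)
    } else {
      comps <- list(list(index = 0L,
                         syn_kinds = sort(unlist(at$syn[["0"]]) %||% character(0)),
                         input_kinds = sort(unlist(at$input[["0"]]) %||% character(0)),
                         mechanisms = list()))
      groups <- list(list(key = tid, members = 0L))
    }
    an_kinds[[tid]] <- list(
      syn = fb_kind_registry(groups, comps, doc, "syn"),
      input = fb_kind_registry(groups, comps, doc, "input"),
      groups = groups)
  }
  for (ii in seq_len(N)) {
    tid <- items[[ii]]$type
    ks <- c(names(an_kinds[[tid]]$syn), names(an_kinds[[tid]]$input))
    items[[ii]]$kinds <- stats::setNames(
      lapply(ks, function(key) {
        reg <- an_kinds[[tid]]$syn[[key]] %||% an_kinds[[tid]]$input[[key]]
        list(key = key, role = reg$role, dyn = reg$dynamics, entries = list())
      }), ks)
  }

  add_entry <- function(ii, key, e) {
    kg <- items[[ii + 1L]]$kinds[[key]]
    e$states <- numeric(0)
    for (sn in names(kg$dyn$state_vars)) e$states[sn] <- 0
    e$flag <- 0
    kg$entries[[length(kg$entries) + 1L]] <- e
    items[[ii + 1L]]$kinds[[key]] <<- kg
    length(kg$entries)
  }
  kind_key_of <- function(tid, comp, kind, what = "syn") {
    groups <- an_kinds[[tid]]$groups
    for (gi in seq_along(groups)) {
      if (comp %in% groups[[gi]]$members) {
        return(paste0(what, ":", kind, "@g", gi))
      }
    }
    stop("no group")
  }
  comp_of <- function(tid, segment) {
    ct <- doc$cell_types[[tid]]
    if (ct$kind == "point") return(0L)
    comps <- items[[which(vapply(items, function(x) x$type == tid, logical(1)))[1]]]$comps
    for (c in comps) if (c$seg_id == segment) return(c$index)
    stop("no segment")
  }

  # routing: per source item, ordered targets (item, key, entry, delay)
  routing <- vector("list", N)
  for (pr in net$projections) {
    pre0 <- pop_offset[[pr$presynaptic]]; post0 <- pop_offset[[pr$postsynaptic]]
    post_t <- pops[[pr$postsynaptic]]$component
    cd <- pr$connections
    for (k in seq_len(nrow(cd))) {
      src <- pre0 + cd$pre_cell[k]; dst <- post0 + cd$post_cell[k]
      comp <- comp_of(post_t, cd$post_segment[k])
      key <- kind_key_of(post_t, comp, pr$synapse)
      entry <- add_entry(dst, key, list(tc = comp, w = cd$weight[k],
                                        dl = cd$delay[k]))
      routing[[src + 1L]] <- c(routing[[src + 1L]],
                               list(list(item = dst, key = key, entry = entry,
                                         delay = cd$delay[k])))
    }
  }
  for (pr in net$electrical_projections) {
    pre0 <- pop_offset[[pr$presynaptic]]; post0 <- pop_offset[[pr$postsynaptic]]
    pre_t <- pops[[pr$presynaptic]]$component
    post_t <- pops[[pr$postsynaptic]]$component
    cd <- pr$connections
    for (k in seq_len(nrow(cd))) {
      a_idx <- pre0 + cd$pre_cell[k]; b_idx <- post0 + cd$post_cell[k]
      ca <- comp_of(pre_t, cd$pre_segment[k])
      cb <- comp_of(post_t, cd$post_segment[k])
      ka <- kind_key_of(pre_t, ca, paste0("gap:", cd$synapse[k]))
      kb <- kind_key_of(post_t, cb, paste0("gap:", cd$synapse[k]))
      add_entry(a_idx, ka, list(tc = ca, peer = b_idx, peer_comp = cb))
      add_entry(b_idx, kb, list(tc = cb, peer = a_idx, peer_comp = ca))
    }
  }
  for (il in net$input_lists) {
    base0 <- pop_offset[[il$population]]
    tid <- pops[[il$population]]$component
    counters <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(il$inputs))) {
      dst <- base0 + il$inputs$target[k]
      ck <- as.character(dst)
      cnt <- (get0(ck, envir = counters) %||% 0L) + 1L
      assign(ck, cnt, envir = counters)
      comp <- comp_of(tid, il$inputs$segment[k])
      key <- kind_key_of(tid, comp, il$component, what = "input")
      add_entry(dst, key, list(tc = comp,
                               stream = fb_rng_stream(seed, dst, cnt)))
    }
  }

  # ---- probes and event selections
  probes <- list()
  for (of in spec$output_files) {
    for (pstr in of$probes) {
      pp <- fb_parse_probe(pstr)
      gidx <- pop_offset[[pp$population]] + pp$index
      it <- items[[gidx + 1L]]
      comp <- if (it$kind == "morph") comp_of(it$type, pp$segment) else 0L
      probes[[length(probes) + 1L]] <- list(item = gidx, comp = comp,
                                            var = pp$var, path = pstr)
    }
  }
  # initial state carries the working precision, like the instantiated tables
  if (!fp64) {
    for (ii in seq_len(N)) {
      if (items[[ii]]$kind == "morph") {
        items[[ii]]$v <- fb_round_f32(items[[ii]]$v)
        items[[ii]]$gates <- lapply(items[[ii]]$gates, fb_round_f32)
      } else {
        items[[ii]]$states <- fb_round_f32(items[[ii]]$states)
      }
    }
  }

  ev_sources <- lapply(spec$event_files, function(ef) {
    vapply(ef$sources, function(s) {
      ep <- fb_parse_endpoint(s)
      pop_offset[[ep$population]] + ep$index
    }, numeric(1))
  })

  read_probe <- function(p) {
    it <- items[[p$item + 1L]]
    if (it$kind == "morph") it$v[p$comp + 1L] else it$states[[p$var]]
  }

  # ---- pending event deliveries: step -> list of (item, key, entry)
  pending <- new.env(parent = emptyenv())

  np <- length(probes)
  wf <- matrix(0, nrow = steps + 1L, ncol = np)
  time <- (0:steps) * dt
  if (np > 0L) wf[1L, ] <- vapply(probes, read_probe, numeric(1))
  spikes_n <- integer(0); spikes_s <- integer(0)
  ev_file <- integer(0); ev_src <- integer(0); ev_t <- double(0)
  f32 <- function(x) if (fp64) x else fb_round_f32(x)

  for (k in 0:(steps - 1L)) {
    t <- k * dt
    # deliver due events (increment flags)
    due <- get0(as.character(k), envir = pending)
    if (!is.null(due)) {
      for (d in due) {
        kg <- items[[d$item + 1L]]$kinds[[d$key]]
        kg$entries[[d$entry]]$flag <- kg$entries[[d$entry]]$flag + 1
        items[[d$item + 1L]]$kinds[[d$key]] <- kg
      }
      rm(list = as.character(k), envir = pending)
    }
    new_items <- items
    fired <- integer(0)
    for (ii in seq_len(N)) {
      it <- items[[ii]]
      res <- fb_oracle_step_item(it, items, t, dt, k, f32)
      new_items[[ii]] <- res$item
      if (res$spiked) fired <- c(fired, it$idx)
    }
    items <- new_items
    if (length(fired) > 0L) {
      # route spikes (same arrival rule as the engine)
      for (src in fired) {
        for (r in routing[[src + 1L]]) {
          a <- k + max(1L, as.integer(round(r$delay / dt)))
          if (a < steps) {
            ky <- as.character(a)
            assign(ky, c(get0(ky, envir = pending),
                         list(list(item = r$item, key = r$key,
                                   entry = r$entry))), envir = pending)
          }
        }
      }
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
    if (np > 0L) wf[k + 2L, ] <- vapply(probes, read_probe, numeric(1))
  }
  structure(list(
    time = time, waveforms = wf,
    events = data.frame(file = ev_file, source = ev_src, time = ev_t),
    spikes = data.frame(neuron = spikes_n, step = spikes_s,
                        time = spikes_s * dt),
    probe_paths = vapply(probes, function(p) p$path, character(1)),
    dt = dt, steps = steps
  ), class = "fb_recording")
}

#' @keywords internal
#' Process all synapse/input kinds of one item: consume flags, draw Poisson
#' events, evaluate currents in (kind, entry) order into `isyn`, and advance
#' the per-entry states with forward Euler. Returns list(it, isyn).
#' Expressions are evaluated against plain lists (enclosed by the math
#' helpers), exactly elementwise-equivalent to the generated kernels'
#' vectorized evaluation.
fb_oracle_kind_block <- function(it, items, v, isyn, t, dt, step) {
  math <- fb_math_env()
  for (key in names(it$kinds)) {
    kg <- it$kinds[[key]]
    nk <- length(kg$entries)
    if (nk == 0L) next
    dyn <- kg$dyn
    if (is.null(kg$pvals)) {
      pv <- list(t = 0, dt = dt)
      for (pn in names(dyn$parameters)) {
        val <- dyn$parameters[[pn]]$value
        if (!is.na(val)) pv[[pn]] <- val
      }
      kg$pvals <- pv
    }
    base_vars <- kg$pvals
    base_vars$t <- t
    for (j in seq_len(nk)) {
      e <- kg$entries[[j]]
      vars <- base_vars
      for (sn in names(e$states)) vars[[sn]] <- e$states[[sn]]
      vars$v <- v[e$tc + 1L]
      if (kg$role == "event") {
        vars$weight <- e$w
        while (e$flag > 0) {
          h <- dyn$on_events[[1]]
          for (tgt in names(h$assignments)) {
            nv <- eval(h$assignments[[tgt]], vars, math)
            e$states[[tgt]] <- nv
            vars[[tgt]] <- nv
          }
          e$flag <- e$flag - 1
        }
      }
      if (kg$role == "poisson") {
        u <- fb_rng_uniform(e$stream, step)
        if (u < kg$pvals[[dyn$poisson_fire$rate_param]] * dt) {
          for (tgt in names(dyn$poisson_fire$assignments)) {
            nv <- eval(dyn$poisson_fire$assignments[[tgt]], vars, math)
            e$states[[tgt]] <- nv
            vars[[tgt]] <- nv
          }
        }
      }
      if (kg$role == "gap") {
        peer <- items[[e$peer + 1L]]
        vars$vpeer <- if (peer$kind == "morph") peer$v[e$peer_comp + 1L]
                      else peer$states[["v"]]
      }
      # derived variables in DAG order
      for (nm in names(dyn$derived_vars)) {
        vars[[nm]] <- eval(dyn$derived_vars[[nm]], vars, math)
      }
      isym <- dyn$exposures[["i"]]
      if (!is.null(isym) && !is.na(isym)) {
        kk <- e$tc + 1L
        isyn[kk] <- isyn[kk] + vars[[isym]]
      }
      # forward-Euler state updates
      for (sn in names(e$states)) {
        d <- dyn$time_derivatives[[sn]]
        if (!is.null(d)) {
          e$states[[sn]] <- e$states[[sn]] + dt * eval(d, vars, math)
        }
      }
      kg$entries[[j]] <- e
    }
    it$kinds[[key]] <- kg
  }
  list(it = it, isyn = isyn)
}

#' @keywords internal
#' Advance one neuron by one step (pure interpretation). `items` holds the
#' previous-step states of all neurons (for gap-junction peers). Returns
#' list(item, spiked).
fb_oracle_step_item <- function(it, items, t, dt, step, f32) {
  math <- fb_math_env()
  if (it$kind == "morph") {
    nC <- it$nC
    v <- it$v
    Gtot <- numeric(nC); GE <- numeric(nC); isyn <- numeric(nC)
    Cc <- numeric(nC); gaf <- numeric(nC)
    tauinf_all <- list()
    for (ci in seq_len(nC)) {
      comp <- it$comps[[ci]]
      Cc[ci] <- comp$capacitance; gaf[ci] <- comp$g_axial
      vars <- list(v = v[ci])
      gsum <- 0; gesum <- 0
      for (m in comp$mechanisms) {
        gv <- it$gates[[paste0(ci, ".", m$id)]]
        g <- m$gbar
        ch <- it$channels[[m$channel]]
        tauinf <- list()
        for (gt in ch$gates) {
          if (gt$form == "rates") {
            a <- eval(fb_rate_ast(gt$forward), vars, math)
            b <- eval(fb_rate_ast(gt$reverse), vars, math)
            tau <- 1 / (a + b); inf <- a * tau
          } else {
            tau <- eval(fb_rate_ast(gt$timeCourse), vars, math)
            inf <- eval(fb_rate_ast(gt$steadyState), vars, math)
          }
          tauinf[[gt$name]] <- c(tau, inf)
          q <- gv[[gt$name]]
          g <- g * (if (gt$instances == 1L) q else q^gt$instances)
        }
        tauinf_all[[paste0(ci, ".", m$id)]] <- tauinf
        gsum <- gsum + g
        gesum <- gesum + g * m$erev
      }
      Gtot[ci] <- gsum
      GE[ci] <- gesum
    }
    kb <- fb_oracle_kind_block(it, items, v, isyn, t, dt, step)
    it <- kb$it; isyn <- kb$isyn
    # implicit cable solve (same assembly order as the generated kernel)
    Cdt <- Cc / dt
    aa <- Cdt + Gtot
    bb <- numeric(nC)
    rr <- Cdt * v + GE + isyn
    par <- vapply(it$comps, function(c) c$parent + 1L, integer(1))
    if (nC > 1L) {
      for (ii in 2:nC) {
        aa[ii] <- aa[ii] + gaf[ii]
        aa[par[ii]] <- aa[par[ii]] + gaf[ii]
        bb[ii] <- -gaf[ii]
      }
    }
    vn <- hines_solve(aa, bb, rr, par)
    # cnexp gate updates from start-of-step rates
    for (ci in seq_len(nC)) {
      for (m in it$comps[[ci]]$mechanisms) {
        keyg <- paste0(ci, ".", m$id)
        gv <- it$gates[[keyg]]
        for (gn in names(gv)) {
          ti <- tauinf_all[[keyg]][[gn]]
          gv[[gn]] <- ti[2] + (gv[[gn]] - ti[2]) * exp(-dt / ti[1])
        }
        it$gates[[keyg]] <- f32(gv)
      }
    }
    spiked <- (v[1] < it$thresh && vn[1] >= it$thresh)
    it$v <- f32(vn)
    for (key in names(it$kinds)) {
      for (j in seq_along(it$kinds[[key]]$entries)) {
        it$kinds[[key]]$entries[[j]]$states <-
          f32(it$kinds[[key]]$entries[[j]]$states)
      }
    }
    return(list(item = it, spiked = spiked))
  }
  # ---- point cell
  dyn <- it$dynamics
  v <- it$states[["v"]]
  isyn <- 0
  kb <- fb_oracle_kind_block(it, items, v, isyn, t, dt, step)
  it <- kb$it; isyn <- kb$isyn
  vars <- it$params
  for (sn in names(it$states)) vars[[sn]] <- it$states[[sn]]
  vars$iSyn <- isyn
  vars$t <- t; vars$dt <- dt
  stream0 <- it$stream0
  vars$random <- function(x) x * fb_rng_uniform(stream0, step)
  for (nm in names(dyn$derived_vars)) {
    vars[[nm]] <- eval(dyn$derived_vars[[nm]], vars, math)
  }
  new_states <- it$states
  for (sn in names(it$states)) {
    d <- dyn$time_derivatives[[sn]]
    if (!is.null(d)) {
      new_states[[sn]] <- it$states[[sn]] + dt * eval(d, vars, math)
    }
  }
  spiked <- FALSE
  # conditions are tested on the updated values
  vars2 <- vars
  for (sn in names(new_states)) vars2[[sn]] <- new_states[[sn]]
  for (oc in dyn$on_conditions) {
    if (isTRUE(eval(oc$test, vars2, math))) {
      for (tgt in names(oc$assignments)) {
        nv <- eval(oc$assignments[[tgt]], vars2, math)
        new_states[[tgt]] <- nv
        vars2[[tgt]] <- nv
      }
      if (length(oc$emits) > 0L) spiked <- TRUE
    }
  }
  if (!is.null(dyn$poisson_fire) && length(dyn$poisson_fire$emits) > 0L) {
    rate <- dyn$parameters[[dyn$poisson_fire$rate_param]]$value
    if (fb_rng_uniform(it$stream0, step) < rate * dt) spiked <- TRUE
  }
  it$states <- f32(new_states)
  for (key in names(it$kinds)) {
    for (j in seq_along(it$kinds[[key]]$entries)) {
      it$kinds[[key]]$entries[[j]]$states <-
        f32(it$kinds[[key]]$entries[[j]]$states)
    }
  }
  list(item = it, spiked = spiked)
}
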