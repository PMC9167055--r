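# Kernel code generation.
#
# Each neuron type's signature is emitted as R source for one kernel
# function with the fixed calling contract
#   function(TS, it, t, dt, step)
# where TS is the table-set environment and `it` the work item's instance
# record. A kernel reads old-step state only from the A buffers and writes
# only its own slots in the B buffers (plus its own spike flag); event
# delivery into other items' flag slots is performed by the engine between
# steps, so work items can run in any order within a step.
#
# The emitted step order is fixed: eval statements (per code unit, vectorized
# over the unit's member compartments), synapse/input table loops (consume
# spike flags, accumulate currents into per-compartment sums in entry order),
# the implicit cable solve for multi-compartment types, state updates
# (forward Euler or cnexp from start-of-step values), and event emission
# (threshold conditions set the item's spike flag).
#
# Regenerating from the same signature yields byte-identical source; kernels
# are cached by a hash of their source.

#' Choose the integrator for a state variable
#'
#' Returns `"cnexp"` (exponential Euler under frozen rates) exactly when the
#' state is a Hodgkin-Huxley gate with alpha-beta or tau-inf dynamics, i.e.
#' its derivative is linear in the state with voltage-dependent
#' coefficients; every other state (synapse states, point-cell states,
#' custom LEMS states) advances with forward Euler.
#'
#' @param state a state record from an `fb_signature` (fields `name`,
#'   `gate`, ...).
#' @param context list with `kind` (`"gate"`, `"synapse"`, `"cell"`, ...)
#'   and `deriv` (the derivative AST).
#' @return `"cnexp"` or `"fwd_euler"`.
#' @export
choose_integrator <- function(state, context = list(kind = "cell", deriv = NULL)) {
  if (identical(context$kind, "gate") && !is.null(context$deriv) &&
      fb_linear_in(context$deriv, state$name)) {
    return("cnexp")
  }
  "fwd_euler"
}

#' @keywords internal
#' Deparse to single-line source; digits17 keeps numeric literals exact under
#' the parse/deparse round trip (a 15-digit literal would perturb values like
#' the double-exponential waveform factor by one ulp).
fb_src <- function(e) {
  paste(deparse(e, width.cutoff = 500L,
                control = c("keepInteger", "keepNA", "digits17")),
        collapse = " ")
}

#' @keywords internal
#' Literal integer vector source, e.g. "c(1L, 4L)" or "2L".
fb_lit_ivec <- function(x) {
  if (length(x) == 1L) sprintf("%dL", x)
  else paste0("c(", paste(sprintf("%dL", x), collapse = ", "), ")")
}

#' @keywords internal
fb_lit_num <- function(x) sprintf("%.17g", x)

#' @keywords internal
#' FNV-1a hash of a string, as hex.
fb_hash <- function(s) {
  b <- utf8ToInt(s)
  h <- 2166136261
  for (x in b) {
    h <- .fb_xor32(h, x)
    h <- .fb_mul32(h, 16777619)
  }
  sprintf("%08x", as.integer(h %% 2^31))  # stable printable form
}

#' Emit the kernel source for a neuron type
#'
#' @param analysis analysis object from `flatbrain:::fb_analyze` (or a
#'   `model_document`, analysed with defaults).
#' @param type_id cell type id.
#' @return a `kernel_source`: list with `type_id`, `source`, `entry`,
#'   `hash`, `n_statements`.
#' @export
emit_kernel <- function(analysis, type_id) {
  if (inherits(analysis, "model_document")) analysis <- fb_analyze(analysis)
  an <- analysis
  tp <- an$types[[type_id]]
  if (is.null(tp)) {
    fb_abort("UnresolvedReference", sprintf("unknown type '%s'", type_id))
  }
  lay <- fb_layout_type(tp, an$doc)
  src <- if (tp$kind == "point") fb_emit_point(tp, lay, an)
         else fb_emit_morph(tp, lay, an)
  structure(list(
    type_id = type_id,
    source = src,
    entry = paste0("kernel_", type_id),
    hash = fb_hash(src),
    n_statements = fb_signature_statement_count(tp$nsig)
  ), class = "kernel_source")
}

#' Load a kernel from its generated source
#'
#' Parses and evaluates the kernel source into a callable, with the package
#' internals (tree solver, RNG, dereferencing, math helpers) in scope.
#' Kernels are cached by source hash: loading the same source twice returns
#' the same callable. A source that fails to parse or evaluate raises
#' `GenerationBug` including an excerpt.
#'
#' @param ks a `kernel_source` from [emit_kernel()].
#' @return the kernel function `(TS, it, t, dt, step)`.
#' @export
load_kernel <- function(ks) {
  cached <- get0(ks$hash, envir = .fb_kernel_cache)
  if (!is.null(cached)) return(cached)
  env <- new.env(parent = tryCatch(asNamespace("flatbrain"),
                                   error = function(e) globalenv()))
  fn <- tryCatch(
    eval(parse(text = ks$source, keep.source = FALSE), envir = env),
    error = function(e) {
      excerpt <- substr(ks$source, 1, 200)
      fb_abort("GenerationBug", sprintf(
        "kernel for '%s' failed to load: %s\nsource starts: %s",
        ks$type_id, conditionMessage(e), excerpt))
    })
  if (!is.function(fn)) {
    fb_abort("GenerationBug",
             sprintf("kernel source for '%s' did not yield a function", ks$type_id))
  }
  assign(ks$hash, fn, envir = .fb_kernel_cache)
  fn
}

.fb_kernel_cache <- new.env(parent = emptyenv())

# ---------------------------------------------------------------------------
# emission: shared kind blocks
# ---------------------------------------------------------------------------

#' @keywords internal
#' Source lines for one synapse/input kind block. `vsym` is the source text
#' of the per-compartment voltage vector ("v" for morph, the scalar local
#' for point cells); isyn is accumulated into `isyn[tc + 1L]`.
fb_emit_kind_block <- function(key, kind, an) {
  dyn <- kind$dynamics
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  q <- function(s) sprintf('"%s"', s)
  add(sprintf("  kt <- it$k[[%s]]", q(key)))
  add("  if (kt$n > 0L) {")
  add("    tc1 <- TS[[kt$cols$tc$binding]] + 1L")
  states <- names(dyn$state_vars)
  # symbol map: states -> ks_<s>, v -> vt, params -> literals, weight -> kw
  map <- list(v = quote(vt))
  for (s in states) map[[s]] <- as.name(paste0("ks_", s))
  for (p in names(dyn$parameters)) {
    val <- dyn$parameters[[p]]$value
    if (!is.na(val)) map[[p]] <- val
  }
  if (kind$role == "event") {
    add("    kw <- TS[[kt$cols$w$binding]]")
    map$weight <- quote(kw[sel])
  }
  for (s in states) {
    add(sprintf('    ks_%s <- TS[[paste0(kt$cols$st_%s$binding, "A")]]', s, s))
  }
  add("    vt <- v[tc1]")
  if (kind$role == "event") {
    add('    fl <- TS[[paste0(kt$cols$fl$binding, "A")]]')
    # consume pending events: apply the OnEvent handler once per pending count
    h <- NULL
    for (hh in dyn$on_events) { h <- hh; break }
    add("    while (any(fl > 0)) {")
    add("      sel <- fl > 0")
    selmap <- map
    for (s in states) selmap[[s]] <- bquote(.(as.name(paste0("ks_", s)))[sel])
    selmap$v <- quote(vt[sel])
    if (!is.null(h)) {
      for (tgt in names(h$assignments)) {
        add(sprintf("      ks_%s[sel] <- %s", tgt,
                    fb_src(fb_expr_subst(h$assignments[[tgt]], selmap))))
      }
    }
    add("      fl <- fl - (fl > 0)")
    add("    }")
  }
  if (kind$role == "poisson") {
    add("    us <- fb_rng_uniform(TS[[kt$cols$stream$binding]], step)")
    rate <- dyn$parameters[[dyn$poisson_fire$rate_param]]$value
    add(sprintf("    fire <- us < %s * dt", fb_lit_num(rate)))
    if (length(dyn$poisson_fire$assignments) > 0L) {
      add("    if (any(fire)) {")
      fmap <- map
      for (s in states) fmap[[s]] <- bquote(.(as.name(paste0("ks_", s)))[fire])
      fmap$v <- quote(vt[fire])
      for (tgt in names(dyn$poisson_fire$assignments)) {
        add(sprintf("      ks_%s[fire] <- %s", tgt,
                    fb_src(fb_expr_subst(dyn$poisson_fire$assignments[[tgt]], fmap))))
      }
      add("    }")
    }
  }
  if (kind$role == "gap") {
    add('    vpeer <- fb_deref(TS, TS[[kt$cols$ref$binding]], "A")')
    map$vpeer <- quote(vpeer)
  }
  # eval statements (derived variables) in DAG order
  for (nm in names(dyn$derived_vars)) {
    add(sprintf("    kd_%s <- rep_len(%s, kt$n)", nm,
                fb_src(fb_expr_subst(dyn$derived_vars[[nm]], map))))
    map[[nm]] <- as.name(paste0("kd_", nm))
  }
  isym <- dyn$exposures[["i"]]
  if (!is.null(isym) && !is.na(isym)) {
    cur <- if (isym %in% names(dyn$derived_vars)) paste0("kd_", isym)
           else fb_src(map[[isym]] %||% as.name(isym))
    add(sprintf("    cur <- %s", cur))
    add("    for (jj in seq_len(kt$n)) {")
    add("      kk <- tc1[jj]")
    add("      isyn[kk] <- isyn[kk] + cur[jj]")
    add("    }")
  }
  # state updates: forward Euler
  for (s in states) {
    d <- dyn$time_derivatives[[s]]
    if (is.null(d)) {
      add(sprintf('    TS[[paste0(kt$cols$st_%s$binding, "B")]] <- ks_%s', s, s))
    } else {
      add(sprintf('    TS[[paste0(kt$cols$st_%s$binding, "B")]] <- ks_%s + dt * (%s)',
                  s, s, fb_src(fb_expr_subst(d, map))))
    }
  }
  if (kind$role == "event") {
    add('    TS[[paste0(kt$cols$fl$binding, "B")]] <- numeric(kt$n)')
  }
  add("  }")
  L
}

# ---------------------------------------------------------------------------
# emission: point cells
# ---------------------------------------------------------------------------

#' @keywords internal
fb_emit_point <- function(tp, lay, an) {
  sig <- tp$comp_sigs[[1]]
  dyn <- tp$dynamics
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add("function(TS, it, t, dt, step) {")
  add("  SA <- TS$T2A; CF <- TS$T1")
  add("  sf <- it$sf; cf <- it$cf")
  snames <- vapply(sig$states, `[[`, character(1), "name")
  for (i in seq_along(snames)) {
    add(sprintf("  %s <- SA[sf + %dL]", snames[i], i))
  }
  cnames <- vapply(sig$constants, `[[`, character(1), "name")
  for (i in seq_along(cnames)) {
    add(sprintf("  %s <- CF[cf + %dL]", cnames[i], i))
  }
  add("  isyn <- 0")
  uses_random <- any(vapply(c(dyn$derived_vars, dyn$time_derivatives),
                            function(e) "random" %in% all.names(e), logical(1)))
  if (uses_random) {
    add("  random <- function(x) x * fb_rng_uniform(it$stream0, step)")
  }
  for (key in names(tp$syn_kinds)) {
    L <- c(L, fb_emit_kind_block(key, tp$syn_kinds[[key]], an))
  }
  for (key in names(tp$input_kinds)) {
    L <- c(L, fb_emit_kind_block(key, tp$input_kinds[[key]], an))
  }
  # eval statements (derived variables), iSyn bound to the accumulated sum
  map <- list(iSyn = quote(isyn))
  for (st in sig$eval_statements) {
    add(sprintf("  %s <- %s", st$target, fb_src(fb_expr_subst(st$expr, map))))
  }
  # updates: forward Euler on every state with a derivative
  deriv_of <- list()
  for (st in sig$update_statements) deriv_of[[st$state]] <- st$deriv
  for (s in snames) {
    d <- deriv_of[[s]]
    if (is.null(d)) {
      add(sprintf("  %s_n <- %s", s, s))
    } else {
      add(sprintf("  %s_n <- %s + dt * (%s)", s, s,
                  fb_src(fb_expr_subst(d, map))))
    }
  }
  # event emission: conditions tested on the updated values
  add("  spk <- 0")
  nmap <- map
  for (s in snames) nmap[[s]] <- as.name(paste0(s, "_n"))
  for (h in sig$event_handlers) {
    if (identical(h$trigger$kind, "condition")) {
      add(sprintf("  if (%s) {", fb_src(fb_expr_subst(h$trigger$test, nmap))))
      for (tgt in names(h$assignments)) {
        add(sprintf("    %s_n <- %s", tgt,
                    fb_src(fb_expr_subst(h$assignments[[tgt]], nmap))))
      }
      if (length(h$emits) > 0L) add("    spk <- 1")
      add("  }")
    } else if (identical(h$trigger$kind, "poisson")) {
      rate <- NULL
      for (cst in sig$constants) {
        if (cst$name == h$trigger$rate_param) rate <- cst$default
      }
      add(sprintf("  if (fb_rng_uniform(it$stream0, step) < %s * dt) spk <- 1",
                  fb_lit_num(rate)))
    }
  }
  for (i in seq_along(snames)) {
    add(sprintf("  TS$T2B[sf + %dL] <- %s_n", i, snames[i]))
  }
  add("  TS$T4B[it$si + 1L] <- spk")
  add("  invisible(NULL)")
  add("}")
  paste(L, collapse = "\n")
}

# ---------------------------------------------------------------------------
# emission: multi-compartment cells
# ---------------------------------------------------------------------------

#' @keywords internal
fb_emit_morph <- function(tp, lay, an) {
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  nC <- tp$n_comp
  parent1 <- vapply(tp$comps, function(c) c$parent + 1L, integer(1))
  add("function(TS, it, t, dt, step) {")
  add("  SA <- TS$T2A; CF <- TS$T1")
  add("  sf <- it$sf; cf <- it$cf")
  add(sprintf("  nC <- %dL", nC))
  add("  v <- numeric(nC); Gtot <- numeric(nC); GE <- numeric(nC)")
  add("  isyn <- numeric(nC); Cc <- numeric(nC); gaf <- numeric(nC)")
  units <- tp$nsig$units
  post_updates <- character(0)  # update lines collected, emitted after solve
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    gl <- lay$groups[[u$gi]]
    slots <- match(u$members, gl$members)       # 1-based within group block
    pos <- u$members + 1L                       # compartment order position
    sig <- u$sig
    sfx <- sprintf("_u%d", ui)
    add(sprintf("  pos%d <- %s", ui, fb_lit_ivec(pos)))
    # state reads
    smap <- list()
    for (st in sig$states) {
      s <- st$name
      off <- if (s == "v") gl$sf$v else gl$sf[[s]]
      idx <- off + slots
      add(sprintf("  %s%s <- SA[sf + %s]", s, sfx, fb_lit_ivec(idx)))
      smap[[s]] <- as.name(paste0(s, sfx))
    }
    for (cst in sig$constants) {
      s <- cst$name
      off <- gl$cf[[s]]
      if (is.null(off)) next
      idx <- off + slots
      add(sprintf("  %s%s <- CF[cf + %s]", s, sfx, fb_lit_ivec(idx)))
      smap[[s]] <- as.name(paste0(s, sfx))
    }
    add(sprintf("  v[pos%d] <- v%s", ui, sfx))
    add(sprintf("  Cc[pos%d] <- C%s", ui, sfx))
    add(sprintf("  gaf[pos%d] <- ga%s", ui, sfx))
    # eval statements
    for (st in sig$eval_statements) {
      tgt <- paste0(st$target, sfx)
      add(sprintf("  %s <- %s", tgt, fb_src(fb_expr_subst(st$expr, smap))))
      smap[[st$target]] <- as.name(tgt)
    }
    add(sprintf("  Gtot[pos%d] <- Gtot%s", ui, sfx))
    add(sprintf("  GE[pos%d] <- GE%s", ui, sfx))
    # collect state updates for after the solve (gates: cnexp)
    for (st in sig$update_statements) {
      if (identical(st$method, "cable") || st$state == "v") next
      srec <- sig$states[[st$state]]
      ctx <- list(kind = if (isTRUE(srec$gate)) "gate" else "other",
                  deriv = st$deriv)
      meth <- choose_integrator(srec, ctx)
      off <- gl$sf[[st$state]]
      idx <- off + slots
      if (meth == "cnexp" && !is.null(srec$tau_sym)) {
        upd <- sprintf(
          "  TS$T2B[sf + %s] <- %s + (%s - %s) * exp(-dt / %s)",
          fb_lit_ivec(idx),
          paste0(srec$inf_sym, sfx), paste0(st$state, sfx),
          paste0(srec$inf_sym, sfx), paste0(srec$tau_sym, sfx))
      } else {
        upd <- sprintf("  TS$T2B[sf + %s] <- %s + dt * (%s)",
                       fb_lit_ivec(idx), paste0(st$state, sfx),
                       fb_src(fb_expr_subst(st$deriv, smap)))
      }
      post_updates <- c(post_updates, upd)
    }
    post_updates <- c(post_updates, sprintf(
      "  TS$T2B[sf + %s] <- vn[pos%d]", fb_lit_ivec(gl$sf$v + slots), ui))
  }
  # synapse / input table loops
  for (key in names(tp$syn_kinds)) {
    L <- c(L, fb_emit_kind_block(key, tp$syn_kinds[[key]], an))
  }
  for (key in names(tp$input_kinds)) {
    L <- c(L, fb_emit_kind_block(key, tp$input_kinds[[key]], an))
  }
  # implicit cable solve: backward Euler with conductances frozen at
  # start-of-step gate values
  add("  Cdt <- Cc / dt")
  add("  aa <- Cdt + Gtot")
  add("  bb <- numeric(nC)")
  add("  rr <- Cdt * v + GE + isyn")
  add(sprintf("  par <- %s", fb_lit_ivec(parent1)))
  if (nC > 1L) {
    add("  for (ii in 2:nC) {")
    add("    aa[ii] <- aa[ii] + gaf[ii]")
    add("    aa[par[ii]] <- aa[par[ii]] + gaf[ii]")
    add("    bb[ii] <- -gaf[ii]")
    add("  }")
  }
  add("  vn <- hines_solve(aa, bb, rr, par)")
  for (u in post_updates) add(u)
  # spike detection on the soma (compartment 0) against the cell threshold
  add("  th <- CF[cf + 1L]")
  add("  TS$T4B[it$si + 1L] <- if (v[1L] < th && vn[1L] >= th) 1 else 0")
  add("  invisible(NULL)")
  add("}")
  paste(L, collapse = "\n")
}
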