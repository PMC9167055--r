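# Model analysis: from the parsed object model to per-neuron-type signatures
# and a work plan.
#
# Each neuron type used by the target network is analysed once: morphologies
# are discretized, channel mechanisms, synapse kinds and input kinds are
# attached per compartment, compartments with identical mathematical
# structure are grouped (signature deduplication), and a neuron-wide
# signature is formed — fully flattened when the compartment count is at most
# the flattening threshold K, otherwise as one block per dedup group with
# offset-shifted per-member data slices. The two forms are semantically
# identical; only the generated code layout differs.

#' @keywords internal
#' DynamicsSpec for one channel-density instance on a compartment. Gate
#' variables get canonical tau/inf evals: rates form tau = 1/(a+b),
#' inf = a*tau; tauInf form direct. Conductance g = gbar * prod(q^n).
fb_channel_dynamics <- function(density_id, channel) {
  states <- list(); derived <- list(); tds <- list()
  gfactors <- list()
  for (g in channel$gates) {
    q <- g$name
    tau_s <- paste0("tau_", q); inf_s <- paste0("inf_", q)
    if (g$form == "rates") {
      a_s <- paste0("alpha_", q); b_s <- paste0("beta_", q)
      derived[[a_s]] <- fb_rate_ast(g$forward)
      derived[[b_s]] <- fb_rate_ast(g$reverse)
      derived[[tau_s]] <- bquote(1 / (.(as.name(a_s)) + .(as.name(b_s))))
      derived[[inf_s]] <- bquote(.(as.name(a_s)) * .(as.name(tau_s)))
    } else {
      derived[[tau_s]] <- fb_rate_ast(g$timeCourse)
      derived[[inf_s]] <- fb_rate_ast(g$steadyState)
    }
    states[[q]] <- list(dim = "none", init = NULL)
    tds[[q]] <- bquote((.(as.name(inf_s)) - .(as.name(q))) / .(as.name(tau_s)))
    gfactors[[length(gfactors) + 1L]] <-
      if (g$instances == 1L) as.name(q) else bquote(.(as.name(q))^.(g$instances))
  }
  gexpr <- quote(gbar)
  for (f in gfactors) gexpr <- bquote(.(gexpr) * .(f))
  derived[["g"]] <- gexpr
  spec <- new_dynamics_spec(
    id = density_id,
    parameters = list(gbar = list(dim = "conductance", value = NA_real_),
                      erev = list(dim = "voltage", value = NA_real_)),
    requirements = c(v = "voltage"),
    exposures = c(g = "g", erev = "erev"),
    state_vars = states, derived_vars = derived, time_derivatives = tds,
    kind = "channel")
  spec
}

#' @keywords internal
#' Leaf signature of a channel instance, with gate metadata (tau/inf symbol
#' names) attached so the integrator chooser can emit cnexp updates.
fb_channel_signature <- function(density_id, channel) {
  sig <- build_leaf_signature(fb_channel_dynamics(density_id, channel))
  for (g in channel$gates) {
    q <- g$name
    sig$states[[q]]$tau_sym <- paste0("tau_", q)
    sig$states[[q]]$inf_sym <- paste0("inf_", q)
    sig$states[[q]]$gate <- TRUE
  }
  sig$meta$kind <- "channel"
  sig
}

#' Resolve which synapse and input kinds attach to which neuron types
#'
#' Scans the network's projections, electrical projections and input lists
#' and records, for every cell type and compartment, the set of synapse
#' component kinds and input kinds that may attach there. Gap junctions
#' register on both endpoint types (they carry a peer-voltage requirement).
#'
#' @param network a network from a `model_document`.
#' @param cell_types the document's cell type registry.
#' @param doc the containing `model_document`.
#' @return named list: cell type id -> list with `syn` and `input`, each a
#'   list mapping compartment index (as character, 0-based) to a character
#'   vector of kind ids.
#' @export
resolve_attachments <- function(network, cell_types, doc) {
  out <- list()
  ensure <- function(type_id) {
    if (is.null(out[[type_id]])) out[[type_id]] <<- list(syn = list(), input = list())
  }
  note <- function(type_id, what, comp, kind) {
    ensure(type_id)
    key <- as.character(comp)
    cur <- out[[type_id]][[what]][[key]]
    if (is.null(cur) || !(kind %in% cur)) {
      out[[type_id]][[what]][[key]] <<- c(cur, kind)
    }
  }
  comp_index <- fb_comp_index_fn(doc)
  for (pr in network$projections) {
    post_pop <- network$populations[[pr$postsynaptic]]
    tid <- post_pop$component
    for (k in seq_len(nrow(pr$connections))) {
      comp <- comp_index(tid, pr$connections$post_segment[k])
      note(tid, "syn", comp, pr$synapse)
    }
  }
  for (pr in network$electrical_projections) {
    pre_t <- network$populations[[pr$presynaptic]]$component
    post_t <- network$populations[[pr$postsynaptic]]$component
    for (k in seq_len(nrow(pr$connections))) {
      kind <- paste0("gap:", pr$connections$synapse[k])
      note(post_t, "syn", comp_index(post_t, pr$connections$post_segment[k]), kind)
      note(pre_t, "syn", comp_index(pre_t, pr$connections$pre_segment[k]), kind)
    }
  }
  for (il in network$input_lists) {
    tid <- network$populations[[il$population]]$component
    for (k in seq_len(nrow(il$inputs))) {
      note(tid, "input", comp_index(tid, il$inputs$segment[k]), il$component)
    }
  }
  out
}

#' @keywords internal
#' Returns f(type_id, segment_id) -> 0-based compartment index, caching
#' discretizations.
fb_comp_index_fn <- function(doc) {
  cache <- new.env(parent = emptyenv())
  function(type_id, segment_id) {
    ct <- doc$cell_types[[type_id]]
    if (ct$kind != "morph") return(0L)
    comps <- get0(type_id, envir = cache)
    if (is.null(comps)) {
      comps <- discretize(ct, doc)
      assign(type_id, comps, envir = cache)
    }
    for (c in comps) if (c$seg_id == segment_id) return(c$index)
    fb_abort("UnresolvedReference", sprintf(
      "segment %d not present on cell type '%s'", segment_id, type_id))
  }
}

#' Group compartments by structural similarity
#'
#' Compartments with an identical canonical signature — the same ordered list
#' of mechanism kinds, the same synapse/input table kinds and the same
#' integrator tags; constant values are data and do not participate — share a
#' dedup group. Groups are ordered by first occurrence.
#'
#' @param compartments output of [discretize()], with `syn_kinds` /
#'   `input_kinds` fields filled in.
#' @return list of groups: each has `key`, `members` (0-based compartment
#'   indices).
#' @export
deduplicate <- function(compartments) {
  keys <- vapply(compartments, function(c) {
    paste(
      paste(vapply(c$mechanisms, function(m) paste0(m$id, ":", m$channel),
                   character(1)), collapse = ","),
      paste(sort(c$syn_kinds), collapse = ","),
      paste(sort(c$input_kinds), collapse = ","),
      sep = " | ")
  }, character(1))
  groups <- list()
  seen <- character(0)
  for (i in seq_along(keys)) {
    k <- keys[i]
    gi <- match(k, seen)
    if (is.na(gi)) {
      seen <- c(seen, k)
      groups[[length(groups) + 1L]] <- list(key = k,
                                            members = compartments[[i]]$index)
    } else {
      groups[[gi]]$members <- c(groups[[gi]]$members, compartments[[i]]$index)
    }
  }
  groups
}

#' Build the neuron-wide signature of a cell type
#'
#' Joins the per-compartment signatures into a neuron-level signature. With
#' at most `K` compartments the result is fully flattened (one code unit per
#' compartment); above `K` it has one code unit per dedup group, vectorized
#' over the group members with offset-shifted data slices. Both forms are
#' semantically identical.
#'
#' @param comp_sigs list of per-group compartment signatures (one per dedup
#'   group).
#' @param groups dedup groups from [deduplicate()].
#' @param K flattening threshold (compartment count), default 8.
#' @return an `fb_neuron_signature`: `form`, `units` (each with `gi`,
#'   `members`, `sig`).
#' @export
build_neuron_signature <- function(comp_sigs, groups, K = 8L) {
  n_comp <- sum(vapply(groups, function(g) length(g$members), integer(1)))
  if (n_comp <= K) {
    units <- list()
    # flat: one unit per compartment, in compartment order
    for (ci in seq_len(n_comp) - 1L) {
      for (gi in seq_along(groups)) {
        if (ci %in% groups[[gi]]$members) {
          units[[length(units) + 1L]] <- list(gi = gi, members = ci,
                                              sig = comp_sigs[[gi]])
        }
      }
    }
    form <- "flat"
  } else {
    units <- lapply(seq_along(groups), function(gi) {
      list(gi = gi, members = groups[[gi]]$members, sig = comp_sigs[[gi]])
    })
    form <- "loop"
  }
  structure(list(form = form, units = units, n_comp = n_comp, K = K),
            class = "fb_neuron_signature")
}

#' @keywords internal
#' Number of generated code statements for a neuron signature: evals,
#' updates and handlers per unit (independent of member count per unit).
fb_signature_statement_count <- function(nsig) {
  sum(vapply(nsig$units, function(u) {
    length(u$sig$eval_statements) + length(u$sig$update_statements) +
      length(u$sig$event_handlers) + 1L  # + the per-unit data-slice setup
  }, integer(1)))
}

#' Build the work plan for a model
#'
#' Enumerates all neurons population-by-population in document order (one
#' work item per neuron, 0-based gapless global indices) and assigns each
#' neuron type a kernel type id.
#'
#' @param doc a `model_document`.
#' @param network network id (default: the first network).
#' @return a `fb_work_plan`: `work_items` data.frame (`idx`, `type`, `pop`,
#'   `inst`), `pop_offset` (named first-index per population), `types`
#'   (character vector of kernel type ids).
#' @export
build_work_plan <- function(doc, network = NULL) {
  net <- if (is.null(network)) doc$networks[[1]] else doc$networks[[network]]
  if (is.null(net)) fb_abort("UnresolvedReference", "no such network")
  items <- list()
  pop_offset <- integer(0)
  idx <- 0L
  for (p in net$populations) {
    pop_offset[p$id] <- idx
    for (i in seq_len(p$size) - 1L) {
      items[[length(items) + 1L]] <- data.frame(
        idx = idx, type = p$component, pop = p$id, inst = i,
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  wi <- do.call(rbind, items)
  structure(list(
    network = net$id,
    work_items = wi,
    pop_offset = pop_offset,
    types = unique(wi$type)
  ), class = "fb_work_plan")
}

#' @keywords internal
#' Full analysis of the network: per-type plans with groups, signatures and
#' kind registries, plus the work plan.
fb_analyze <- function(doc, network = NULL, K = 8L) {
  net <- if (is.null(network)) doc$networks[[1]] else doc$networks[[network]]
  plan <- build_work_plan(doc, net$id)
  attach <- resolve_attachments(net, doc$cell_types, doc)
  types <- list()
  for (tid in plan$types) {
    ct <- doc$cell_types[[tid]]
    at <- attach[[tid]]
    if (is.null(at)) at <- list(syn = list(), input = list())
    if (ct$kind == "morph") {
      comps <- discretize(ct, doc)
      for (ci in seq_along(comps)) {
        key <- as.character(comps[[ci]]$index)
        comps[[ci]]$syn_kinds <- sort(unlist(at$syn[[key]]) %||% character(0))
        comps[[ci]]$input_kinds <- sort(unlist(at$input[[key]]) %||% character(0))
      }
      groups <- deduplicate(comps)
      comp_sigs <- lapply(groups, function(g) {
        fb_comp_group_signature(comps[[g$members[1] + 1L]], doc)
      })
      nsig <- build_neuron_signature(comp_sigs, groups, K)
      types[[tid]] <- list(
        type_id = tid, kind = "morph", comps = comps, n_comp = length(comps),
        groups = groups, comp_sigs = comp_sigs, nsig = nsig,
        thresh = ct$spike_thresh, init_v = ct$init_v,
        syn_kinds = fb_kind_registry(groups, comps, doc, "syn"),
        input_kinds = fb_kind_registry(groups, comps, doc, "input"))
    } else {
      dyn <- ct$dynamics
      sig <- build_leaf_signature(dyn)
      comps <- list(list(index = 0L, parent = -1L,
                         syn_kinds = sort(unlist(at$syn[["0"]]) %||% character(0)),
                         input_kinds = sort(unlist(at$input[["0"]]) %||% character(0)),
                         mechanisms = list()))
      groups <- list(list(key = dyn$id, members = 0L))
      nsig <- build_neuron_signature(list(sig), groups, K)
      types[[tid]] <- list(
        type_id = tid, kind = "point", comps = comps, n_comp = 1L,
        groups = groups, comp_sigs = list(sig), nsig = nsig,
        dynamics = dyn,
        syn_kinds = fb_kind_registry(groups, comps, doc, "syn"),
        input_kinds = fb_kind_registry(groups, comps, doc, "input"))
    }
  }
  structure(list(network = net$id, net = net, plan = plan, types = types,
                 K = K, doc = doc),
            class = "fb_analysis")
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' Signature of one compartment: compartment base (state v, constants C and
#' axial conductance, conductance/driving-force accumulation) merged with the
#' channel-instance signatures found on it.
fb_comp_group_signature <- function(comp, doc) {
  base <- new_signature(
    id = "compartment",
    constants = list(list(name = "C", dim = "capacitance", default = NA_real_),
                     list(name = "ga", dim = "conductance", default = NA_real_)),
    states = list(v = list(name = "v", dim = "voltage", init = NULL,
                           tau_sym = NULL, inf_sym = NULL)),
    requirements = c(isyn = "current"),
    exposures = c(v = "v"),
    update_statements = list(list(state = "v", method = "cable",
                                  deriv = NULL, tau = NULL, inf = NULL)),
    meta = list(kind = "compartment"))
  chans <- list()
  for (m in comp$mechanisms) {
    chans[[m$id]] <- fb_channel_signature(m$id, doc$ion_channels[[m$channel]])
  }
  if (length(chans) == 0L) {
    base$eval_statements <- list(
      list(target = "Gtot", expr = quote(0)),
      list(target = "GE", expr = quote(0)))
    return(base)
  }
  gsum <- NULL; gesum <- NULL
  bindings <- character(0)
  for (nm in names(chans)) {
    gsym <- as.name(paste0(nm, "_g")); esym <- as.name(paste0(nm, "_erev"))
    gsum <- if (is.null(gsum)) gsym else bquote(.(gsum) + .(gsym))
    gesum <- if (is.null(gesum)) bquote(.(gsym) * .(esym))
             else bquote(.(gesum) + .(gsym) * .(esym))
    bindings[paste0(nm, ".v")] <- "v"
  }
  base$eval_statements <- list(
    list(target = "Gtot", expr = gsum),
    list(target = "GE", expr = gesum))
  merge_signatures(base, chans, bindings)
}

#' @keywords internal
#' Kind registry: one table-kind entry per (dedup group, synapse/input id)
#' present on that group's compartments.
fb_kind_registry <- function(groups, comps, doc, what) {
  reg <- list()
  for (gi in seq_along(groups)) {
    c0 <- comps[[groups[[gi]]$members[1] + 1L]]
    kinds <- if (what == "syn") c0$syn_kinds else c0$input_kinds
    for (kind in kinds) {
      if (startsWith(kind, "gap:")) {
        sid <- sub("^gap:", "", kind)
        dyn <- doc$synapse_types[[sid]]
        role <- "gap"
      } else if (what == "syn") {
        sid <- kind
        dyn <- doc$synapse_types[[sid]]
        role <- "event"
      } else {
        sid <- kind
        dyn <- doc$input_types[[sid]]
        role <- if (!is.null(dyn$poisson_fire)) "poisson" else "pulse"
      }
      key <- paste0(what, ":", kind, "@g", gi)
      reg[[key]] <- list(key = key, id = sid, dynamics = dyn, gi = gi,
                         role = role, kind = kind)
    }
  }
  reg
}
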