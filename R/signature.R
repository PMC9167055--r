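# Code/data signatures.
#
# A signature pairs the code needed to simulate a mechanism (ordered "eval"
# statements defining all assigned variables, per-state "update" rules tagged
# with an integrator, and event handlers) with the flat data it owns
# (constants, states, requirements, exposures and variable-sized table kinds).
# Signatures of child mechanisms are merged into compartment- and neuron-wide
# signatures; merging concatenates the data parts and topologically orders the
# eval code so every mechanism's requirements are evaluated before its own
# code runs.

#' @keywords internal
new_signature <- function(id = "",
                          constants = list(),
                          states = list(),
                          requirements = character(0),
                          exposures = character(0),
                          eval_statements = list(),
                          update_statements = list(),
                          event_handlers = list(),
                          tables_needed = list(),
                          meta = list()) {
  structure(list(
    id = id,
    constants = constants,          # list(name, dim, default)
    states = states,                # list(name, dim, init, tau_sym, inf_sym)
    requirements = requirements,    # named chr name -> dimension
    exposures = exposures,          # named chr exposure -> defining symbol
    eval_statements = eval_statements,   # list(target, expr)
    update_statements = update_statements, # list(state, method, deriv, tau, inf)
    event_handlers = event_handlers, # list(trigger, assignments, emits)
    tables_needed = tables_needed,  # named list of kind descriptors
    meta = meta
  ), class = "fb_signature")
}

#' Build the leaf signature of a single mechanism
#'
#' Translates a `dynamics_spec` into a signature: derived variables become
#' eval statements in dependency (DAG) order, time derivatives become update
#' statements (integrator chosen later), OnCondition / OnEvent blocks become
#' event handlers, and requirements/exposures are carried over.
#'
#' @param dynamics a `dynamics_spec`.
#' @return an `fb_signature`.
#' @export
build_leaf_signature <- function(dynamics) {
  constants <- lapply(names(dynamics$parameters), function(nm) {
    p <- dynamics$parameters[[nm]]
    list(name = nm, dim = p$dim, default = p$value)
  })
  # initial value: OnStart assignment wins over the state's own init field
  on_start_map <- list()
  for (os in dynamics$on_start) on_start_map[[os$var]] <- os$expr
  states <- lapply(names(dynamics$state_vars), function(nm) {
    sv <- dynamics$state_vars[[nm]]
    init <- if (!is.null(on_start_map[[nm]])) on_start_map[[nm]] else sv$init
    list(name = nm, dim = sv$dim, init = init, tau_sym = NULL, inf_sym = NULL)
  })
  names(states) <- names(dynamics$state_vars)
  evals <- lapply(names(dynamics$derived_vars), function(nm) {
    list(target = nm, expr = dynamics$derived_vars[[nm]])
  })
  updates <- lapply(names(dynamics$time_derivatives), function(nm) {
    list(state = nm, method = NA_character_,
         deriv = dynamics$time_derivatives[[nm]], tau = NULL, inf = NULL)
  })
  handlers <- list()
  for (oc in dynamics$on_conditions) {
    handlers[[length(handlers) + 1L]] <- list(
      trigger = list(kind = "condition", test = oc$test),
      assignments = oc$assignments, emits = oc$emits)
  }
  for (p in names(dynamics$on_events)) {
    handlers[[length(handlers) + 1L]] <- list(
      trigger = list(kind = "event", port = p),
      assignments = dynamics$on_events[[p]]$assignments, emits = character(0))
  }
  if (!is.null(dynamics$poisson_fire)) {
    handlers[[length(handlers) + 1L]] <- list(
      trigger = list(kind = "poisson",
                     rate_param = dynamics$poisson_fire$rate_param),
      assignments = dynamics$poisson_fire$assignments,
      emits = dynamics$poisson_fire$emits)
  }
  new_signature(
    id = dynamics$id, constants = constants, states = states,
    requirements = dynamics$requirements, exposures = dynamics$exposures,
    eval_statements = evals, update_statements = updates,
    event_handlers = handlers,
    meta = list(kind = dynamics$kind))
}

#' @keywords internal
#' Rename every symbol of a signature with `map` (named list old -> new
#' symbol name). Expressions are rewritten with the same map.
fb_sig_rename <- function(sig, map) {
  rn <- function(nm) if (!is.null(map[[nm]])) map[[nm]] else nm
  emap <- lapply(map, as.name)
  sig$constants <- lapply(sig$constants, function(c) { c$name <- rn(c$name); c })
  sig$states <- lapply(sig$states, function(s) {
    s$name <- rn(s$name)
    if (!is.null(s$init) && is.language(s$init)) s$init <- fb_expr_subst(s$init, emap)
    if (!is.null(s$tau_sym)) s$tau_sym <- rn(s$tau_sym)
    if (!is.null(s$inf_sym)) s$inf_sym <- rn(s$inf_sym)
    s
  })
  names(sig$states) <- vapply(sig$states, `[[`, character(1), "name")
  req <- sig$requirements
  names(req) <- vapply(names(req), rn, character(1))
  sig$requirements <- req
  exp <- sig$exposures
  sig$exposures <- stats::setNames(
    vapply(unname(exp), rn, character(1)),
    vapply(names(exp), rn, character(1)))
  sig$eval_statements <- lapply(sig$eval_statements, function(st) {
    st$target <- rn(st$target); st$expr <- fb_expr_subst(st$expr, emap); st
  })
  sig$update_statements <- lapply(sig$update_statements, function(st) {
    st$state <- rn(st$state)
    if (!is.null(st$deriv)) st$deriv <- fb_expr_subst(st$deriv, emap)
    if (!is.null(st$tau)) st$tau <- fb_expr_subst(st$tau, emap)
    if (!is.null(st$inf)) st$inf <- fb_expr_subst(st$inf, emap)
    st
  })
  sig$event_handlers <- lapply(sig$event_handlers, function(h) {
    if (!is.null(h$trigger$test)) h$trigger$test <- fb_expr_subst(h$trigger$test, emap)
    if (!is.null(h$trigger$rate_param)) h$trigger$rate_param <- rn(h$trigger$rate_param)
    h$assignments <- stats::setNames(
      lapply(h$assignments, fb_expr_subst, map = emap),
      vapply(names(h$assignments), rn, character(1)))
    h
  })
  sig
}

#' Merge mechanism signatures into a composite signature
#'
#' Children are namespaced with their instance names; `bindings` connects
#' child requirements to exposures of the parent or of siblings, written as
#' `"child.requirement" = "symbol"` where the symbol is either a parent
#' variable (unprefixed) or `"otherchild_exposure"`. Data signatures are
#' concatenated preserving per-mechanism contiguity; eval statements are
#' topologically ordered so each mechanism's requirements are defined and
#' evaluated before the mechanism's own evaluation code, with document order
#' as the tie-break; update statements are appended after all evals, in
#' mechanism order.
#'
#' @param parent an `fb_signature`.
#' @param children named list of `fb_signature`s.
#' @param bindings named character vector `"child.req" -> symbol`; parent
#'   requirements can be bound with key `"parent.req"`. Unbound requirements
#'   remain requirements of the merged result.
#' @return an `fb_signature`.
#' @export
merge_signatures <- function(parent, children = list(), bindings = character(0)) {
  mechs <- c(list(parent = parent), children)
  nm_mech <- names(mechs)
  renamed <- vector("list", length(mechs))
  bound_reqs <- vector("list", length(mechs))  # renamed names of bound reqs
  for (i in seq_along(mechs)) {
    m <- mechs[[i]]; mname <- nm_mech[i]
    prefix <- if (i == 1L) "" else paste0(mname, "_")
    map <- list()
    own <- c(vapply(m$constants, `[[`, character(1), "name"),
             vapply(m$states, `[[`, character(1), "name"),
             vapply(m$eval_statements, `[[`, character(1), "target"))
    for (s in own) map[[s]] <- paste0(prefix, s)
    # requirements: bound ones become the bound symbol, others are prefixed
    for (r in names(m$requirements)) {
      key <- paste0(mname, ".", r)
      if (key %in% names(bindings)) {
        tgt <- bindings[[key]]
        # binding targets in child namespaces use their prefixed symbol
        map[[r]] <- tgt
        bound_reqs[[i]] <- c(bound_reqs[[i]], tgt)
      } else if (i > 1L) {
        map[[r]] <- paste0(prefix, r)
      }
    }
    renamed[[i]] <- fb_sig_rename(m, map)
    renamed[[i]]$meta$mech_name <- mname
  }

  constants <- do.call(c, lapply(renamed, `[[`, "constants"))
  states <- do.call(c, lapply(renamed, `[[`, "states"))
  tables_needed <- do.call(c, lapply(renamed, `[[`, "tables_needed"))

  # merged requirements: those that were not satisfied by a binding
  requirements <- character(0)
  for (i in seq_along(renamed)) {
    for (r in names(renamed[[i]]$requirements)) {
      if (r %in% bound_reqs[[i]]) next
      requirements[r] <- renamed[[i]]$requirements[[r]]
    }
  }
  defined <- c(vapply(constants, `[[`, character(1), "name"),
               vapply(states, `[[`, character(1), "name"))
  all_evals <- list()
  for (i in seq_along(renamed)) {
    for (st in renamed[[i]]$eval_statements) {
      st$mech <- i
      all_evals[[length(all_evals) + 1L]] <- st
    }
  }
  targets <- vapply(all_evals, `[[`, character(1), "target")
  requirements <- requirements[!(names(requirements) %in% c(defined, targets))]
  given <- c(defined, names(requirements), "t", "dt", "weight")

  # check that every bound symbol exists
  for (key in names(bindings)) {
    tgt <- bindings[[key]]
    if (!(tgt %in% c(given, targets))) {
      fb_abort("UnboundRequirement", sprintf(
        "binding %s -> '%s' does not name an exposed or defined symbol",
        key, tgt))
    }
  }
  # any symbol read by an eval that is neither given nor a target is unbound
  for (st in all_evals) {
    missing <- setdiff(fb_expr_vars(st$expr), c(given, targets))
    if (length(missing) > 0L) {
      fb_abort("UnboundRequirement", sprintf(
        "eval of '%s' reads unbound symbol(s): %s",
        st$target, paste(missing, collapse = ", ")))
    }
  }

  # stable topological sort of eval statements
  n <- length(all_evals)
  if (n > 0L) {
    def_of <- stats::setNames(seq_len(n), targets)
    deps <- lapply(all_evals, function(st) {
      vs <- intersect(fb_expr_vars(st$expr), targets)
      unname(def_of[vs])
    })
    done <- logical(n)
    order <- integer(0)
    repeat {
      progressed <- FALSE
      for (k in seq_len(n)) {
        if (done[k]) next
        if (all(done[deps[[k]]])) {
          order <- c(order, k); done[k] <- TRUE; progressed <- TRUE
        }
      }
      if (all(done)) break
      if (!progressed) {
        fb_abort("CyclicExposureDependency", sprintf(
          "cyclic same-step dependency among: %s",
          paste(targets[!done], collapse = ", ")))
      }
    }
    all_evals <- all_evals[order]
  }

  updates <- do.call(c, lapply(renamed, `[[`, "update_statements"))
  handlers <- do.call(c, lapply(renamed, `[[`, "event_handlers"))

  exposures <- renamed[[1]]$exposures
  for (i in seq_along(renamed)[-1]) {
    ex <- renamed[[i]]$exposures
    names(ex) <- paste0(nm_mech[i], "_", names(renamed[[i]]$exposures))
    # values were already renamed by fb_sig_rename; exposure keys gain prefix
    exposures <- c(exposures, stats::setNames(unname(ex), names(ex)))
  }

  new_signature(
    id = paste0(parent$id, "+", paste(nm_mech[-1], collapse = "+")),
    constants = constants, states = states, requirements = requirements,
    exposures = exposures,
    eval_statements = lapply(all_evals, function(st) { st$mech <- NULL; st }),
    update_statements = updates, event_handlers = handlers,
    tables_needed = tables_needed,
    meta = list(kind = "merged", members = nm_mech))
}

#' @keywords internal
#' Well-formedness: every symbol read by an eval statement is a constant,
#' state, requirement or previously assigned variable.
fb_sig_check <- function(sig) {
  given <- c(vapply(sig$constants, `[[`, character(1), "name"),
             vapply(sig$states, `[[`, character(1), "name"),
             names(sig$requirements), "t", "dt", "weight")
  for (st in sig$eval_statements) {
    bad <- setdiff(fb_expr_vars(st$expr), given)
    if (length(bad) > 0L) return(FALSE)
    given <- c(given, st$target)
  }
  for (st in sig$update_statements) {
    exprs <- Filter(Negate(is.null), list(st$deriv, st$tau, st$inf))
    for (e in exprs) {
      if (length(setdiff(fb_expr_vars(e), given)) > 0L) return(FALSE)
    }
  }
  for (ex in names(sig$exposures)) {
    if (!(sig$exposures[[ex]] %in% given)) return(FALSE)
  }
  TRUE
}
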