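# DynamicsSpec: the parsed dynamics of one mechanism (cell, synapse or input
# component). Built-in NeuroML component types are expressed as DynamicsSpec
# templates so that custom LEMS components and standard types flow through the
# same analysis, code-generation and interpretation paths.

#' @keywords internal
new_dynamics_spec <- function(id,
                              parameters = list(),
                              requirements = character(0),
                              exposures = character(0),
                              state_vars = list(),
                              derived_vars = list(),
                              time_derivatives = list(),
                              on_start = list(),
                              on_conditions = list(),
                              on_events = list(),
                              event_ports_in = character(0),
                              event_ports_out = character(0),
                              poisson_fire = NULL,
                              kind = "generic") {
  spec <- structure(list(
    id = id,
    parameters = parameters,            # name -> list(dim, value SI or NA)
    requirements = requirements,        # named chr: name -> dimension
    exposures = exposures,              # named chr: exposure -> defining var
    state_vars = state_vars,            # name -> list(dim, init expr or NULL)
    derived_vars = derived_vars,        # ordered name -> expr (DAG order)
    time_derivatives = time_derivatives, # state -> expr
    on_start = on_start,                # list(list(var, expr))
    on_conditions = on_conditions,      # list(list(test, assignments, emits))
    on_events = on_events,              # port -> list(assignments)
    event_ports_in = event_ports_in,
    event_ports_out = event_ports_out,
    poisson_fire = poisson_fire,        # list(rate_param, assignments, emits)
    kind = kind                         # cell / synapse / input / gap / generic
  ), class = "dynamics_spec")
  fb_validate_dynamics(spec)
}

#' @keywords internal
#' Topologically order derived variables and check that every expression only
#' references declared symbols. Raises CyclicDerivedVariables /
#' UnresolvedReference.
fb_validate_dynamics <- function(spec) {
  dnames <- names(spec$derived_vars)
  known <- c(names(spec$parameters), names(spec$requirements),
             names(spec$state_vars), dnames, "t", "dt", "weight")
  # DAG order over derived variables
  if (length(dnames) > 0L) {
    deps <- lapply(spec$derived_vars, function(e) {
      intersect(fb_expr_vars(e), dnames)
    })
    order <- character(0)
    remaining <- dnames
    while (length(remaining) > 0L) {
      ready <- remaining[vapply(remaining, function(n) {
        all(deps[[n]] %in% order)
      }, logical(1))]
      if (length(ready) == 0L) {
        fb_abort("CyclicDerivedVariables", sprintf(
          "derived variables of '%s' contain a cycle involving: %s",
          spec$id, paste(remaining, collapse = ", ")))
      }
      order <- c(order, ready)
      remaining <- setdiff(remaining, ready)
    }
    # keep first-declaration tie-break: stable order among ready sets is the
    # declaration order because `remaining` preserves it
    spec$derived_vars <- spec$derived_vars[order]
  }
  check_syms <- function(e, where) {
    bad <- setdiff(fb_expr_vars(e), known)
    if (length(bad) > 0L) {
      fb_abort("UnresolvedReference", sprintf(
        "undeclared symbol(s) %s in %s of '%s'",
        paste(sprintf("'%s'", bad), collapse = ", "), where, spec$id))
    }
  }
  for (nm in names(spec$derived_vars)) {
    check_syms(spec$derived_vars[[nm]], sprintf("derived variable '%s'", nm))
  }
  for (nm in names(spec$time_derivatives)) {
    if (!(nm %in% names(spec$state_vars))) {
      fb_abort("UnresolvedReference", sprintf(
        "time derivative of undeclared state '%s' in '%s'", nm, spec$id))
    }
    check_syms(spec$time_derivatives[[nm]], sprintf("d%s/dt", nm))
  }
  for (oc in spec$on_conditions) {
    check_syms(oc$test, "OnCondition test")
    for (a in names(oc$assignments)) check_syms(oc$assignments[[a]], "OnCondition assignment")
  }
  for (p in names(spec$on_events)) {
    for (a in names(spec$on_events[[p]]$assignments)) {
      check_syms(spec$on_events[[p]]$assignments[[a]], "OnEvent assignment")
    }
  }
  # every exposure resolves to a state or derived (or parameter) variable
  for (ex in names(spec$exposures)) {
    v <- spec$exposures[[ex]]
    if (!(v %in% c(names(spec$state_vars), names(spec$derived_vars),
                   names(spec$parameters)))) {
      fb_abort("UnresolvedReference", sprintf(
        "exposure '%s' of '%s' resolves to undeclared variable '%s'",
        ex, spec$id, v))
    }
  }
  spec
}

#' Parse a LEMS ComponentType into a DynamicsSpec
#'
#' Supports the LEMS subset: Parameter, Constant, Requirement, Exposure,
#' EventPort, and a Dynamics block with StateVariable, DerivedVariable,
#' TimeDerivative, OnStart, OnCondition and OnEvent. KineticScheme and Regime
#' blocks are outside the subset and raise `UnsupportedLemsFeature`.
#'
#' @param node an `xml2` node for `<ComponentType>`, or an XML string.
#' @return a `dynamics_spec` object.
#' @export
parse_dynamics <- function(node) {
  if (is.character(node)) node <- xml2::read_xml(node)
  if (inherits(node, "xml_document")) node <- xml2::xml_root(node)
  id <- xml2::xml_attr(node, "name")

  grab <- function(xpath) xml2::xml_find_all(node, xpath)

  parameters <- list()
  for (p in grab("./Parameter|./Constant")) {
    nm <- xml2::xml_attr(p, "name")
    val <- xml2::xml_attr(p, "value")
    parameters[[nm]] <- list(
      dim = xml2::xml_attr(p, "dimension"),
      value = if (is.na(val)) NA_real_ else as.double(to_si(val))
    )
  }
  requirements <- character(0)
  for (r in grab("./Requirement")) {
    requirements[[xml2::xml_attr(r, "name")]] <- xml2::xml_attr(r, "dimension")
  }
  exposures_raw <- character(0)
  for (e in grab("./Exposure")) {
    exposures_raw <- c(exposures_raw, xml2::xml_attr(e, "name"))
  }
  event_in <- character(0); event_out <- character(0)
  for (ep in grab("./EventPort")) {
    if (identical(xml2::xml_attr(ep, "direction"), "in")) {
      event_in <- c(event_in, xml2::xml_attr(ep, "name"))
    } else {
      event_out <- c(event_out, xml2::xml_attr(ep, "name"))
    }
  }

  dyn <- grab("./Dynamics")
  if (length(dyn) == 0L) {
    fb_abort("UnsupportedLemsFeature",
             sprintf("ComponentType '%s' has no Dynamics block", id))
  }
  dyn <- dyn[[1]]
  for (bad in c("KineticScheme", "Regime")) {
    if (length(xml2::xml_find_all(dyn, paste0(".//", bad))) > 0L) {
      fb_abort("UnsupportedLemsFeature",
               sprintf("LEMS %s in '%s' is not supported", bad, id))
    }
  }

  state_vars <- list()
  for (s in xml2::xml_find_all(dyn, "./StateVariable")) {
    state_vars[[xml2::xml_attr(s, "name")]] <- list(
      dim = xml2::xml_attr(s, "dimension"), init = NULL)
  }
  derived_vars <- list()
  for (d in xml2::xml_find_all(dyn, "./DerivedVariable")) {
    val <- xml2::xml_attr(d, "value")
    if (is.na(val)) {
      fb_abort("UnsupportedLemsFeature", sprintf(
        "DerivedVariable '%s' of '%s' without value attribute (select/reduce unsupported)",
        xml2::xml_attr(d, "name"), id))
    }
    derived_vars[[xml2::xml_attr(d, "name")]] <- fb_parse_expr(val)
  }
  time_derivatives <- list()
  for (td in xml2::xml_find_all(dyn, "./TimeDerivative")) {
    time_derivatives[[xml2::xml_attr(td, "variable")]] <-
      fb_parse_expr(xml2::xml_attr(td, "value"))
  }
  on_start <- list()
  for (os in xml2::xml_find_all(dyn, "./OnStart/StateAssignment")) {
    on_start[[length(on_start) + 1L]] <- list(
      var = xml2::xml_attr(os, "variable"),
      expr = fb_parse_expr(xml2::xml_attr(os, "value")))
  }
  on_conditions <- list()
  for (oc in xml2::xml_find_all(dyn, "./OnCondition")) {
    assignments <- list()
    for (sa in xml2::xml_find_all(oc, "./StateAssignment")) {
      assignments[[xml2::xml_attr(sa, "variable")]] <-
        fb_parse_expr(xml2::xml_attr(sa, "value"))
    }
    emits <- vapply(xml2::xml_find_all(oc, "./EventOut"), function(e) {
      xml2::xml_attr(e, "port")
    }, character(1))
    on_conditions[[length(on_conditions) + 1L]] <- list(
      test = fb_parse_expr(xml2::xml_attr(oc, "test")),
      assignments = assignments, emits = emits)
  }
  on_events <- list()
  for (oe in xml2::xml_find_all(dyn, "./OnEvent")) {
    assignments <- list()
    for (sa in xml2::xml_find_all(oe, "./StateAssignment")) {
      assignments[[xml2::xml_attr(sa, "variable")]] <-
        fb_parse_expr(xml2::xml_attr(sa, "value"))
    }
    on_events[[xml2::xml_attr(oe, "port")]] <- list(assignments = assignments)
  }

  # exposures resolve to the variable of the same name
  exposures <- stats::setNames(exposures_raw, exposures_raw)

  new_dynamics_spec(
    id = id, parameters = parameters, requirements = requirements,
    exposures = exposures, state_vars = state_vars,
    derived_vars = derived_vars, time_derivatives = time_derivatives,
    on_start = on_start, on_conditions = on_conditions, on_events = on_events,
    event_ports_in = event_in, event_ports_out = event_out,
    kind = "generic")
}

# ---------------------------------------------------------------------------
# Built-in NeuroML component types as DynamicsSpec templates
# ---------------------------------------------------------------------------

#' @keywords internal
#' Numeric SI value of a required XML attribute.
fb_attr_si <- function(attrs, name, default = NULL) {
  v <- attrs[[name]]
  if (is.null(v) || is.na(v)) {
    if (!is.null(default)) return(default)
    fb_abort("UnresolvedReference", sprintf("missing attribute '%s'", name))
  }
  as.double(to_si(v))
}

#' @keywords internal
#' Build the DynamicsSpec for a built-in NeuroML component element.
#' `attrs` is a named character vector of XML attributes (including `id`).
fb_builtin_dynamics <- function(tag, attrs) {
  id <- attrs[["id"]]
  P <- function(name, default = NULL) fb_attr_si(attrs, name, default)
  par <- function(...) {
    vals <- list(...)
    lapply(vals, function(v) list(dim = NA_character_, value = v))
  }
  switch(tag,
    "izhikevichCell" = {
      # Phenomenological 2003 model; v in volts internally, equation in
      # mV/ms with synaptic current taken in nA.
      new_dynamics_spec(id,
        parameters = par(v0 = P("v0"), thresh = P("thresh"),
                         a = P("a"), b = P("b"), c = P("c"), d = P("d")),
        requirements = c(iSyn = "current"),
        exposures = c(v = "v", U = "U"),
        state_vars = list(v = list(dim = "voltage", init = quote(v0)),
                          U = list(dim = "none",
                                   init = quote(b * (v0 * 1000)))),
        time_derivatives = list(
          v = quote((0.04 * (v * 1000)^2 + 5 * (v * 1000) + 140 - U +
                       iSyn * 1e9)),
          U = quote(a * (b * (v * 1000) - U) * 1000)),
        on_conditions = list(list(
          test = quote(v >= thresh),
          assignments = list(v = quote(c), U = quote(U + d)),
          emits = "spike")),
        event_ports_out = "spike", kind = "cell")
    },
    "izhikevich2007Cell" = {
      new_dynamics_spec(id,
        parameters = par(v0 = P("v0"), k = P("k"), vr = P("vr"), vt = P("vt"),
                         vpeak = P("vpeak"), a = P("a"), b = P("b"),
                         c = P("c"), d = P("d"), C = P("C")),
        requirements = c(iSyn = "current"),
        exposures = c(v = "v", u = "u"),
        state_vars = list(v = list(dim = "voltage", init = quote(v0)),
                          u = list(dim = "current", init = quote(0))),
        time_derivatives = list(
          v = quote((k * (v - vr) * (v - vt) - u + iSyn) / C),
          u = quote(a * (b * (v - vr) - u))),
        on_conditions = list(list(
          test = quote(v > vpeak),
          assignments = list(v = quote(c), u = quote(u + d)),
          emits = "spike")),
        event_ports_out = "spike", kind = "cell")
    },
    "iafTauCell" = {
      new_dynamics_spec(id,
        parameters = par(leakReversal = P("leakReversal"), thresh = P("thresh"),
                         reset = P("reset"), tau = P("tau")),
        exposures = c(v = "v"),
        state_vars = list(v = list(dim = "voltage", init = quote(leakReversal))),
        time_derivatives = list(v = quote((leakReversal - v) / tau)),
        on_conditions = list(list(
          test = quote(v > thresh),
          assignments = list(v = quote(reset)), emits = "spike")),
        event_ports_out = "spike", kind = "cell")
    },
    "iafCell" = {
      new_dynamics_spec(id,
        parameters = par(leakReversal = P("leakReversal"), thresh = P("thresh"),
                         reset = P("reset"), C = P("C"),
                         leakConductance = P("leakConductance")),
        requirements = c(iSyn = "current"),
        exposures = c(v = "v"),
        state_vars = list(v = list(dim = "voltage", init = quote(leakReversal))),
        time_derivatives = list(
          v = quote((leakConductance * (leakReversal - v) + iSyn) / C)),
        on_conditions = list(list(
          test = quote(v > thresh),
          assignments = list(v = quote(reset)), emits = "spike")),
        event_ports_out = "spike", kind = "cell")
    },
    "adExIaFCell" = {
      new_dynamics_spec(id,
        parameters = par(C = P("C"), gL = P("gL"), EL = P("EL"),
                         reset = P("reset"), VT = P("VT"), thresh = P("thresh"),
                         delT = P("delT"), tauw = P("tauw"),
                         a = P("a"), b = P("b")),
        requirements = c(iSyn = "current"),
        exposures = c(v = "v", w = "w"),
        state_vars = list(v = list(dim = "voltage", init = quote(EL)),
                          w = list(dim = "current", init = quote(0))),
        time_derivatives = list(
          v = quote((-gL * (v - EL) + gL * delT * exp((v - VT) / delT) - w +
                       iSyn) / C),
          w = quote((a * (v - EL) - w) / tauw)),
        on_conditions = list(list(
          test = quote(v > thresh),
          assignments = list(v = quote(reset), w = quote(w + b)),
          emits = "spike")),
        event_ports_out = "spike", kind = "cell")
    },
    "expOneSynapse" = {
      new_dynamics_spec(id,
        parameters = par(gbase = P("gbase"), erev = P("erev"),
                         tauDecay = P("tauDecay")),
        requirements = c(v = "voltage"),
        exposures = c(i = "i", g = "g"),
        state_vars = list(g = list(dim = "conductance", init = quote(0))),
        derived_vars = list(i = quote(g * (erev - v))),
        time_derivatives = list(g = quote(-g / tauDecay)),
        on_events = list("in" = list(assignments = list(
          g = quote(g + weight * gbase)))),
        event_ports_in = "in", kind = "synapse")
    },
    "expTwoSynapse" = {
      tauRise <- P("tauRise"); tauDecay <- P("tauDecay")
      tp <- (tauRise * tauDecay / (tauDecay - tauRise)) * log(tauDecay / tauRise)
      wf <- 1 / (-exp(-tp / tauRise) + exp(-tp / tauDecay))
      new_dynamics_spec(id,
        parameters = par(gbase = P("gbase"), erev = P("erev"),
                         tauRise = tauRise, tauDecay = tauDecay,
                         waveformFactor = wf),
        requirements = c(v = "voltage"),
        exposures = c(i = "i", g = "g"),
        state_vars = list(A = list(dim = "none", init = quote(0)),
                          B = list(dim = "none", init = quote(0))),
        derived_vars = list(g = quote(gbase * (B - A)),
                            i = quote(g * (erev - v))),
        time_derivatives = list(A = quote(-A / tauRise),
                                B = quote(-B / tauDecay)),
        on_events = list("in" = list(assignments = list(
          A = quote(A + weight * waveformFactor),
          B = quote(B + weight * waveformFactor)))),
        event_ports_in = "in", kind = "synapse")
    },
    "gapJunction" = {
      new_dynamics_spec(id,
        parameters = par(conductance = P("conductance")),
        requirements = c(v = "voltage", vpeer = "voltage"),
        exposures = c(i = "i"),
        derived_vars = list(i = quote(conductance * (vpeer - v))),
        kind = "gap")
    },
    "pulseGenerator" = {
      new_dynamics_spec(id,
        parameters = par(delay = P("delay"), duration = P("duration"),
                         amplitude = P("amplitude")),
        exposures = c(i = "i"),
        derived_vars = list(
          i = quote(amplitude * (t >= delay) * (t < delay + duration))),
        kind = "input")
    },
    "spikeGeneratorPoisson" = {
      new_dynamics_spec(id,
        parameters = par(averageRate = P("averageRate")),
        exposures = c(v = "v"),
        state_vars = list(v = list(dim = "voltage", init = quote(0))),
        poisson_fire = list(rate_param = "averageRate", assignments = list(),
                            emits = "spike"),
        event_ports_out = "spike", kind = "cell")
    },
    "poissonFiringSynapse" = {
      new_dynamics_spec(id,
        parameters = par(averageRate = P("averageRate"), gbase = P("gbase"),
                         erev = P("erev"), tauDecay = P("tauDecay")),
        requirements = c(v = "voltage"),
        exposures = c(i = "i"),
        state_vars = list(g = list(dim = "conductance", init = quote(0))),
        derived_vars = list(i = quote(g * (erev - v))),
        time_derivatives = list(g = quote(-g / tauDecay)),
        poisson_fire = list(rate_param = "averageRate",
                            assignments = list(g = quote(g + gbase)),
                            emits = character(0)),
        kind = "input")
    },
    fb_abort("UnsupportedElement", sprintf("unsupported element <%s>", tag))
  )
}

#' @keywords internal
#' The parameter value (SI) of a DynamicsSpec, error if absent.
fb_param <- function(spec, name) {
  p <- spec$parameters[[name]]
  if (is.null(p) || is.na(p$value)) {
    fb_abort("UnresolvedReference",
             sprintf("parameter '%s' of '%s' has no value", name, spec$id))
  }
  p$value
}
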