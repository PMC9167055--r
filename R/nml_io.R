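# NeuroML v2 / LEMS document I/O.
#
# The supported subset (documented in the package vignette) covers point cells
# (izhikevichCell, izhikevich2007Cell, iafCell, iafTauCell, adExIaFCell),
# morphological cells with HH-style channel densities, expOne/expTwo event
# synapses, gap junctions, pulse and Poisson inputs, size- and instance-based
# populations, chemical and electrical projections, and input lists. Anything
# else raises UnsupportedElement; purely descriptive elements (notes,
# annotations, properties) are skipped with a warning.

.fb_ignorable_tags <- c("notes", "annotation", "property", "comment")

.fb_cell_tags <- c("izhikevichCell", "izhikevich2007Cell", "iafCell",
                   "iafTauCell", "adExIaFCell", "spikeGeneratorPoisson")
.fb_synapse_tags <- c("expOneSynapse", "expTwoSynapse", "gapJunction")
.fb_input_tags <- c("pulseGenerator", "poissonFiringSynapse")

#' @keywords internal
new_model_document <- function() {
  structure(list(
    component_types = list(),   # custom LEMS ComponentType -> dynamics_spec
    cell_types = list(),        # id -> point/morph cell definition
    synapse_types = list(),     # id -> dynamics_spec
    input_types = list(),       # id -> dynamics_spec
    ion_channels = list(),      # id -> channel spec (gates)
    networks = list(),          # id -> network
    component_instances = list() # id -> list(type = ComponentType name, attrs)
  ), class = "model_document")
}

#' Parse NeuroML/LEMS documents into an object model
#'
#' Reads one or more NeuroML v2 / LEMS XML files (or a single XML string) and
#' returns a fully resolved `model_document`. `<Include>` chains are followed
#' (relative to the including file) and must be acyclic. Every reference (cell
#' type, synapse type, population, connection endpoint, segment) is checked;
#' an unresolved id raises `UnresolvedReference`, an element outside the
#' supported subset raises `UnsupportedElement`.
#'
#' @param paths character vector of file paths, or one string of raw XML.
#' @return a `model_document`.
#' @export
parse_model <- function(paths) {
  nodes <- fb_collect_nodes(paths)
  doc <- new_model_document()

  # pass 1: component types (custom LEMS), ion channels, cells, synapses,
  # inputs
  for (nd in nodes) {
    tag <- xml2::xml_name(nd)
    if (tag %in% .fb_ignorable_tags) next
    if (tag == "ComponentType") {
      spec <- parse_dynamics(nd)
      doc$component_types[[spec$id]] <- spec
    }
  }
  for (nd in nodes) {
    tag <- xml2::xml_name(nd)
    attrs <- as.list(xml2::xml_attrs(nd))
    if (tag %in% .fb_ignorable_tags || tag == "ComponentType") next
    if (tag %in% c("ionChannelHH", "ionChannel")) {
      ch <- fb_parse_ion_channel(nd)
      doc$ion_channels[[ch$id]] <- ch
    } else if (tag %in% .fb_cell_tags) {
      dy <- fb_builtin_dynamics(tag, attrs)
      doc$cell_types[[attrs$id]] <- list(kind = "point", tag = tag,
                                         attrs = attrs, dynamics = dy)
    } else if (tag == "cell") {
      doc$cell_types[[attrs$id]] <- fb_parse_morph_cell(nd)
    } else if (tag %in% .fb_synapse_tags) {
      doc$synapse_types[[attrs$id]] <- fb_builtin_dynamics(tag, attrs)
      attr(doc$synapse_types[[attrs$id]], "attrs") <- attrs
    } else if (tag %in% .fb_input_tags) {
      if (tag == "poissonFiringSynapse" && !is.null(attrs$synapse)) {
        # inline the referenced synapse's kinetics (resolved in pass 3)
        doc$input_types[[attrs$id]] <- list(pending = TRUE, tag = tag,
                                            attrs = attrs)
      } else {
        doc$input_types[[attrs$id]] <- fb_builtin_dynamics(tag, attrs)
        attr(doc$input_types[[attrs$id]], "attrs") <- attrs
      }
    } else if (tag == "network") {
      # handled in pass 3
    } else if (tag == "Simulation" || tag == "Target") {
      # handled by load_simulation
    } else if (!is.null(doc$component_types[[tag]])) {
      # instance of a custom LEMS component type
      doc$component_instances[[attrs$id]] <- list(type = tag, attrs = attrs)
    } else {
      fb_abort("UnsupportedElement", sprintf("unsupported element <%s>", tag))
    }
  }

  # pass 2b: custom component instances become point cell types with the
  # component type's dynamics specialised by the instance's parameter values
  for (id in names(doc$component_instances)) {
    inst <- doc$component_instances[[id]]
    ct <- doc$component_types[[inst$type]]
    dy <- ct
    dy$id <- id
    for (nm in names(inst$attrs)) {
      if (nm %in% c("id")) next
      if (!is.null(dy$parameters[[nm]])) {
        dy$parameters[[nm]]$value <- as.double(to_si(inst$attrs[[nm]]))
      }
    }
    dy$kind <- "cell"
    doc$cell_types[[id]] <- list(kind = "point", tag = inst$type,
                                 attrs = inst$attrs, dynamics = dy)
  }

  # resolve pending poissonFiringSynapse synapse references
  for (id in names(doc$input_types)) {
    it <- doc$input_types[[id]]
    if (is.list(it) && isTRUE(it$pending)) {
      syn <- doc$synapse_types[[it$attrs$synapse]]
      if (is.null(syn)) {
        fb_abort("UnresolvedReference", sprintf(
          "poissonFiringSynapse '%s' references undefined synapse '%s'",
          id, it$attrs$synapse))
      }
      sa <- attr(syn, "attrs")
      merged <- it$attrs
      merged$gbase <- sa$gbase; merged$erev <- sa$erev
      merged$tauDecay <- sa$tauDecay
      doc$input_types[[id]] <- fb_builtin_dynamics("poissonFiringSynapse", merged)
      attr(doc$input_types[[id]], "attrs") <- merged
    }
  }

  # pass 3: networks
  for (nd in nodes) {
    if (xml2::xml_name(nd) == "network") {
      net <- fb_parse_network(nd, doc)
      doc$networks[[net$id]] <- net
    }
  }
  doc
}

#' @keywords internal
#' TRUE if an xml_find_first() result is an actual node.
fb_node_exists <- function(nd) {
  !inherits(nd, "xml_missing") && length(nd) > 0L
}

#' @keywords internal
#' Read an XML file or string and strip namespaces so the supported subset can
#' be addressed with plain XPath regardless of the document's xmlns.
fb_read_xml <- function(x) {
  d <- xml2::read_xml(x)
  xml2::xml_ns_strip(d)
  d
}

#' @keywords internal
#' Read files (following <Include>), return all second-level element nodes.
fb_collect_nodes <- function(paths, seen = character(0)) {
  out <- list()
  if (length(paths) == 1L && grepl("^\\s*<", paths[[1]])) {
    roots <- list(xml2::xml_root(fb_read_xml(paths[[1]])))
    dirs <- "."
  } else {
    roots <- list(); dirs <- character(0)
    for (p in paths) {
      np <- normalizePath(p, mustWork = TRUE)
      if (np %in% seen) next
      seen <- c(seen, np)
      roots[[length(roots) + 1L]] <- xml2::xml_root(fb_read_xml(np))
      dirs <- c(dirs, dirname(np))
    }
  }
  for (k in seq_along(roots)) {
    for (ch in xml2::xml_children(roots[[k]])) {
      tag <- xml2::xml_name(ch)
      if (tag %in% c("Include", "include")) {
        f <- xml2::xml_attr(ch, "file")
        if (is.na(f)) f <- xml2::xml_attr(ch, "href")
        inc <- file.path(dirs[[k]], f)
        npi <- normalizePath(inc, mustWork = TRUE)
        if (npi %in% seen) {
          fb_abort("UnsupportedElement",
                   sprintf("cyclic or repeated <Include> of '%s'", f))
        }
        sub <- fb_collect_nodes(inc, seen = seen)
        seen <- c(seen, npi)
        out <- c(out, sub)
      } else {
        out[[length(out) + 1L]] <- ch
      }
    }
  }
  out
}

# ---------------------------------------------------------------------------
# ion channels and morphological cells
# ---------------------------------------------------------------------------

#' @keywords internal
fb_parse_rate <- function(nd) {
  type <- xml2::xml_attr(nd, "type")
  a <- as.list(xml2::xml_attrs(nd))
  if (grepl("fixedTimeCourse", type)) {
    return(list(type = "fixed", tau = as.double(to_si(a$tau))))
  }
  base <- if (grepl("ExpLinear", type)) "explinear"
          else if (grepl("Sigmoid", type)) "sigmoid"
          else if (grepl("Exp", type)) "exp"
          else fb_abort("UnsupportedElement",
                        sprintf("unsupported rate type '%s'", type))
  list(type = base,
       rate = as.double(to_si(a$rate)),
       midpoint = as.double(to_si(a$midpoint)),
       scale = as.double(to_si(a$scale)))
}

#' @keywords internal
#' AST for a rate function evaluated at symbol `v`. Values are baked in as SI
#' literals so the same AST serves codegen and interpretation.
fb_rate_ast <- function(r) {
  v <- quote(v)
  switch(r$type,
    "fixed" = r$tau,
    "exp" = bquote(.(r$rate) * exp((v - .(r$midpoint)) / .(r$scale))),
    "sigmoid" = bquote(.(r$rate) / (1 + exp((.(r$midpoint) - v) / .(r$scale)))),
    "explinear" = bquote(.(r$rate) *
                           hh_explinear((v - .(r$midpoint)) / .(r$scale))))
}

#' @keywords internal
fb_parse_ion_channel <- function(nd) {
  id <- xml2::xml_attr(nd, "id")
  gates <- list()
  for (g in xml2::xml_find_all(nd, "./gateHHrates|./gateHHtauInf|./gate")) {
    gname <- xml2::xml_attr(g, "id")
    inst <- as.integer(xml2::xml_attr(g, "instances"))
    if (is.na(inst)) inst <- 1L
    fw <- xml2::xml_find_first(g, "./forwardRate")
    rv <- xml2::xml_find_first(g, "./reverseRate")
    tc <- xml2::xml_find_first(g, "./timeCourse")
    ss <- xml2::xml_find_first(g, "./steadyState")
    if (fb_node_exists(fw)) {
      gates[[gname]] <- list(name = gname, instances = inst, form = "rates",
                             forward = fb_parse_rate(fw),
                             reverse = fb_parse_rate(rv))
    } else if (fb_node_exists(tc) ||
               fb_node_exists(ss)) {
      gates[[gname]] <- list(name = gname, instances = inst, form = "tauInf",
                             timeCourse = fb_parse_rate(tc),
                             steadyState = fb_parse_rate(ss))
    } else {
      fb_abort("UnsupportedElement",
               sprintf("gate '%s' of channel '%s' has no supported rate form",
                       gname, id))
    }
  }
  list(id = id, gates = gates)
}

#' @keywords internal
fb_parse_morph_cell <- function(nd) {
  id <- xml2::xml_attr(nd, "id")
  morph <- xml2::xml_find_first(nd, "./morphology")
  if (!fb_node_exists(morph)) {
    fb_abort("MissingBiophysics", sprintf("cell '%s' has no morphology", id))
  }
  segs <- xml2::xml_find_all(morph, "./segment")
  n <- length(segs)
  seg_df <- data.frame(
    id = integer(n), name = character(n), parent = integer(n),
    px = double(n), py = double(n), pz = double(n), pd = double(n),
    dx = double(n), dy = double(n), dz = double(n), dd = double(n),
    has_prox = logical(n), stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    s <- segs[[k]]
    seg_df$id[k] <- as.integer(xml2::xml_attr(s, "id"))
    nmv <- xml2::xml_attr(s, "name")
    seg_df$name[k] <- if (is.na(nmv)) "" else nmv
    par <- xml2::xml_find_first(s, "./parent")
    seg_df$parent[k] <- if (!fb_node_exists(par))
      -1L else as.integer(xml2::xml_attr(par, "segment"))
    prox <- xml2::xml_find_first(s, "./proximal")
    dist <- xml2::xml_find_first(s, "./distal")
    seg_df$has_prox[k] <- fb_node_exists(prox)
    if (seg_df$has_prox[k]) {
      seg_df$px[k] <- as.double(xml2::xml_attr(prox, "x"))
      seg_df$py[k] <- as.double(xml2::xml_attr(prox, "y"))
      seg_df$pz[k] <- as.double(xml2::xml_attr(prox, "z"))
      seg_df$pd[k] <- as.double(xml2::xml_attr(prox, "diameter"))
    }
    seg_df$dx[k] <- as.double(xml2::xml_attr(dist, "x"))
    seg_df$dy[k] <- as.double(xml2::xml_attr(dist, "y"))
    seg_df$dz[k] <- as.double(xml2::xml_attr(dist, "z"))
    seg_df$dd[k] <- as.double(xml2::xml_attr(dist, "diameter"))
  }
  groups <- list()
  for (g in xml2::xml_find_all(morph, "./segmentGroup")) {
    gid <- xml2::xml_attr(g, "id")
    members <- as.integer(vapply(xml2::xml_find_all(g, "./member"),
                                 function(m) xml2::xml_attr(m, "segment"),
                                 character(1)))
    incl <- vapply(xml2::xml_find_all(g, "./include"),
                   function(m) xml2::xml_attr(m, "segmentGroup"), character(1))
    groups[[gid]] <- list(members = members, includes = incl)
  }
  # flatten group includes
  flat <- function(gid, seen = character(0)) {
    if (gid %in% seen) {
      fb_abort("CyclicMorphology",
               sprintf("segmentGroup include cycle at '%s'", gid))
    }
    g <- groups[[gid]]
    if (is.null(g)) {
      fb_abort("UnresolvedReference",
               sprintf("segmentGroup '%s' not defined in cell '%s'", gid, id))
    }
    out <- g$members
    for (ic in g$includes) out <- c(out, flat(ic, c(seen, gid)))
    unique(out)
  }
  group_members <- stats::setNames(
    lapply(names(groups), flat), names(groups))
  group_members[["all"]] <- seg_df$id

  bio <- xml2::xml_find_first(nd, "./biophysicalProperties")
  if (!fb_node_exists(bio)) {
    fb_abort("MissingBiophysics",
             sprintf("cell '%s' has no biophysicalProperties", id))
  }
  memb <- xml2::xml_find_first(bio, "./membraneProperties")
  dens <- list()
  for (cd in xml2::xml_find_all(memb, "./channelDensity")) {
    a <- as.list(xml2::xml_attrs(cd))
    dens[[length(dens) + 1L]] <- list(
      id = a$id, ion_channel = a$ionChannel,
      cond_density = as.double(to_si(a$condDensity)),
      erev = as.double(to_si(a$erev)),
      segment_group = if (is.null(a$segmentGroup)) "all" else a$segmentGroup)
  }
  gv <- function(xp, default = NULL) {
    e <- xml2::xml_find_first(memb, xp)
    if (!fb_node_exists(e)) return(default)
    as.double(to_si(xml2::xml_attr(e, "value")))
  }
  spike_thresh <- gv("./spikeThresh", default = -0.020)
  spec_cap <- gv("./specificCapacitance")
  init_v <- gv("./initMembPotential")
  if (is.null(spec_cap) || is.null(init_v)) {
    fb_abort("MissingBiophysics", sprintf(
      "cell '%s' lacks specificCapacitance or initMembPotential", id))
  }
  intra <- xml2::xml_find_first(bio, "./intracellularProperties/resistivity")
  resistivity <- if (!fb_node_exists(intra))
    1.0 else as.double(to_si(xml2::xml_attr(intra, "value")))

  list(kind = "morph", id = id, segments = seg_df,
       segment_groups = group_members,
       channel_densities = dens, spike_thresh = spike_thresh,
       specific_capacitance = spec_cap, init_v = init_v,
       resistivity = resistivity)
}

# ---------------------------------------------------------------------------
# networks
# ---------------------------------------------------------------------------

#' @keywords internal
#' Parse "pop[3]" / "../pop/3/type" / "pop/3" connection endpoint syntax into
#' list(population, index).
fb_parse_endpoint <- function(s) {
  s <- sub("^\\.\\./", "", s)
  m <- regmatches(s, regexec("^([A-Za-z0-9_.-]+)\\[([0-9]+)\\]$", s))[[1]]
  if (length(m) == 3L) {
    return(list(population = m[2], index = as.integer(m[3])))
  }
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(parts) >= 2L && grepl("^[0-9]+$", parts[2])) {
    return(list(population = parts[1], index = as.integer(parts[2])))
  }
  fb_abort("UnresolvedReference",
           sprintf("cannot parse connection endpoint '%s'", s))
}

#' @keywords internal
fb_parse_network <- function(nd, doc) {
  id <- xml2::xml_attr(nd, "id")
  populations <- list()
  for (p in xml2::xml_find_all(nd, "./population")) {
    a <- as.list(xml2::xml_attrs(p))
    comp <- a$component
    if (is.null(doc$cell_types[[comp]])) {
      fb_abort("UnresolvedReference", sprintf(
        "population '%s' references undefined cell type '%s'", a$id, comp))
    }
    inst_nodes <- xml2::xml_find_all(p, "./instance")
    if (length(inst_nodes) > 0L) {
      size <- length(inst_nodes)
    } else {
      size <- as.integer(a$size)
    }
    if (is.na(size) || size < 1L) {
      fb_abort("UnresolvedReference",
               sprintf("population '%s' must have size >= 1", a$id))
    }
    populations[[a$id]] <- list(id = a$id, component = comp, size = size)
  }
  resolve_pop <- function(pid, ctx) {
    if (is.null(populations[[pid]])) {
      fb_abort("UnresolvedReference", sprintf(
        "%s references undefined population '%s'", ctx, pid))
    }
    populations[[pid]]
  }
  frac_or <- function(v) if (is.null(v) || is.na(v)) 0.5 else as.double(v)
  seg_or <- function(v) if (is.null(v) || is.na(v)) 0L else as.integer(v)

  projections <- list()
  for (pr in xml2::xml_find_all(nd, "./projection")) {
    a <- as.list(xml2::xml_attrs(pr))
    syn <- a$synapse
    if (is.null(doc$synapse_types[[syn]])) {
      fb_abort("UnresolvedReference", sprintf(
        "projection '%s' references undefined synapse '%s'", a$id, syn))
    }
    pre_pop <- resolve_pop(a$presynapticPopulation, sprintf("projection '%s'", a$id))
    post_pop <- resolve_pop(a$postsynapticPopulation, sprintf("projection '%s'", a$id))
    conns <- xml2::xml_find_all(pr, "./connection|./connectionWD")
    m <- length(conns)
    cd <- data.frame(pre_cell = integer(m), pre_segment = integer(m),
                     pre_fraction = double(m), post_cell = integer(m),
                     post_segment = integer(m), post_fraction = double(m),
                     weight = double(m), delay = double(m))
    for (k in seq_len(m)) {
      c <- conns[[k]]
      ca <- as.list(xml2::xml_attrs(c))
      pre <- fb_parse_endpoint(ca$preCellId)
      post <- fb_parse_endpoint(ca$postCellId)
      cd$pre_cell[k] <- pre$index
      cd$post_cell[k] <- post$index
      cd$pre_segment[k] <- seg_or(ca$preSegmentId)
      cd$post_segment[k] <- seg_or(ca$postSegmentId)
      cd$pre_fraction[k] <- frac_or(ca$preFractionAlong)
      cd$post_fraction[k] <- frac_or(ca$postFractionAlong)
      cd$weight[k] <- if (is.null(ca$weight)) 1.0 else as.double(ca$weight)
      cd$delay[k] <- if (is.null(ca$delay)) 0.0 else as.double(to_si(ca$delay))
      if (cd$pre_cell[k] < 0L || cd$pre_cell[k] >= pre_pop$size ||
          cd$post_cell[k] < 0L || cd$post_cell[k] >= post_pop$size) {
        fb_abort("UnresolvedReference", sprintf(
          "connection %d of projection '%s' endpoint outside population", k, a$id))
      }
    }
    projections[[length(projections) + 1L]] <- list(
      id = a$id, presynaptic = pre_pop$id, postsynaptic = post_pop$id,
      synapse = syn, connections = cd)
  }

  electrical <- list()
  for (pr in xml2::xml_find_all(nd, "./electricalProjection")) {
    a <- as.list(xml2::xml_attrs(pr))
    pre_pop <- resolve_pop(a$presynapticPopulation,
                           sprintf("electricalProjection '%s'", a$id))
    post_pop <- resolve_pop(a$postsynapticPopulation,
                            sprintf("electricalProjection '%s'", a$id))
    conns <- xml2::xml_find_all(pr, "./electricalConnection|./electricalConnectionInstance")
    m <- length(conns)
    cd <- data.frame(pre_cell = integer(m), pre_segment = integer(m),
                     pre_fraction = double(m), post_cell = integer(m),
                     post_segment = integer(m), post_fraction = double(m),
                     synapse = character(m), stringsAsFactors = FALSE)
    for (k in seq_len(m)) {
      c <- conns[[k]]
      ca <- as.list(xml2::xml_attrs(c))
      pre <- fb_parse_endpoint(ca$preCell)
      post <- fb_parse_endpoint(ca$postCell)
      cd$pre_cell[k] <- pre$index; cd$post_cell[k] <- post$index
      cd$pre_segment[k] <- seg_or(ca$preSegment)
      cd$post_segment[k] <- seg_or(ca$postSegment)
      cd$pre_fraction[k] <- frac_or(ca$preFractionAlong)
      cd$post_fraction[k] <- frac_or(ca$postFractionAlong)
      cd$synapse[k] <- ca$synapse
      if (is.null(doc$synapse_types[[ca$synapse]])) {
        fb_abort("UnresolvedReference", sprintf(
          "electrical connection references undefined synapse '%s'", ca$synapse))
      }
      if (cd$pre_cell[k] >= pre_pop$size || cd$post_cell[k] >= post_pop$size) {
        fb_abort("UnresolvedReference", sprintf(
          "electrical connection %d of '%s' endpoint outside population", k, a$id))
      }
    }
    electrical[[length(electrical) + 1L]] <- list(
      id = a$id, presynaptic = pre_pop$id, postsynaptic = post_pop$id,
      connections = cd)
  }

  input_lists <- list()
  for (il in xml2::xml_find_all(nd, "./inputList")) {
    a <- as.list(xml2::xml_attrs(il))
    if (is.null(doc$input_types[[a$component]])) {
      fb_abort("UnresolvedReference", sprintf(
        "inputList '%s' references undefined input component '%s'",
        a$id, a$component))
    }
    pop <- resolve_pop(a$population, sprintf("inputList '%s'", a$id))
    ins <- xml2::xml_find_all(il, "./input")
    m <- length(ins)
    idf <- data.frame(target = integer(m), segment = integer(m),
                      fraction = double(m))
    for (k in seq_len(m)) {
      ia <- as.list(xml2::xml_attrs(ins[[k]]))
      tgt <- fb_parse_endpoint(ia$target)
      idf$target[k] <- tgt$index
      idf$segment[k] <- seg_or(ia$segmentId)
      idf$fraction[k] <- frac_or(ia$fractionAlong)
      if (idf$target[k] >= pop$size) {
        fb_abort("UnresolvedReference", sprintf(
          "input %d of inputList '%s' targets outside population", k, a$id))
      }
    }
    input_lists[[length(input_lists) + 1L]] <- list(
      id = a$id, component = a$component, population = pop$id, inputs = idf)
  }

  list(id = id, populations = populations, projections = projections,
       electrical_projections = electrical, input_lists = input_lists)
}

# ---------------------------------------------------------------------------
# simulation specs
# ---------------------------------------------------------------------------

#' Load a LEMS simulation file
#'
#' Reads a LEMS file containing a `<Simulation>` element (with `OutputFile` /
#' `EventOutputFile` children) plus the model documents it includes, and
#' returns both the parsed model and the bound simulation spec. Probe paths
#' are validated against the model.
#'
#' @param path path to the LEMS file (or raw XML string).
#' @return list with elements `model` (a `model_document`) and
#'   `spec` (a `simulation_spec`).
#' @export
load_simulation <- function(path) {
  model <- parse_model(path)
  if (length(path) == 1L && grepl("^\\s*<", path)) {
    root <- xml2::xml_root(fb_read_xml(path))
  } else {
    root <- xml2::xml_root(fb_read_xml(normalizePath(path, mustWork = TRUE)))
  }
  sim <- xml2::xml_find_first(root, ".//Simulation")
  if (!fb_node_exists(sim)) {
    fb_abort("MissingSimulation", "document contains no <Simulation> element")
  }
  a <- as.list(xml2::xml_attrs(sim))
  target_net <- a$target
  if (is.null(model$networks[[target_net]])) {
    fb_abort("UnresolvedReference", sprintf(
      "simulation targets undefined network '%s'", target_net))
  }
  duration <- as.double(to_si(a$length))
  dt <- as.double(to_si(a$step))
  if (dt <= 0 || duration < dt) {
    fb_abort("MissingSimulation", "require dt > 0 and duration >= dt")
  }
  seed <- if (is.null(a$seed)) 12345L else as.integer(a$seed)

  output_files <- list()
  for (of in xml2::xml_find_all(sim, "./OutputFile")) {
    oa <- as.list(xml2::xml_attrs(of))
    cols <- xml2::xml_find_all(of, "./OutputColumn")
    probes <- vapply(cols, function(c) xml2::xml_attr(c, "quantity"), character(1))
    for (p in probes) fb_validate_probe(p, model, target_net)
    output_files[[length(output_files) + 1L]] <- list(
      path = oa$fileName, probes = probes)
  }
  event_files <- list()
  for (ef in xml2::xml_find_all(sim, "./EventOutputFile")) {
    ea <- as.list(xml2::xml_attrs(ef))
    sels <- xml2::xml_find_all(ef, "./EventSelection")
    sources <- vapply(sels, function(s) xml2::xml_attr(s, "select"), character(1))
    for (s in sources) {
      ep <- fb_parse_endpoint(s)
      net <- model$networks[[target_net]]
      if (is.null(net$populations[[ep$population]]) ||
          ep$index >= net$populations[[ep$population]]$size) {
        fb_abort("UnresolvedProbePath",
                 sprintf("event selection '%s' does not resolve", s))
      }
    }
    event_files[[length(event_files) + 1L]] <- list(
      path = ea$fileName, sources = sources,
      format = if (is.null(ea$format)) "TIME_ID" else ea$format)
  }
  spec <- structure(list(
    target = target_net, duration = duration, dt = dt, seed = seed,
    output_files = output_files, event_files = event_files
  ), class = "simulation_spec")
  list(model = model, spec = spec)
}

#' @keywords internal
#' Validate a probe path "pop[i]/v" or "pop[i]/<segment>/v" against a model.
fb_validate_probe <- function(p, model, target_net) {
  pp <- fb_parse_probe(p)
  net <- model$networks[[target_net]]
  pop <- net$populations[[pp$population]]
  if (is.null(pop) || pp$index >= pop$size) {
    fb_abort("UnresolvedProbePath", sprintf("probe '%s' does not resolve", p))
  }
  ct <- model$cell_types[[pop$component]]
  if (ct$kind == "morph") {
    if (!(pp$segment %in% ct$segments$id)) {
      fb_abort("UnresolvedProbePath", sprintf(
        "probe '%s' names segment %d absent from cell '%s'",
        p, pp$segment, pop$component))
    }
  } else {
    if (!(pp$var %in% names(ct$dynamics$state_vars))) {
      fb_abort("UnresolvedProbePath", sprintf(
        "probe '%s' names unknown state '%s'", p, pp$var))
    }
  }
  invisible(TRUE)
}

#' @keywords internal
#' Parse "pop[i]/v", "pop[i]/seg/v" or "pop/i/.../v" probe syntax.
fb_parse_probe <- function(p) {
  parts <- strsplit(p, "/", fixed = TRUE)[[1]]
  m <- regmatches(parts[1], regexec("^([A-Za-z0-9_.-]+)\\[([0-9]+)\\]$", parts[1]))[[1]]
  if (length(m) == 3L) {
    pop <- m[2]; idx <- as.integer(m[3]); rest <- parts[-1]
  } else {
    pop <- parts[1]; idx <- as.integer(parts[2]); rest <- parts[-(1:2)]
    # tolerate "pop/i/celltype/0/v" jLEMS style: drop non-numeric type name
    if (length(rest) >= 2L && !grepl("^[0-9]+$", rest[1]) &&
        grepl("^[0-9]+$", rest[2])) {
      rest <- rest[-(1:2)]
    }
  }
  if (length(rest) == 1L) {
    list(population = pop, index = idx, segment = 0L, var = rest[1])
  } else if (length(rest) == 2L && grepl("^[0-9]+$", rest[1])) {
    list(population = pop, index = idx, segment = as.integer(rest[1]),
         var = rest[2])
  } else {
    fb_abort("UnresolvedProbePath", sprintf("cannot parse probe path '%s'", p))
  }
}

# ---------------------------------------------------------------------------
# recordings on disk
# ---------------------------------------------------------------------------

#' Write a recording to jLEMS-style output files
#'
#' Waveform files hold whitespace-separated columns, first column simulated
#' time in seconds, remaining columns the probed values in SI units, one row
#' per recorded step. Event files hold `<source_index>\t<time_s>` rows sorted
#' by time, with no header. Identical recordings produce bit-identical files.
#'
#' @param recording a `recording` as returned by [run_simulation()].
#' @param spec the `simulation_spec` naming the output files.
#' @param dir directory the file names are resolved against.
#' @return invisibly, the paths written.
#' @export
write_recordings <- function(recording, spec, dir = ".") {
  written <- character(0)
  col_cursor <- 0L
  for (of in spec$output_files) {
    k <- length(of$probes)
    cols <- recording$waveforms[, col_cursor + seq_len(k), drop = FALSE]
    col_cursor <- col_cursor + k
    if (ncol(cols) != k) {
      fb_abort("IOFailure", "recording column count does not match spec")
    }
    path <- file.path(dir, of$path)
    lines <- vapply(seq_along(recording$time), function(i) {
      paste(c(sprintf("%.17g", recording$time[i]),
              sprintf("%.17g", cols[i, ])), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    written <- c(written, path)
  }
  for (fi in seq_along(spec$event_files)) {
    ef <- spec$event_files[[fi]]
    path <- file.path(dir, ef$path)
    ev <- recording$events
    if (!is.null(ev$file)) ev <- ev[ev$file == fi, , drop = FALSE]
    ev <- ev[order(ev$time, ev$source), , drop = FALSE]
    writeLines(sprintf("%d\t%.17g", ev$source, ev$time), path)
    written <- c(written, path)
  }
  invisible(written)
}

#' Read back a waveform file written by [write_recordings()]
#'
#' @param path waveform file path.
#' @return list with `time` (numeric) and `waveforms` (matrix, one column per
#'   probe).
#' @export
read_waveforms <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  list(time = m[, 1], waveforms = m[, -1, drop = FALSE])
}

#' Read back an event file written by [write_recordings()]
#'
#' @param path event file path.
#' @return data.frame with `source` (0-based index) and `time` (seconds);
#'   zero rows for an empty file.
#' @export
read_events <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(source = integer(0), time = double(0)))
  }
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("source", "time"))
  d
}
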