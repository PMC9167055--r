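# Serialization of the supported NeuroML/LEMS subset back to XML.
#
# serialize_model(parse_model(xml)) round-trips to an equal object model;
# numeric values are written with 17 significant digits (exact for doubles)
# in SI units.

#' @keywords internal
#' Deparse an R AST back into LEMS expression text (log10 -> log, log -> ln).
fb_deparse_lems <- function(e) {
  txt <- paste(deparse(e), collapse = " ")
  txt <- gsub("\\blog10\\(", "log(", gsub("\\blog\\(", "ln(", txt))
  txt
}

#' @keywords internal
fb_xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub('"', "&quot;", s, fixed = TRUE)
}

#' @keywords internal
fb_attr_str <- function(attrs) {
  attrs <- attrs[!vapply(attrs, is.null, logical(1))]
  if (length(attrs) == 0L) return("")
  paste0(" ", paste(sprintf('%s="%s"', names(attrs),
                            fb_xml_escape(unlist(attrs))), collapse = " "))
}

#' @keywords internal
fb_num <- function(x) sprintf("%.17g", x)

#' Serialize a model document to NeuroML/LEMS XML
#'
#' Writes the supported subset back out; `parse_model(serialize_model(doc))`
#' yields an object model equal to `doc`. Values are emitted in SI units.
#'
#' @param doc a `model_document`.
#' @return a single string of XML.
#' @export
serialize_model <- function(doc) {
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  add('<neuroml xmlns="http://www.neuroml.org/schema/neuroml2">')

  for (ct in doc$component_types) {
    add(sprintf('  <ComponentType name="%s">', ct$id))
    for (nm in names(ct$parameters)) {
      p <- ct$parameters[[nm]]
      dim_attr <- if (is.na(p$dim)) "" else sprintf(' dimension="%s"', p$dim)
      if (is.na(p$value)) {
        add(sprintf('    <Parameter name="%s"%s/>', nm, dim_attr))
      } else {
        add(sprintf('    <Constant name="%s"%s value="%s"/>',
                    nm, dim_attr, fb_num(p$value)))
      }
    }
    for (nm in names(ct$requirements)) {
      add(sprintf('    <Requirement name="%s" dimension="%s"/>',
                  nm, ct$requirements[[nm]]))
    }
    for (nm in names(ct$exposures)) {
      add(sprintf('    <Exposure name="%s" dimension="none"/>', nm))
    }
    for (p in ct$event_ports_in) {
      add(sprintf('    <EventPort name="%s" direction="in"/>', p))
    }
    for (p in ct$event_ports_out) {
      add(sprintf('    <EventPort name="%s" direction="out"/>', p))
    }
    add("    <Dynamics>")
    for (nm in names(ct$state_vars)) {
      add(sprintf('      <StateVariable name="%s" dimension="%s"/>',
                  nm, ct$state_vars[[nm]]$dim))
    }
    for (nm in names(ct$derived_vars)) {
      add(sprintf('      <DerivedVariable name="%s" value="%s"/>',
                  nm, fb_xml_escape(fb_deparse_lems(ct$derived_vars[[nm]]))))
    }
    for (nm in names(ct$time_derivatives)) {
      add(sprintf('      <TimeDerivative variable="%s" value="%s"/>',
                  nm, fb_xml_escape(fb_deparse_lems(ct$time_derivatives[[nm]]))))
    }
    if (length(ct$on_start) > 0L) {
      add("      <OnStart>")
      for (os in ct$on_start) {
        add(sprintf('        <StateAssignment variable="%s" value="%s"/>',
                    os$var, fb_xml_escape(fb_deparse_lems(os$expr))))
      }
      add("      </OnStart>")
    }
    for (oc in ct$on_conditions) {
      add(sprintf('      <OnCondition test="%s">',
                  fb_xml_escape(fb_deparse_lems(oc$test))))
      for (v in names(oc$assignments)) {
        add(sprintf('        <StateAssignment variable="%s" value="%s"/>',
                    v, fb_xml_escape(fb_deparse_lems(oc$assignments[[v]]))))
      }
      for (p in oc$emits) add(sprintf('        <EventOut port="%s"/>', p))
      add("      </OnCondition>")
    }
    for (p in names(ct$on_events)) {
      add(sprintf('      <OnEvent port="%s">', p))
      for (v in names(ct$on_events[[p]]$assignments)) {
        add(sprintf('        <StateAssignment variable="%s" value="%s"/>',
                    v, fb_xml_escape(fb_deparse_lems(ct$on_events[[p]]$assignments[[v]]))))
      }
      add("      </OnEvent>")
    }
    add("    </Dynamics>")
    add("  </ComponentType>")
  }

  rate_xml <- function(tag, r) {
    if (r$type == "fixed") {
      return(sprintf('      <%s type="fixedTimeCourse" tau="%s s"/>',
                     tag, fb_num(r$tau)))
    }
    tname <- switch(r$type, exp = "HHExpRate", sigmoid = "HHSigmoidRate",
                    explinear = "HHExpLinearRate")
    sprintf('      <%s type="%s" rate="%s per_s" midpoint="%s V" scale="%s V"/>',
            tag, tname, fb_num(r$rate), fb_num(r$midpoint), fb_num(r$scale))
  }
  for (ch in doc$ion_channels) {
    add(sprintf('  <ionChannelHH id="%s">', ch$id))
    for (g in ch$gates) {
      if (g$form == "rates") {
        add(sprintf('    <gateHHrates id="%s" instances="%d">', g$name, g$instances))
        add(rate_xml("forwardRate", g$forward))
        add(rate_xml("reverseRate", g$reverse))
        add("    </gateHHrates>")
      } else {
        add(sprintf('    <gateHHtauInf id="%s" instances="%d">', g$name, g$instances))
        add(rate_xml("timeCourse", g$timeCourse))
        add(rate_xml("steadyState", g$steadyState))
        add("    </gateHHtauInf>")
      }
    }
    add("  </ionChannelHH>")
  }

  for (id in names(doc$cell_types)) {
    ct <- doc$cell_types[[id]]
    if (ct$kind == "point") {
      if (!is.null(doc$component_types[[ct$tag]])) {
        add(sprintf("  <%s%s/>", ct$tag, fb_attr_str(ct$attrs)))
      } else {
        add(sprintf("  <%s%s/>", ct$tag, fb_attr_str(ct$attrs)))
      }
      next
    }
    add(sprintf('  <cell id="%s">', ct$id))
    add("    <morphology>")
    sd <- ct$segments
    for (k in seq_len(nrow(sd))) {
      nm <- if (nzchar(sd$name[k])) sprintf(' name="%s"', sd$name[k]) else ""
      add(sprintf('      <segment id="%d"%s>', sd$id[k], nm))
      if (sd$parent[k] >= 0L) {
        add(sprintf('        <parent segment="%d"/>', sd$parent[k]))
      }
      if (sd$has_prox[k]) {
        add(sprintf('        <proximal x="%s" y="%s" z="%s" diameter="%s"/>',
                    fb_num(sd$px[k]), fb_num(sd$py[k]), fb_num(sd$pz[k]),
                    fb_num(sd$pd[k])))
      }
      add(sprintf('        <distal x="%s" y="%s" z="%s" diameter="%s"/>',
                  fb_num(sd$dx[k]), fb_num(sd$dy[k]), fb_num(sd$dz[k]),
                  fb_num(sd$dd[k])))
      add("      </segment>")
    }
    for (gn in setdiff(names(ct$segment_groups), "all")) {
      add(sprintf('      <segmentGroup id="%s">', gn))
      for (m in ct$segment_groups[[gn]]) {
        add(sprintf('        <member segment="%d"/>', m))
      }
      add("      </segmentGroup>")
    }
    add("    </morphology>")
    add('    <biophysicalProperties id="bio">')
    add("      <membraneProperties>")
    for (d in ct$channel_densities) {
      sg <- if (identical(d$segment_group, "all")) ""
            else sprintf(' segmentGroup="%s"', d$segment_group)
      add(sprintf(paste0('        <channelDensity id="%s" ionChannel="%s" ',
                         'condDensity="%s S_per_m2" erev="%s V"%s/>'),
                  d$id, d$ion_channel, fb_num(d$cond_density),
                  fb_num(d$erev), sg))
    }
    add(sprintf('        <spikeThresh value="%s V"/>', fb_num(ct$spike_thresh)))
    add(sprintf('        <specificCapacitance value="%s F_per_m2"/>',
                fb_num(ct$specific_capacitance)))
    add(sprintf('        <initMembPotential value="%s V"/>', fb_num(ct$init_v)))
    add("      </membraneProperties>")
    add("      <intracellularProperties>")
    add(sprintf('        <resistivity value="%s ohm_m"/>', fb_num(ct$resistivity)))
    add("      </intracellularProperties>")
    add("    </biophysicalProperties>")
    add("  </cell>")
  }

  for (id in names(doc$synapse_types)) {
    st <- doc$synapse_types[[id]]
    add(sprintf("  <%s%s/>", fb_syn_tag(st), fb_attr_str(attr(st, "attrs"))))
  }
  for (id in names(doc$input_types)) {
    it <- doc$input_types[[id]]
    tag <- if (!is.null(it$poisson_fire)) "poissonFiringSynapse"
           else "pulseGenerator"
    add(sprintf("  <%s%s/>", tag, fb_attr_str(attr(it, "attrs"))))
  }

  for (net in doc$networks) {
    add(sprintf('  <network id="%s">', net$id))
    for (p in net$populations) {
      add(sprintf('    <population id="%s" component="%s" size="%d"/>',
                  p$id, p$component, p$size))
    }
    for (pr in net$projections) {
      add(sprintf(paste0('    <projection id="%s" presynapticPopulation="%s" ',
                         'postsynapticPopulation="%s" synapse="%s">'),
                  pr$id, pr$presynaptic, pr$postsynaptic, pr$synapse))
      cd <- pr$connections
      for (k in seq_len(nrow(cd))) {
        add(sprintf(paste0('      <connectionWD id="%d" preCellId="%s[%d]" ',
                           'postCellId="%s[%d]" preSegmentId="%d" ',
                           'preFractionAlong="%s" postSegmentId="%d" ',
                           'postFractionAlong="%s" weight="%s" delay="%s s"/>'),
                    k - 1L, pr$presynaptic, cd$pre_cell[k],
                    pr$postsynaptic, cd$post_cell[k], cd$pre_segment[k],
                    fb_num(cd$pre_fraction[k]), cd$post_segment[k],
                    fb_num(cd$post_fraction[k]), fb_num(cd$weight[k]),
                    fb_num(cd$delay[k])))
      }
      add("    </projection>")
    }
    for (pr in net$electrical_projections) {
      add(sprintf(paste0('    <electricalProjection id="%s" ',
                         'presynapticPopulation="%s" postsynapticPopulation="%s">'),
                  pr$id, pr$presynaptic, pr$postsynaptic))
      cd <- pr$connections
      for (k in seq_len(nrow(cd))) {
        add(sprintf(paste0('      <electricalConnection id="%d" preCell="%s[%d]" ',
                           'postCell="%s[%d]" preSegment="%d" ',
                           'preFractionAlong="%s" postSegment="%d" ',
                           'postFractionAlong="%s" synapse="%s"/>'),
                    k - 1L, pr$presynaptic, cd$pre_cell[k],
                    pr$postsynaptic, cd$post_cell[k], cd$pre_segment[k],
                    fb_num(cd$pre_fraction[k]), cd$post_segment[k],
                    fb_num(cd$post_fraction[k]), cd$synapse[k]))
      }
      add("    </electricalProjection>")
    }
    for (il in net$input_lists) {
      add(sprintf('    <inputList id="%s" component="%s" population="%s">',
                  il$id, il$component, il$population))
      idf <- il$inputs
      for (k in seq_len(nrow(idf))) {
        add(sprintf(paste0('      <input id="%d" target="%s[%d]" ',
                           'segmentId="%d" fractionAlong="%s"/>'),
                    k - 1L, il$population, idf$target[k], idf$segment[k],
                    fb_num(idf$fraction[k])))
      }
      add("    </inputList>")
    }
    add("  </network>")
  }
  add("</neuroml>")
  paste(L, collapse = "\n")
}

#' @keywords internal
fb_syn_tag <- function(st) {
  if (st$kind == "gap") return("gapJunction")
  if (!is.null(st$state_vars$A)) "expTwoSynapse" else "expOneSynapse"
}
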