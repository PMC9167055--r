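# Morphology discretization: one compartment per morphological segment.
#
# Geometry is taken from the segment end points (micron coordinates in the
# document, converted to SI): membrane area is the frustum lateral surface
# pi*(r_prox + r_dist)*sqrt((r_prox - r_dist)^2 + L^2); a zero-length root
# segment with equal diameters is treated as a sphere of area pi*d^2.
# Axial conductance to the parent uses the mean diameter:
# g = (pi/4) * dbar^2 / (Ra * L).

#' Discretize a morphological cell into compartments
#'
#' Produces one compartment per morphological segment, in topological order
#' (every parent precedes its children; the root has parent index -1), with
#' membrane capacitance, axial conductance to the parent, and the channel
#' mechanisms whose segment groups cover the segment made explicit.
#'
#' @param cell a morphological cell definition from [parse_model()]
#'   (`doc$cell_types[[id]]` with `kind == "morph"`).
#' @param doc the containing `model_document` (for ion channel lookups).
#' @return a list of compartments; each has `index`, `seg_id`, `parent`
#'   (compartment index, -1 for root), `length`, `diam_prox`, `diam_dist`
#'   (SI), `area`, `capacitance`, `g_axial`, and `mechanisms` (list of
#'   channel-density instances with `channel`, `gbar` in S and `erev` in V).
#' @export
discretize <- function(cell, doc) {
  if (!identical(cell$kind, "morph")) {
    fb_abort("MissingBiophysics", "discretize() requires a morphological cell")
  }
  sd <- cell$segments
  n <- nrow(sd)
  # topological order over segment ids
  id2row <- stats::setNames(seq_len(n), as.character(sd$id))
  order <- integer(0)
  placed <- logical(n)
  guard <- 0L
  while (length(order) < n) {
    guard <- guard + 1L
    if (guard > n + 1L) {
      fb_abort("CyclicMorphology",
               sprintf("segment parents of cell '%s' do not form a tree", cell$id))
    }
    for (k in seq_len(n)) {
      if (placed[k]) next
      par <- sd$parent[k]
      if (par < 0L || placed[id2row[[as.character(par)]]]) {
        order <- c(order, k); placed[k] <- TRUE
      }
    }
  }
  comp_of_seg <- stats::setNames(seq_along(order) - 1L, as.character(sd$id[order]))

  um <- 1e-6
  comps <- vector("list", n)
  for (ci in seq_along(order)) {
    k <- order[ci]
    par_seg <- sd$parent[k]
    par_comp <- if (par_seg < 0L) -1L else comp_of_seg[[as.character(par_seg)]]
    if (sd$has_prox[k]) {
      p <- c(sd$px[k], sd$py[k], sd$pz[k]); pdi <- sd$pd[k]
    } else {
      pk <- id2row[[as.character(par_seg)]]
      p <- c(sd$dx[pk], sd$dy[pk], sd$dz[pk]); pdi <- sd$dd[pk]
    }
    d <- c(sd$dx[k], sd$dy[k], sd$dz[k]); ddi <- sd$dd[k]
    L <- sqrt(sum((d - p)^2)) * um
    r1 <- pdi / 2 * um; r2 <- ddi / 2 * um
    if (L == 0) {
      area <- pi * (2 * r2)^2           # sphere
    } else {
      area <- pi * (r1 + r2) * sqrt((r1 - r2)^2 + L^2)
    }
    dbar <- (pdi + ddi) / 2 * um
    g_ax <- if (par_comp < 0L || L == 0) 0.0 else
      (pi / 4) * dbar^2 / (cell$resistivity * L)
    mechs <- list()
    for (cd in cell$channel_densities) {
      members <- cell$segment_groups[[cd$segment_group]]
      if (is.null(members)) {
        fb_abort("UnresolvedReference", sprintf(
          "channelDensity '%s' names unknown segmentGroup '%s'",
          cd$id, cd$segment_group))
      }
      if (sd$id[k] %in% members) {
        ch <- doc$ion_channels[[cd$ion_channel]]
        if (is.null(ch)) {
          fb_abort("UnresolvedReference", sprintf(
            "channelDensity '%s' references undefined channel '%s'",
            cd$id, cd$ion_channel))
        }
        mechs[[length(mechs) + 1L]] <- list(
          id = cd$id, channel = cd$ion_channel,
          gbar = cd$cond_density * area, erev = cd$erev)
      }
    }
    comps[[ci]] <- list(
      index = ci - 1L, seg_id = sd$id[k], parent = par_comp,
      length = L, diam_prox = 2 * r1, diam_dist = 2 * r2, area = area,
      capacitance = cell$specific_capacitance * area, g_axial = g_ax,
      mechanisms = mechs, syn_kinds = character(0), input_kinds = character(0))
  }
  comps
}
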