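# Neuron-level classification: soma region and cortical layer, the IT
# subclass split (callosal CPN vs associative APN), and reproducible
# grouping of projection profiles into categories.
#
# The CPN / APN split is operationalized geometrically: a neuron is a CPN
# iff it places at least `min_contra_mm` of axonal cable in the hemisphere
# opposite its soma (default 1 mm). Whether the crossing runs through the
# corpus-callosum band is reported separately (`crossed_via_cc`) rather
# than required, so a stray sub-threshold midline crossing never flips the
# class.

#' Soma region and cortical layer
#'
#' The soma region is the label at the root-node coordinate; the layer is
#' read from the nearest layer-tagged region among the label itself and
#' its ontology ancestors (`"unknown"` for unlayered regions such as the
#' striatum).
#'
#' @param m a valid [morphology()].
#' @param vol a [label_volume()].
#' @param ont a [region_ontology()].
#' @return list with `soma_region` (region id), `soma_acronym`,
#'   `soma_layer` (`"L1"`, `"L2/3"`, `"L5"` or `"unknown"`).
#' @export
assign_soma_location <- function(m, vol, ont) {
  root <- m$nodes[match(m$root_id, m$nodes$id), ]
  id <- region_at(vol, c(root$x, root$y, root$z))
  if (id == 0) {
    proj_error("soma_outside_volume",
               sprintf("soma of '%s' is in background / outside the volume",
                       m$name))
  }
  chain <- c(id, region_ancestors(ont, id))
  layers <- ont$layer[match(chain, ont$region_id)]
  layer <- layers[!is.na(layers)][1]
  list(soma_region = id,
       soma_acronym = ont$acronym[match(id, ont$region_id)],
       soma_layer = if (is.na(layer)) "unknown" else layer)
}

#' Classify an IT neuron as CPN or APN
#'
#' Computes the hemisphere split of the axon and labels the neuron CPN
#' (callosal projection neuron) iff its contralateral axonal cable reaches
#' `min_contra_mm` millimeters, else APN (associative projection neuron).
#' Also reports whether any axonal piece runs through the corpus-callosum
#' region, and the signed displacement of the contralateral axonal
#' centroid along the anterior-posterior axis (descriptive only).
#'
#' @param m a valid [morphology()].
#' @param vol a [label_volume()].
#' @param ont a [region_ontology()].
#' @param mid a [midline_plane()].
#' @param cc_region region id (or acronym) of the corpus-callosum band.
#' @param min_contra_mm CPN threshold on contralateral cable, millimeters.
#' @param step subdivision step, micrometers.
#' @param ap_axis axis name of the anterior-posterior direction (for the
#'   descriptive extension direction), default `"y"`.
#' @return one-row data.frame: `name`, `soma_region`, `soma_acronym`,
#'   `soma_layer`, `it_subclass`, `contra_axon_mm`, `ipsi_axon_mm`,
#'   `crossed_via_cc`, `contra_ap_displacement_um`.
#' @export
classify_it <- function(m, vol, ont, mid, cc_region,
                        min_contra_mm = 1.0, step = min(vol$voxel_size),
                        ap_axis = "y") {
  if (is.character(cc_region)) {
    cc_region <- ont$region_id[match(cc_region, ont$acronym)]
  }
  soma <- assign_soma_location(m, vol, ont)
  root <- m$nodes[match(m$root_id, m$nodes$id), ]
  soma_side <- hemisphere_of(c(root$x, root$y, root$z), mid)
  pieces <- subdivide_cable(m, step, "AXON")
  mids <- cbind(pieces$mx, pieces$my, pieces$mz)
  side <- hemisphere_of(mids, mid)
  contra_side <- setdiff(c("LEFT", "RIGHT"), soma_side)
  contra_um <- sum(pieces$len[side == contra_side])
  ipsi_um <- sum(pieces$len[side == soma_side])
  ids <- region_at(vol, mids)
  crossed <- any(ids == cc_region)
  ap <- mids[, match(ap_axis, c("x", "y", "z"))]
  is_contra <- side == contra_side
  ap_disp <- if (any(is_contra)) {
    stats::weighted.mean(ap[is_contra], pieces$len[is_contra]) -
      root[[ap_axis]]
  } else NA_real_
  data.frame(
    name = m$name,
    soma_region = soma$soma_region,
    soma_acronym = soma$soma_acronym,
    soma_layer = soma$soma_layer,
    it_subclass = if (contra_um / 1000 >= min_contra_mm) "CPN" else "APN",
    contra_axon_mm = contra_um / 1000,
    ipsi_axon_mm = ipsi_um / 1000,
    crossed_via_cc = crossed,
    contra_ap_displacement_um = ap_disp,
    stringsAsFactors = FALSE)
}

# union-find for single-linkage grouping
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Group projection profiles into categories
#'
#' A reproducible stand-in for qualitative by-eye groupings of projection
#' patterns: each neuron's target set is the set of regions receiving at
#' least `theta` of its axonal cable (the background bucket is never a
#' target); neurons are grouped by single linkage over Jaccard similarity
#' of target sets at cutoff `jaccard_cutoff`. Category ids are assigned in
#' order of each category's first member in the input, so the grouping is
#' deterministic and permutation-equivariant.
#'
#' @param mat neurons x regions matrix of projection strengths (rows
#'   normalized), e.g. from [projection_matrix()].
#' @param theta binarization threshold on strength (default 0.05).
#' @param jaccard_cutoff minimum Jaccard similarity to link two neurons
#'   (default 0.5). Two empty target sets are treated as identical.
#' @return integer vector of category ids, named by neuron.
#' @export
categorize_profiles <- function(mat, theta = 0.05, jaccard_cutoff = 0.5) {
  if (is.null(dim(mat)) || nrow(mat) == 0) {
    proj_error("empty_matrix", "no rows to categorize")
  }
  cols <- colnames(mat)
  target_cols <- if (is.null(cols)) seq_len(ncol(mat)) else which(cols != "0")
  sets <- lapply(seq_len(nrow(mat)), function(i) {
    target_cols[mat[i, target_cols] >= theta]
  })
  n <- length(sets)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    jac <- apply(pairs, 2, function(p) {
      a <- sets[[p[1]]]; b <- sets[[p[2]]]
      if (length(a) == 0 && length(b) == 0) return(1)
      length(intersect(a, b)) / length(union(a, b))
    })
    edges <- t(pairs[, jac >= jaccard_cutoff, drop = FALSE])
  }
  comp <- .components(n, edges)
  ids <- match(comp, unique(comp))  # number categories by first appearance
  stats::setNames(ids, rownames(mat))
}
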