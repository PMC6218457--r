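# Brain-wide output quantification. Projection strength is the field's
# operational quantity: the fraction of a neuron's total axonal cable
# length lying inside each target region. Each axonal edge is subdivided
# into pieces no longer than `step` and each piece's full length is booked
# to the region (and hemisphere) at its midpoint — length is conserved
# exactly by construction, and the assignment converges to exact clipping
# as step -> 0. A background bucket (region id 0) is always carried:
# unlabeled cable is reported, never silently renormalized away.

#' Subdivide axonal cable into short pieces
#'
#' Cuts every parent-child edge of the requested class into pieces of
#' length at most `step` and returns one row per piece with its midpoint,
#' length and the id of the tree edge it came from. All region and
#' hemisphere bookings derive from this table.
#'
#' @param m a valid [morphology()].
#' @param step maximum piece length in micrometers (> 0).
#' @param cls structure class to quantify (default `"AXON"`).
#' @return data.frame with columns `mx`, `my`, `mz` (piece midpoints, um),
#'   `len` (piece length, um) and `edge` (index of the originating edge).
#' @export
subdivide_cable <- function(m, step, cls = "AXON") {
  if (step <= 0) proj_error("bad_step", "step must be > 0")
  nodes <- m$nodes
  sel <- which(nodes$parent != -1 & class_of_nodes(m) %in% cls)
  if (length(sel) == 0) {
    proj_error("empty_axon",
               sprintf("neuron '%s' has no %s cable", m$name,
                       paste(cls, collapse = "/")))
  }
  pidx <- match(nodes$parent[sel], nodes$id)
  p0 <- cbind(nodes$x[pidx], nodes$y[pidx], nodes$z[pidx])
  p1 <- cbind(nodes$x[sel], nodes$y[sel], nodes$z[sel])
  elen <- sqrt(rowSums((p1 - p0)^2))
  npieces <- pmax(1L, as.integer(ceiling(elen / step)))
  rep_i <- rep(seq_along(sel), npieces)
  # midpoint parameter of piece k of n: (k - 0.5)/n
  t_mid <- (sequence(npieces) - 0.5) / npieces[rep_i]
  data.frame(
    mx = p0[rep_i, 1] + t_mid * (p1[rep_i, 1] - p0[rep_i, 1]),
    my = p0[rep_i, 2] + t_mid * (p1[rep_i, 2] - p0[rep_i, 2]),
    mz = p0[rep_i, 3] + t_mid * (p1[rep_i, 3] - p0[rep_i, 3]),
    len = elen[rep_i] / npieces[rep_i],
    edge = rep_i)
}

#' Axonal cable length per region
#'
#' Books each axonal piece (see [subdivide_cable()]) to the region at its
#' midpoint. The total over regions (background id 0 included) equals the
#' total axonal cable length exactly.
#'
#' @param m a valid [morphology()].
#' @param vol a [label_volume()].
#' @param step piece length in micrometers; defaults to the smallest voxel
#'   edge.
#' @return named numeric vector, region id -> axonal length (um); includes
#'   a `"0"` background entry when any cable is unlabeled.
#' @export
segment_region_lengths <- function(m, vol, step = min(vol$voxel_size)) {
  pieces <- subdivide_cable(m, step, "AXON")
  ids <- region_at(vol, cbind(pieces$mx, pieces$my, pieces$mz))
  out <- rowsum(pieces$len, ids)
  stats::setNames(as.vector(out), rownames(out))
}

#' Axonal terminal tips per region
#'
#' Assigns each axonal terminal tip to the region at its coordinate;
#' counts sum to [count_tips()] of the axon.
#'
#' @inheritParams segment_region_lengths
#' @return named integer vector, region id -> tip count.
#' @export
tips_per_region <- function(m, vol) {
  nodes <- m$nodes
  is_ax <- class_of_nodes(m) == "AXON"
  tips <- which(is_ax & .class_child_counts(m, "AXON") == 0L)
  if (length(tips) == 0) return(stats::setNames(integer(0), character(0)))
  ids <- region_at(vol, cbind(nodes$x[tips], nodes$y[tips], nodes$z[tips]))
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build a neuron's projection profile
#'
#' The per-neuron record of brain-wide output: soma location and side,
#' axonal length and terminal tips per region, and the total axonal
#' length. Values are micrometers.
#'
#' @inheritParams segment_region_lengths
#' @param mid a [midline_plane()].
#' @return object of class `projection_profile`: list with `name`,
#'   `soma_region`, `soma_side`, `region_lengths`, `region_tips`,
#'   `total_axon_length`.
#' @export
projection_profile <- function(m, vol, mid, step = min(vol$voxel_size)) {
  root <- m$nodes[match(m$root_id, m$nodes$id), ]
  soma_p <- c(root$x, root$y, root$z)
  lens <- segment_region_lengths(m, vol, step)
  structure(list(
    name = m$name,
    soma_region = region_at(vol, soma_p),
    soma_side = hemisphere_of(soma_p, mid),
    region_lengths = lens,
    region_tips = tips_per_region(m, vol),
    total_axon_length = sum(lens)),
    class = "projection_profile")
}

#' Projection strengths (fractions of total axonal length)
#'
#' Aggregates a profile's per-region lengths up the ontology to a chosen
#' level and divides by the total axonal length. The denominator is the
#' full axonal cable including unlabeled (background) cable, so fractions
#' sum to 1 only once the background bucket is included — printed
#' ipsilateral + contralateral percentages may legitimately fall short of
#' 100%. Set `include_background = FALSE` to renormalize over labeled
#' cable only.
#'
#' @param profile a [projection_profile()].
#' @param ont a [region_ontology()].
#' @param level region ids or acronyms defining the aggregation level
#'   (each leaf maps to its nearest ancestor-or-self in the set; leaves
#'   outside the set join the background bucket). `NULL` keeps leaf
#'   regions as-is.
#' @param include_background if `TRUE` (default) the denominator is total
#'   axonal length and a `"0"` background entry is carried.
#' @return named numeric vector of fractions (names are acronyms where
#'   known, else region ids; `"0"` is background).
#' @export
projection_strengths <- function(profile, ont, level = NULL,
                                 include_background = TRUE) {
  lens <- profile$region_lengths
  if (sum(lens) <= 0) proj_error("zero_length", "total axonal length is zero")
  ids <- as.integer(names(lens))
  if (!is.null(level)) {
    if (is.character(level)) {
      level <- ont$region_id[match(level, ont$acronym)]
      if (anyNA(level)) proj_error("unknown_region", "unknown acronym in level")
    }
    ids <- .aggregate_to_level(ont, ids, level)
  }
  agg <- rowsum(as.vector(lens), ids)
  vals <- as.vector(agg)
  keys <- rownames(agg)
  if (!include_background) {
    keep <- keys != "0"
    vals <- vals[keep]; keys <- keys[keep]
    denom <- sum(vals)
  } else {
    denom <- profile$total_axon_length
  }
  acro <- ont$acronym[match(as.integer(keys), ont$region_id)]
  keys <- ifelse(is.na(acro), keys, acro)
  stats::setNames(vals / denom, keys)
}

#' Ipsilateral / contralateral decomposition of axonal output
#'
#' Books each axonal piece to the hemisphere of its midpoint relative to
#' the soma side. Lengths are conserved:
#' ipsi + contra + on-midline == total axonal length.
#'
#' @inheritParams projection_profile
#' @return list with `soma_side`, `ipsi_length`, `contra_length`,
#'   `on_midline_length` (um), `total_axon_length` and fractions
#'   `ipsi_fraction`, `contra_fraction`.
#' @export
hemisphere_split <- function(m, vol, mid, step = min(vol$voxel_size)) {
  root <- m$nodes[match(m$root_id, m$nodes$id), ]
  soma_side <- hemisphere_of(c(root$x, root$y, root$z), mid)
  pieces <- subdivide_cable(m, step, "AXON")
  side <- hemisphere_of(cbind(pieces$mx, pieces$my, pieces$mz), mid)
  total <- sum(pieces$len)
  on_mid <- sum(pieces$len[side == "ON_MIDLINE"])
  ipsi <- sum(pieces$len[side == soma_side])
  contra <- total - ipsi - on_mid
  list(soma_side = soma_side,
       ipsi_length = ipsi, contra_length = contra,
       on_midline_length = on_mid, total_axon_length = total,
       ipsi_fraction = ipsi / total, contra_fraction = contra / total)
}

#' Neurons x regions projection-strength matrix
#'
#' Assembles projection strengths across neurons into a matrix whose rows
#' (neurons) sum to 1 when the background column is included. Columns
#' follow ontology order, with the background column (`"0"`) last.
#'
#' @param profiles list of [projection_profile()] objects.
#' @param ont a [region_ontology()].
#' @param level aggregation level, as in [projection_strengths()].
#' @param include_background carry the background column (default `TRUE`).
#' @return numeric matrix, rownames = neuron names, colnames = region
#'   acronyms (+ `"0"`).
#' @export
projection_matrix <- function(profiles, ont, level = NULL,
                              include_background = TRUE) {
  if (length(profiles) == 0) proj_error("empty_matrix", "no profiles")
  rows <- lapply(profiles, projection_strengths, ont = ont, level = level,
                 include_background = include_background)
  keys <- unique(unlist(lapply(rows, names)))
  # ontology order, background last
  ord <- order(match(keys, ont$acronym, nomatch = length(ont$acronym) + 2L))
  keys <- keys[ord]
  mat <- matrix(0, nrow = length(rows), ncol = length(keys),
                dimnames = list(vapply(profiles, `[[`, "", "name"), keys))
  for (i in seq_along(rows)) mat[i, names(rows[[i]])] <- rows[[i]]
  mat
}
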