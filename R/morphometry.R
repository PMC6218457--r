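# Per-neuron morphometrics: cable length, terminal tips, branch points and
# branches, computed per structure class (AXON / DENDRITE / SOMA).
#
# Conventions, fixed once for the whole package:
#  * An edge belongs to the class of its CHILD node, so the soma->axon stem
#    edge counts as axonal cable.
#  * Tips and branch points are computed on the class-restricted subforest:
#    a class-cls node is a tip iff it has no cls children, and a branch
#    point iff it has >= 2 cls children (multifurcations count once).
#  * A "branch" is an edge of the condensed class subtree — a maximal
#    unbranched path between stem / branch point / tip — which makes
#    branches == tips + branchpoints per connected class component, and
#    branches == 2*tips - 1 for a strictly bifurcating single-stem arbor.

class_of_nodes <- function(m) structure_class(m$nodes$type)

# children count restricted to a class: for each node, number of children
# of class cls (cls = NULL counts all children)
.class_child_counts <- function(m, cls = NULL) {
  nodes <- m$nodes
  keep <- nodes$parent != -1
  if (!is.null(cls)) keep <- keep & (class_of_nodes(m) == cls)
  idx <- match(nodes$parent[keep], nodes$id)
  tabulate(idx, nbins = nrow(nodes))
}

#' Total cable length per structure class
#'
#' Sums Euclidean parent-child edge lengths over all edges whose child node
#' has the requested class. Zero-length edges (coincident nodes) are
#' allowed and contribute 0. Returns 0 if the class is absent.
#'
#' @param m a valid [morphology()].
#' @param cls `"AXON"`, `"DENDRITE"`, `"SOMA"` or `"OTHER"`; or a vector of
#'   classes whose union is measured.
#' @return cable length in micrometers.
#' @export
cable_length <- function(m, cls = "AXON") {
  nodes <- m$nodes
  sel <- nodes$parent != -1 & class_of_nodes(m) %in% cls
  if (!any(sel)) return(0)
  pidx <- match(nodes$parent[sel], nodes$id)
  sum(sqrt((nodes$x[sel] - nodes$x[pidx])^2 +
           (nodes$y[sel] - nodes$y[pidx])^2 +
           (nodes$z[sel] - nodes$z[pidx])^2))
}

#' Count terminal tips of a structure class
#'
#' A tip is a class-`cls` node with no children of the same class (a leaf
#' of the class-restricted subforest).
#'
#' @inheritParams cable_length
#' @return non-negative integer count.
#' @export
count_tips <- function(m, cls = "AXON") {
  is_cls <- class_of_nodes(m) == cls
  sum(is_cls & .class_child_counts(m, cls) == 0L)
}

#' Count branch points of a structure class
#'
#' A branch point is a class-`cls` node with two or more children of the
#' same class; a multifurcation counts once.
#'
#' @inheritParams cable_length
#' @return non-negative integer count.
#' @export
count_branchpoints <- function(m, cls = "AXON") {
  is_cls <- class_of_nodes(m) == cls
  sum(is_cls & .class_child_counts(m, cls) >= 2L)
}

#' Count branches of a structure class
#'
#' A branch is a maximal unbranched path of the class subtree (an edge of
#' the condensed tree): each branch ends, walking away from the soma, at
#' either a tip or a branch point, and every tip or branch point ends
#' exactly one branch — so the count equals `count_tips + count_branchpoints`.
#' For a strictly bifurcating arbor with one stem and `T` tips this gives
#' `2*T - 1`.
#'
#' @inheritParams cable_length
#' @return non-negative integer count.
#' @export
count_branches <- function(m, cls = "AXON") {
  is_cls <- class_of_nodes(m) == cls
  cc <- .class_child_counts(m, cls)
  sum(is_cls & (cc == 0L | cc >= 2L))
}

#' Summarize one neuron's morphometrics
#'
#' Computes the six headline metrics — axonal and dendritic cable length
#' (reported in mm), branch count and terminal-tip count — for one neuron.
#' A neuron with no axonal cable is flagged (`no_axon`) rather than
#' rejected, with a warning.
#'
#' @param m a valid [morphology()].
#' @return one-row data.frame with columns `name`, `axon_length_mm`,
#'   `axon_branches`, `axon_tips`, `dend_length_mm`, `dend_branches`,
#'   `dend_tips`, `no_axon`.
#' @export
summarize_neuron <- function(m) {
  ax_um <- cable_length(m, "AXON")
  rec <- data.frame(
    name = if (nzchar(m$name)) m$name else NA_character_,
    axon_length_mm = ax_um / 1000,
    axon_branches = count_branches(m, "AXON"),
    axon_tips = count_tips(m, "AXON"),
    dend_length_mm = cable_length(m, "DENDRITE") / 1000,
    dend_branches = count_branches(m, "DENDRITE"),
    dend_tips = count_tips(m, "DENDRITE"),
    no_axon = ax_um == 0,
    stringsAsFactors = FALSE)
  if (rec$no_axon) {
    warning(sprintf("neuron '%s' has no axonal cable", m$name),
            call. = FALSE)
  }
  rec
}

#' Summarize a collection of neurons
#'
#' @param ms list of morphologies.
#' @return data.frame, one row per neuron, columns as [summarize_neuron()].
#' @export
summarize_neurons <- function(ms) {
  do.call(rbind, lapply(ms, function(m) suppressWarnings(summarize_neuron(m))))
}
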