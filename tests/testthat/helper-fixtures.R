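# Fixtures and independent oracles used across the test files.
# Oracles are deliberately written as naive per-node loops so they share
# no code path with the package's vectorized implementations.

# --- morphology builders ---

# unbranched path along x: soma at 0, then `k` axon nodes step um apart
make_path <- function(k = 3, step = 10, type = 2) {
  nodes <- data.frame(
    id = 1:(k + 1),
    type = c(1, rep(type, k)),
    x = seq(0, k * step, by = step), y = 0, z = 0,
    radius = c(5, rep(0.5, k)),
    parent = c(-1, 1:k))
  morphology(nodes, name = "path")
}

# soma -> stem A -> two daughters B, C (all axon)
make_y_tree <- function() {
  nodes <- data.frame(
    id = 1:4,
    type = c(1, 2, 2, 2),
    x = c(0, 0, -10, 10), y = c(0, 10, 20, 20), z = 0,
    radius = c(5, 1, 1, 1),
    parent = c(-1, 1, 2, 2))
  morphology(nodes, name = "y")
}

# random tree: node i attaches to a uniformly chosen earlier node; classes
# drawn per node so mixed-class subtrees get exercised
random_tree <- function(n, p_axon = 0.6, p_dend = 0.3, coord_sd = 50) {
  type <- c(1, sample(c(2, 3, 2, 4, 6), n - 1, replace = TRUE,
                      prob = c(p_axon, p_dend / 2, 0.05, p_dend / 2, 0.05)))
  parent_idx <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
  ids <- sample.int(10 * n, n)  # non-consecutive ids
  nodes <- data.frame(
    id = ids, type = type,
    x = rnorm(n, sd = coord_sd), y = rnorm(n, sd = coord_sd),
    z = rnorm(n, sd = coord_sd),
    radius = runif(n, 0, 2),
    parent = c(-1, ids[parent_idx[-1]]))
  morphology(nodes, name = "random")
}

# strictly bifurcating axon with `tips` terminal tips and one stem
bifurcating_tree <- function(tips) {
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 5, parent = -1L)
  nodes <- rbind(nodes, data.frame(id = 2L, type = 2L, x = 0, y = 10, z = 0,
                                   radius = 1, parent = 1L))
  open <- 2L
  nid <- 2L
  while (length(open) < tips) {
    leaf <- open[1]
    open <- open[-1]
    for (b in 1:2) {
      nid <- nid + 1L
      px <- nodes$x[nodes$id == leaf]
      nodes <- rbind(nodes, data.frame(
        id = nid, type = 2L, x = px + runif(1, -5, 5),
        y = nodes$y[nodes$id == leaf] + 10, z = 0, radius = 1,
        parent = leaf))
      open <- c(open, nid)
    }
  }
  morphology(nodes, name = sprintf("bif%d", tips))
}

# --- oracles (naive loops) ---

oracle_cable_length <- function(m, cls) {
  nodes <- m$nodes
  total <- 0
  for (i in seq_len(nrow(nodes))) {
    if (nodes$parent[i] == -1) next
    if (!(structure_class(nodes$type[i]) %in% cls)) next
    j <- which(nodes$id == nodes$parent[i])
    total <- total + sqrt((nodes$x[i] - nodes$x[j])^2 +
                          (nodes$y[i] - nodes$y[j])^2 +
                          (nodes$z[i] - nodes$z[j])^2)
  }
  total
}

# per-node count of same-class children via explicit scan
.oracle_cls_children <- function(m, cls) {
  nodes <- m$nodes
  is_cls <- structure_class(nodes$type) == cls
  vapply(seq_len(nrow(nodes)), function(i) {
    sum(nodes$parent == nodes$id[i] & is_cls)
  }, 0L)
}

oracle_tips <- function(m, cls) {
  is_cls <- structure_class(m$nodes$type) == cls
  sum(is_cls & .oracle_cls_children(m, cls) == 0)
}

oracle_branchpoints <- function(m, cls) {
  is_cls <- structure_class(m$nodes$type) == cls
  sum(is_cls & .oracle_cls_children(m, cls) >= 2)
}

# branches = maximal unbranched paths of the class subforest, counted by
# walking down from every segment start (stem node or branch-point child)
oracle_branches <- function(m, cls) {
  nodes <- m$nodes
  is_cls <- structure_class(nodes$type) == cls
  cc <- .oracle_cls_children(m, cls)
  n_seg <- 0
  for (i in seq_len(nrow(nodes))) {
    if (!is_cls[i]) next
    p <- nodes$parent[i]
    pi <- if (p == -1) NA_integer_ else which(nodes$id == p)
    # a segment starts at a class node whose parent is absent, other-class,
    # or a branch point of the class
    starts <- is.na(pi) || !is_cls[pi] || cc[pi] >= 2
    if (!starts) next
    # walk down single-child chains to the segment end
    cur <- i
    while (cc[cur] == 1) {
      cur <- which(nodes$parent == nodes$id[cur] & is_cls)
    }
    n_seg <- n_seg + 1
  }
  n_seg
}

# --- tiny atlas: two regions split at x = 100, extent 200 x 100 x 100 ---
tiny_atlas <- function() {
  labels <- array(0L, dim = c(20, 10, 10))
  labels[1:10, , ] <- 1L
  labels[11:20, , ] <- 2L
  vol <- label_volume(labels, c(10, 10, 10), c(0, 0, 0))
  ont <- region_ontology(data.frame(
    region_id = c(3L, 1L, 2L), acronym = c("brain", "A", "B"),
    name = c("root", "left half", "right half"),
    parent_id = c(NA, 3L, 3L),
    hemisphere = c("B", "L", "R")))
  list(volume = vol, ontology = ont,
       midline = midline_plane("x", 100))
}

# mirror a morphology about an x-plane
mirror_morphology <- function(m, x_plane) {
  nodes <- m$nodes
  nodes$x <- 2 * x_plane - nodes$x
  morphology(nodes, name = paste0(m$name, "_mirrored"))
}

# mirror a label volume about the x midline of its grid (labels swapped by map)
mirror_volume <- function(vol, swap = identity) {
  labels <- vol$labels[dim(vol$labels)[1]:1, , , drop = FALSE]
  labels[] <- swap(as.vector(labels))
  label_volume(labels, vol$voxel_size, vol$origin)
}
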