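# The anatomical reference frame: a voxel label volume (integer region ids,
# 0 = background/unlabeled), a region ontology table, and an axis-aligned
# midline plane. Voxels are half-open intervals in physical micrometer
# coordinates: voxel (i,j,k) (0-based) covers
# [origin + i*d, origin + (i+1)*d) on each axis.

#' Construct a label volume
#'
#' @param labels 3D integer array of non-negative region ids; 0 is the
#'   background / unlabeled id.
#' @param voxel_size numeric length-3, voxel edge lengths (dx, dy, dz) in
#'   micrometers, strictly positive.
#' @param origin numeric length-3, physical coordinate (micrometers) of the
#'   corner of voxel (0,0,0).
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3) {
    proj_error("bad_volume", "labels must be a 3D array")
  }
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    proj_error("bad_volume", "voxel_size must be 3 strictly positive values")
  }
  if (any(labels < 0)) proj_error("bad_volume", "negative region id")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels of %g x %g x %g um, %d region ids\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Axis-aligned midline plane
#'
#' The hemisphere boundary, e.g. the sagittal midplane. Supplied explicitly
#' (the anatomy is given, not inferred).
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param coordinate plane position in micrometers.
#' @return object of class `midline_plane`.
#' @export
midline_plane <- function(axis = "x", coordinate = 0) {
  axis <- match.arg(axis, c("x", "y", "z"))
  structure(list(axis = axis, coordinate = as.numeric(coordinate)),
            class = "midline_plane")
}

#' Region id at physical points
#'
#' Looks up the region id of the voxel containing each point, under the
#' half-open voxel convention: a point exactly on an interior voxel
#' boundary belongs to the higher-index voxel. Points outside the volume
#' extent get the background id 0.
#'
#' @param vol a [label_volume()].
#' @param p numeric length-3 point, or an n x 3 matrix of points
#'   (micrometers).
#' @return integer vector of region ids, one per point.
#' @export
region_at <- function(vol, p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  d <- dim(vol$labels)
  i <- floor((p[, 1] - vol$origin[1]) / vol$voxel_size[1])
  j <- floor((p[, 2] - vol$origin[2]) / vol$voxel_size[2])
  k <- floor((p[, 3] - vol$origin[3]) / vol$voxel_size[3])
  inside <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
  out <- integer(nrow(p))
  if (any(inside)) {
    lin <- 1 + i[inside] + d[1] * (j[inside] + d[2] * k[inside])
    out[inside] <- vol$labels[lin]
  }
  out
}

#' Hemisphere of physical points
#'
#' @param p length-3 point or n x 3 matrix (micrometers).
#' @param mid a [midline_plane()].
#' @return character vector: `"LEFT"` (coordinate below the plane),
#'   `"RIGHT"` (above), or `"ON_MIDLINE"` (exactly on it).
#' @export
hemisphere_of <- function(p, mid) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  v <- p[, match(mid$axis, c("x", "y", "z"))]
  ifelse(v < mid$coordinate, "LEFT",
         ifelse(v > mid$coordinate, "RIGHT", "ON_MIDLINE"))
}

#' Majority-label downsampling of a label volume
#'
#' Reduces resolution by integer factors: each output voxel takes the
#' majority label of its source block, ties broken by the smallest label
#' id. Edge blocks may be partial. Voxel size is multiplied by the
#' factors; the origin is unchanged. This mirrors the usual preparation of
#' an annotation volume at analysis resolution from the imaging grid.
#'
#' @param vol a [label_volume()].
#' @param factors integer length-3 downsampling factors, all >= 1.
#' @return a new [label_volume()].
#' @export
downsample_labels <- function(vol, factors) {
  factors <- as.integer(factors)
  if (length(factors) != 3 || any(factors < 1)) {
    proj_error("bad_factor", "factors must be 3 integers >= 1")
  }
  d <- dim(vol$labels)
  nd <- as.integer(ceiling(d / factors))
  # block index (0-based, column-major linear) of every source voxel
  bi <- (seq_len(d[1]) - 1L) %/% factors[1]
  bj <- (seq_len(d[2]) - 1L) %/% factors[2]
  bk <- (seq_len(d[3]) - 1L) %/% factors[3]
  block <- rep(bi, times = d[2] * d[3]) +
    nd[1] * (rep(rep(bj, each = d[1]), times = d[3]) +
             nd[2] * rep(bk, each = d[1] * d[2]))
  lab <- as.vector(vol$labels)
  ord <- order(block, lab)
  b <- block[ord]; l <- lab[ord]
  # run-length encode (block,label) pairs; within a block labels ascend, so
  # which.max picks the smallest id among tied counts
  new_run <- c(TRUE, b[-1] != b[-length(b)] | l[-1] != l[-length(l)])
  starts <- which(new_run)
  counts <- diff(c(starts, length(b) + 1L))
  run_block <- b[starts]; run_lab <- l[starts]
  winners <- vapply(split(seq_along(starts), run_block),
                    function(ix) run_lab[ix][which.max(counts[ix])],
                    integer(1))
  out <- array(0L, dim = nd)
  out[as.integer(names(winners)) + 1L] <- winners
  label_volume(out, vol$voxel_size * factors, vol$origin)
}

# Ontology --------------------------------------------------------------

#' Construct a region ontology table
#'
#' The region ontology is a tree of named brain regions: each row one
#' region, with a parent link (NA at the root), an `is_fiber_tract` flag
#' (white-matter tracts such as the corpus callosum), a `hemisphere` tag
#' (`"L"`, `"R"` or `"B"` for bilateral/both) and an optional cortical
#' `layer` tag (`"L1"`, `"L2/3"`, `"L5"`, else NA).
#'
#' @param df data.frame with columns `region_id`, `acronym`, `name`,
#'   `parent_id`; optional `is_fiber_tract`, `hemisphere`, `layer`.
#' @return validated data.frame of class `region_ontology`.
#' @export
region_ontology <- function(df) {
  df <- as.data.frame(df)
  for (col in c("region_id", "acronym", "name", "parent_id")) {
    if (!col %in% names(df)) {
      proj_error("bad_ontology", sprintf("missing column '%s'", col))
    }
  }
  if (is.null(df$is_fiber_tract)) df$is_fiber_tract <- FALSE
  if (is.null(df$hemisphere)) df$hemisphere <- "B"
  if (is.null(df$layer)) df$layer <- NA_character_
  if (anyDuplicated(df$region_id)) proj_error("bad_ontology", "duplicate region_id")
  if (anyDuplicated(df$acronym)) proj_error("bad_ontology", "duplicate acronym")
  known <- df$parent_id %in% df$region_id | is.na(df$parent_id)
  if (!all(known)) proj_error("bad_ontology", "parent_id not in table")
  class(df) <- c("region_ontology", "data.frame")
  # acyclicity: every region must reach a root
  for (id in df$region_id) region_ancestors(df, id)
  df
}

#' Ancestors of a region
#'
#' Walks parent links from a region to the ontology root.
#'
#' @param ont a [region_ontology()].
#' @param region_id a region id present in the ontology.
#' @return integer vector of ancestor ids ordered leaf-to-root, excluding
#'   `region_id` itself; empty for a root.
#' @export
region_ancestors <- function(ont, region_id) {
  if (!region_id %in% ont$region_id) {
    proj_error("unknown_region", sprintf("unknown region id %s", region_id))
  }
  out <- integer(0)
  cur <- region_id
  repeat {
    p <- ont$parent_id[match(cur, ont$region_id)]
    if (is.na(p)) break
    if (p %in% c(out, region_id)) {
      proj_error("bad_ontology",
                 sprintf("cycle in ontology at region %s", region_id))
    }
    out <- c(out, p)
    cur <- p
  }
  out
}

# map leaf region ids to the nearest ancestor-or-self within `level_ids`;
# 0 / unmatched ids map to 0 (background)
.aggregate_to_level <- function(ont, region_ids, level_ids) {
  vapply(region_ids, function(id) {
    if (id == 0 || !(id %in% ont$region_id)) return(0L)
    chain <- c(id, region_ancestors(ont, id))
    hit <- chain[chain %in% level_ids]
    if (length(hit) == 0) 0L else as.integer(hit[1])
  }, integer(1))
}

# Serialization ---------------------------------------------------------

#' Write a label volume as NRRD
#'
#' Minimal NRRD writer (int32 labels, `ascii` or little-endian `raw`
#' encoding) carrying voxel size and origin in the header. The companion
#' of [read_nrrd()].
#'
#' @param vol a [label_volume()].
#' @param path output file path.
#' @param encoding `"ascii"` (text, diff-friendly) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(vol, path, encoding = c("ascii", "raw")) {
  encoding <- match.arg(encoding)
  d <- dim(vol$labels)
  header <- c(
    "NRRD0004",
    "# label volume",
    "type: int32",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            vol$voxel_size[1], vol$voxel_size[2], vol$voxel_size[3]),
    sprintf("space origin: (%g,%g,%g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    "endian: little",
    sprintf("encoding: %s", encoding),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(as.vector(vol$labels), collapse = " "), con)
  } else {
    writeBin(as.vector(vol$labels), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an NRRD label volume
#'
#' Reads the subset of NRRD written by [write_nrrd()]: 3D int32, `ascii`
#' or little-endian `raw` encoding, diagonal space directions.
#'
#' @param path NRRD file path.
#' @return a [label_volume()].
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    header <- c(header, line)
  }
  field <- function(key) {
    hit <- grep(paste0("^", key, ": "), header, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub(paste0("^", key, ": "), "", hit[1])
  }
  sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+]+", s))[[1]])
  dirs <- nums(field("space directions"))
  voxel <- dirs[c(1, 5, 9)]
  origin <- nums(field("space origin"))
  enc <- field("encoding")
  n <- prod(sizes)
  vals <- if (identical(enc, "ascii")) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    readBin(con, integer(), n = n, size = 4, endian = "little")
  }
  label_volume(array(vals, dim = sizes), voxel, origin)
}

#' Write / read a region ontology as CSV
#'
#' @param ont a [region_ontology()].
#' @param path CSV file path.
#' @return `path` invisibly ([write_ontology_csv()]); a
#'   [region_ontology()] ([read_ontology_csv()]).
#' @export
write_ontology_csv <- function(ont, path) {
  utils::write.csv(as.data.frame(ont), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ontology_csv
#' @export
read_ontology_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$is_fiber_tract <- as.logical(df$is_fiber_tract)
  region_ontology(df)
}
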