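# Conditions ------------------------------------------------------------

proj_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "projectome_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Map SWC type codes to structure classes
#'
#' Standard SWC type codes: 1 = soma, 2 = axon, 3 = basal dendrite,
#' 4 = apical dendrite. Codes 3 and 4 are both mapped to `DENDRITE`
#' (basal and apical dendrites are never analysed separately here);
#' every other code maps to `OTHER`. The mapping is total.
#'
#' @param type_code integer vector of SWC type codes.
#' @return character vector with values `"SOMA"`, `"AXON"`, `"DENDRITE"`,
#'   `"OTHER"`.
#' @export
structure_class <- function(type_code) {
  out <- rep("OTHER", length(type_code))
  out[type_code == 1] <- "SOMA"
  out[type_code == 2] <- "AXON"
  out[type_code %in% c(3, 4)] <- "DENDRITE"
  out
}

#' Construct a morphology from a node table
#'
#' A morphology is a rooted tree of 3D-positioned nodes: the unit of
#' analysis for all morphometric and projection quantification. Node
#' coordinates are micrometers. The root is the unique node with
#' `parent == -1` (by convention the soma); additional soma-typed nodes
#' (a soma contour chain) are allowed as ordinary tree nodes.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`. Ids are arbitrary positive integers, not
#'   necessarily consecutive; `parent` is `-1` for the root.
#' @param name free-text neuron name.
#' @param validate if `TRUE` (default) the tree invariants are checked and
#'   the first violation raised as an error.
#' @return an object of class `morphology`: a list with elements `nodes`
#'   (the node table, input order preserved), `root_id` and `name`.
#' @export
morphology <- function(nodes, name = "", validate = TRUE) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes))) {
    proj_error("malformed_morphology",
               paste("node table must have columns:",
                     paste(required, collapse = ", ")))
  }
  nodes <- as.data.frame(nodes)[required]
  rownames(nodes) <- NULL
  root <- nodes$id[nodes$parent == -1]
  m <- structure(
    list(nodes = nodes,
         root_id = if (length(root) == 1) root else NA_integer_,
         name = name),
    class = "morphology")
  if (validate) {
    v <- validate_morphology(m)
    if (nrow(v) > 0) {
      proj_error(paste0("swc_", tolower(gsub("([a-z])([A-Z])", "\\1_\\2",
                                             v$code[1]))),
                 sprintf("invalid morphology '%s': %s (node %s)",
                         name, v$code[1], v$node_id[1]))
    }
  }
  m
}

#' @export
print.morphology <- function(x, ...) {
  cls <- structure_class(x$nodes$type)
  cat(sprintf("<morphology> %s: %d nodes (%d axon, %d dendrite), root id %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$nodes), sum(cls == "AXON"), sum(cls == "DENDRITE"),
              x$root_id))
  invisible(x)
}

#' @export
format.morphology <- function(x, ...) {
  sprintf("<morphology %s, %d nodes>", x$name, nrow(x$nodes))
}

#' Validate morphology invariants
#'
#' Checks the tree invariants without raising: unique node ids, every
#' non-root parent present, exactly one root (`parent == -1`), and
#' acyclicity / single connected component (every node reachable from the
#' root). Violations are returned, one row each, naming the offending node.
#'
#' @param m a `morphology` (or a list with a `nodes` table; invariants are
#'   checked even on objects built with `validate = FALSE`).
#' @return data.frame with columns `code` (one of `DuplicateId`,
#'   `MissingParent`, `MultipleRoots`, `NoRoot`, `CycleDetected`) and
#'   `node_id`. Zero rows iff all invariants hold.
#' @export
validate_morphology <- function(m) {
  nodes <- m$nodes
  bad <- list()
  add <- function(code, ids) {
    if (length(ids) > 0) bad[[length(bad) + 1]] <<-
        data.frame(code = code, node_id = ids)
  }
  dup <- nodes$id[duplicated(nodes$id)]
  add("DuplicateId", unique(dup))
  nonroot <- nodes$parent != -1
  missing <- nodes$parent[nonroot & !(nodes$parent %in% nodes$id)]
  add("MissingParent", unique(missing))
  roots <- nodes$id[!nonroot]
  if (length(roots) == 0) add("NoRoot", NA_integer_)
  if (length(roots) > 1) add("MultipleRoots", roots)
  # Reachability from the root detects both cycles and disconnection;
  # only meaningful when ids are unique and parents resolve.
  if (length(dup) == 0 && length(missing) == 0 && length(roots) == 1) {
    parent_idx <- match(nodes$parent, nodes$id)  # NA at root
    reached <- is.na(parent_idx)                 # root
    repeat {
      newly <- !reached & reached[parent_idx]
      newly[is.na(newly)] <- FALSE
      if (!any(newly)) break
      reached <- reached | newly
    }
    add("CycleDetected", nodes$id[!reached])
  }
  if (length(bad) == 0) {
    data.frame(code = character(), node_id = integer())
  } else {
    do.call(rbind, bad)
  }
}

#' Read a neuron reconstruction from an SWC file
#'
#' Parses standard whitespace-delimited 7-column SWC
#' (`id type x y z radius parent`), with `#` comment lines. Parsing is
#' two-pass, so forward parent references (a child line before its parent
#' line) are accepted; node order is preserved as in the file. Coordinates
#' are taken to be micrometers; no unit auto-detection is attempted.
#'
#' @param source path to an SWC file, or a character vector of SWC lines.
#' @param name neuron name; defaults to the file base name.
#' @return a validated [morphology()].
#' @export
read_swc <- function(source, name = NULL) {
  if (length(source) == 1 && !grepl("\n", source) &&
      (file.exists(source) || grepl("\\.swc$", source, ignore.case = TRUE))) {
    if (!file.exists(source)) {
      proj_error("io_failure", sprintf("SWC file not found: %s", source))
    }
    lines <- readLines(source, warn = FALSE)
    if (is.null(name)) name <- sub("\\.swc$", "", basename(source),
                                   ignore.case = TRUE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(name)) name <- ""
  }
  lines <- sub("#.*$", "", lines)
  keep <- grepl("[^[:space:]]", lines)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0) {
    proj_error("swc_malformed_line", "SWC source contains no data lines")
  }
  fields <- strsplit(lines, "[[:space:]]+")
  ncol <- lengths(fields)
  if (any(ncol != 7)) {
    i <- which(ncol != 7)[1]
    proj_error("swc_malformed_line",
               sprintf("line %d has %d fields (7 expected)",
                       lineno[i], ncol[i]))
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    i <- ceiling(which(is.na(vals))[1] / 7)
    proj_error("swc_malformed_line",
               sprintf("line %d contains a non-numeric field", lineno[i]))
  }
  mat <- matrix(vals, ncol = 7, byrow = TRUE)
  nodes <- data.frame(id = as.integer(mat[, 1]), type = as.integer(mat[, 2]),
                      x = mat[, 3], y = mat[, 4], z = mat[, 5],
                      radius = mat[, 6], parent = as.integer(mat[, 7]))
  if (any(nodes$radius < 0)) {
    proj_error("swc_malformed_line", "negative radius")
  }
  morphology(nodes, name = name)
}

#' Write a morphology to an SWC file
#'
#' Emits standard 7-column SWC with full double precision (`%.17g`), so
#' `read_swc(write_swc(m))` reproduces `m` exactly — ids, type codes,
#' coordinates, radii and parents — and repeated writes of the same
#' morphology are byte-identical.
#'
#' @param m a valid `morphology`.
#' @param target output file path, or a connection.
#' @return `target`, invisibly.
#' @export
write_swc <- function(m, target) {
  n <- m$nodes
  lines <- c(
    sprintf("# SWC export%s",
            if (nzchar(m$name)) paste0(": ", m$name) else ""),
    "# id type x y z radius parent",
    sprintf("%d %d %.17g %.17g %.17g %.17g %d",
            n$id, n$type, n$x, n$y, n$z, n$radius, n$parent))
  tryCatch(writeLines(lines, target),
           error = function(e) proj_error("io_failure", conditionMessage(e)))
  invisible(target)
}
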