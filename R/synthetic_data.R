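# Synthetic study inputs: a two-hemisphere box-region atlas and seeded
# IT-like neuron morphologies with known ground truth.
#
# The atlas is a mirror-symmetric pair of hemispheres populated with the
# region vocabulary of the study system (MOs with cortical layer slabs,
# PL, ORBm, ACA, AI, SS, VIS, RSP, ENT, CP, BLA) plus a corpus-callosum
# band straddling the midline. Neurons are grown as biased random walks:
# one axon stem, shafts routed to each target region (through the cc band
# for contralateral targets of callosal neurons), and a bifurcating arbor
# confined to each target box that consumes the cable allocated to it.
# All randomness derives from the spec seed; the realized per-region cable
# allocation is recorded at generation time as ground truth.

# fold coordinates into [lo, hi] by reflection (triangle wave)
.fold <- function(v, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(rep(lo, length(v)))
  t <- (v - lo) %% (2 * span)
  lo + ifelse(t <= span, t, 2 * span - t)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

#' Default synthetic atlas specification
#'
#' An 8 x 8 x 4 mm two-hemisphere brain with midline at x = 4000 um.
#' Region boxes are given for the right hemisphere (x > midline) in
#' absolute micrometers `c(x0, x1, y0, y1, z0, z1)` (y: anterior -> posterior,
#' z: pial surface -> depth) and mirrored to the left; the soma-hosting
#' areas (MOs, PL, ORBm) carry layer slabs L1 / L2/3 / L5 along z. The
#' corpus-callosum band is a bilateral box straddling the midline at
#' white-matter depth. All box bounds are multiples of the voxel size so
#' the rasterization is exactly mirror-symmetric.
#'
#' @param voxel_size_um voxel edge (isotropic), micrometers.
#' @return list of class `atlas_spec`.
#' @export
default_atlas_spec <- function(voxel_size_um = 100) {
  regions <- list(
    list(acronym = "MOs",  box = c(4300, 5500, 1000, 2800, 0, 1200),
         layers = list("L1" = c(0, 200), "L2/3" = c(200, 600),
                       "L5" = c(600, 1200))),
    list(acronym = "PL",   box = c(4100, 4300, 200, 1000, 0, 1000),
         layers = list("L1" = c(0, 200), "L2/3" = c(200, 600),
                       "L5" = c(600, 1000))),
    list(acronym = "ORBm", box = c(4300, 5200, 200, 1000, 0, 800),
         layers = list("L1" = c(0, 200), "L2/3" = c(200, 500),
                       "L5" = c(500, 800))),
    list(acronym = "ACA",  box = c(4100, 4300, 1000, 4200, 0, 800)),
    list(acronym = "AI",   box = c(6800, 7600, 1000, 3200, 0, 1000)),
    list(acronym = "SS",   box = c(5500, 6800, 1800, 4200, 0, 1200)),
    list(acronym = "VIS",  box = c(4800, 6400, 5400, 6800, 0, 1000)),
    list(acronym = "RSP",  box = c(4100, 4800, 4200, 6800, 0, 800)),
    list(acronym = "ENT",  box = c(6400, 7600, 5400, 7000, 1000, 2200)),
    list(acronym = "CP",   box = c(5000, 6600, 1400, 3800, 1600, 3000)),
    list(acronym = "BLA",  box = c(6200, 7200, 3800, 4800, 2200, 3200)))
  structure(list(
    extent_um = c(8000, 8000, 4000),
    voxel_size_um = voxel_size_um,
    midline = midline_plane("x", 4000),
    regions = regions,
    cc_box = c(3400, 4600, 1000, 4500, 1300, 1600)),
    class = "atlas_spec")
}

#' Build a synthetic atlas from a specification
#'
#' Deterministically rasterizes the spec's region boxes into a label
#' volume (later boxes overwrite earlier ones), builds the region
#' ontology (root -> bilateral area -> hemisphere -> layer leaves), and
#' returns the midline plane. Left-hemisphere regions are exact mirror
#' images of their right twins.
#'
#' @param spec an atlas specification, see [default_atlas_spec()].
#' @return list with elements `volume` ([label_volume()]), `ontology`
#'   ([region_ontology()]) and `midline` ([midline_plane()]).
#' @export
make_atlas <- function(spec = default_atlas_spec()) {
  d_um <- spec$voxel_size_um
  dims <- as.integer(spec$extent_um / d_um)
  xm <- spec$midline$coordinate
  labels <- array(0L, dim = dims)

  check_box <- function(b, acr) {
    if (any(b[c(1, 3, 5)] >= b[c(2, 4, 6)]) ||
        b[1] < 0 || b[3] < 0 || b[5] < 0 ||
        b[2] > spec$extent_um[1] || b[4] > spec$extent_um[2] ||
        b[6] > spec$extent_um[3]) {
      proj_error("box_out_of_bounds",
                 sprintf("region box '%s' is degenerate or outside the extent",
                         acr))
    }
  }
  rasterize <- function(b, id) {
    i <- (ceiling(b[1] / d_um) + 1):(floor(b[2] / d_um))
    j <- (ceiling(b[3] / d_um) + 1):(floor(b[4] / d_um))
    k <- (ceiling(b[5] / d_um) + 1):(floor(b[6] / d_um))
    labels[i, j, k] <<- id
  }
  mirror_box <- function(b) c(2 * xm - b[2], 2 * xm - b[1], b[3:6])

  rows <- list()
  next_id <- 0L
  add_row <- function(acronym, name, parent, fiber = FALSE, hemi = "B",
                      layer = NA_character_) {
    next_id <<- next_id + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      region_id = next_id, acronym = acronym, name = name,
      parent_id = parent, is_fiber_tract = fiber, hemisphere = hemi,
      layer = layer, stringsAsFactors = FALSE)
    next_id
  }

  root <- add_row("brain", "whole brain", NA_integer_)
  boxes <- list()  # acronym -> absolute box, for the generator
  for (rg in spec$regions) {
    check_box(rg$box, rg$acronym)
    area <- add_row(rg$acronym, rg$acronym, root)
    for (hemi in c("R", "L")) {
      hbox <- if (hemi == "R") rg$box else mirror_box(rg$box)
      hnode <- add_row(paste0(rg$acronym, "_", hemi),
                       paste(rg$acronym, "hemisphere", hemi), area,
                       hemi = hemi)
      if (is.null(rg$layers)) {
        rasterize(hbox, hnode)
        boxes[[paste0(rg$acronym, "_", hemi)]] <- hbox
      } else {
        zs <- do.call(rbind, rg$layers)
        if (any(zs[, 1] < rg$box[5]) || any(zs[, 2] > rg$box[6]) ||
            any(zs[-1, 1] < zs[-nrow(zs), 2])) {
          proj_error("overlapping_layer_slabs",
                     sprintf("layer slabs of '%s' overlap or leave the box",
                             rg$acronym))
        }
        for (ln in names(rg$layers)) {
          lb <- hbox
          lb[5:6] <- rg$layers[[ln]]
          leaf_acr <- paste0(rg$acronym, sub("^L", "", ln), "_", hemi)
          leaf <- add_row(leaf_acr, paste(rg$acronym, ln, hemi), hnode,
                          hemi = hemi, layer = ln)
          rasterize(lb, leaf)
          boxes[[leaf_acr]] <- lb
        }
      }
    }
  }
  check_box(spec$cc_box, "cc")
  cc <- add_row("cc", "corpus callosum band", root, fiber = TRUE)
  rasterize(spec$cc_box, cc)
  boxes[["cc"]] <- spec$cc_box

  ont <- region_ontology(do.call(rbind, rows))
  list(volume = label_volume(labels, rep(d_um, 3), c(0, 0, 0)),
       ontology = ont, midline = spec$midline, boxes = boxes,
       cc_region = cc)
}

#' Simulate one IT-like neuron
#'
#' Grows a morphology against a synthetic atlas: a short axon stem leaves
#' the soma, a jittered shaft runs to each target region (via a waypoint
#' inside the corpus-callosum band for contralateral targets), and a
#' bifurcating random-walk arbor confined to the target box consumes the
#' cable allocated to that target (arbor cable is split across targets in
#' proportion to the spec weights, after subtracting the realized routing
#' cable). A local dendritic arbor is grown around the soma. All
#' randomness comes from `spec$seed`; the caller's RNG state is restored.
#'
#' The returned ground truth records the REALIZED allocation: per-region
#' fractions of axonal cable, booked by fine subdivision (pieces no longer
#' than a fifth of a voxel edge) of the actual geometry — routing cable is
#' booked to whatever regions it traverses, like real axons passing
#' through white matter.
#'
#' @param spec list with fields `name`, `soma` (xyz, um), `class`
#'   (`"CPN"`/`"APN"`), `weights` (named fractions over target-region
#'   acronyms, summing to 1), `axon_total_um`, `dendrite_total_um`,
#'   `axon_branch_rate_per_mm`, `dend_branch_rate_per_mm`, `step_um`
#'   (default 25), `seed`.
#' @param atlas output of [make_atlas()].
#' @return list with `morphology` and `truth` (name, class, requested
#'   weights, `realized_fractions` named by region id, `realized_total_um`,
#'   `contra_um`, `soma_side`, seed).
#' @export
simulate_neuron <- function(spec, atlas) {
  if (abs(sum(spec$weights) - 1) > 1e-6 || any(spec$weights < 0)) {
    proj_error("bad_spec", "target weights must be >= 0 and sum to 1")
  }
  missing <- setdiff(names(spec$weights), names(atlas$boxes))
  if (length(missing) > 0) {
    proj_error("unreachable_target",
               paste("unknown target region(s):",
                     paste(missing, collapse = ", ")))
  }
  if (region_at(atlas$volume, spec$soma) == 0) {
    proj_error("bad_spec", "soma must lie inside a labeled region")
  }
  step <- if (is.null(spec$step_um)) 25 else spec$step_um
  if (!is.null(spec$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
  }

  # node accumulator
  acc <- new.env()
  acc$chunks <- list()
  acc$n <- 0L
  emit_chain <- function(pts, parent_id, type, radius = 0.5) {
    k <- nrow(pts)
    ids <- acc$n + seq_len(k)
    acc$chunks[[length(acc$chunks) + 1]] <- cbind(
      ids, type, pts[, 1], pts[, 2], pts[, 3], radius,
      c(parent_id, ids[-k]))
    acc$n <- acc$n + k
    ids[k]
  }

  soma <- spec$soma
  acc$chunks[[1]] <- cbind(1, 1, soma[1], soma[2], soma[3], 8, -1)
  acc$n <- 1L

  extent_box <- c(0, atlas$volume$voxel_size[1] * dim(atlas$volume$labels)[1],
                  0, atlas$volume$voxel_size[2] * dim(atlas$volume$labels)[2],
                  0, atlas$volume$voxel_size[3] * dim(atlas$volume$labels)[3])

  chain_len <- function(pts, from) {
    all_pts <- rbind(from, pts)
    sum(sqrt(rowSums((all_pts[-1, , drop = FALSE] -
                      all_pts[-nrow(all_pts), , drop = FALSE])^2)))
  }

  # jittered polyline through waypoints, endpoints exact
  make_shaft <- function(from, waypoints, jitter = 5) {
    pts <- NULL
    cur <- from
    for (w in waypoints) {
      leg <- sqrt(sum((w - cur)^2))
      n <- max(1L, as.integer(ceiling(leg / step)))
      t <- seq_len(n) / n
      seg <- cbind(cur[1] + t * (w[1] - cur[1]),
                   cur[2] + t * (w[2] - cur[2]),
                   cur[3] + t * (w[3] - cur[3]))
      if (n > 1) {
        seg[-n, ] <- seg[-n, ] + matrix(stats::rnorm(3 * (n - 1), 0, jitter),
                                        ncol = 3)
      }
      pts <- rbind(pts, seg)
      cur <- w
    }
    pts
  }

  # bifurcating random-walk arbor confined to `box`; consumes `budget` um
  grow_arbor <- function(attach_id, start, box, budget, rate_per_mm, type,
                         tort = 0.6) {
    mean_seg <- 1000 / rate_per_mm
    q_pos <- list(start); q_dir <- list(.unit(stats::rnorm(3)))
    q_att <- attach_id
    head <- 1L
    remaining <- budget
    while (remaining > step / 2 && head <= length(q_pos)) {
      pos <- q_pos[[head]]; dir <- q_dir[[head]]; att <- q_att[head]
      head <- head + 1L
      seg <- min(max(stats::rexp(1, rate_per_mm / 1000), step), 4 * mean_seg)
      seg <- min(seg, max(remaining, step))
      n <- max(1L, as.integer(round(seg / step)))
      pts <- matrix(0, n, 3)
      p <- pos
      for (s in seq_len(n)) {
        dir <- .unit(dir + tort * stats::rnorm(3))
        p <- p + dir * step
        pts[s, ] <- p
      }
      pts[, 1] <- .fold(pts[, 1], box[1], box[2])
      pts[, 2] <- .fold(pts[, 2], box[3], box[4])
      pts[, 3] <- .fold(pts[, 3], box[5], box[6])
      last <- emit_chain(pts, att, type)
      remaining <- remaining - chain_len(pts, pos)
      if (remaining > step / 2) {
        endp <- pts[n, ]
        for (b in 1:2) {
          q_pos[[length(q_pos) + 1]] <- endp
          q_dir[[length(q_dir) + 1]] <- .unit(dir + stats::rnorm(3))
          q_att <- c(q_att, last)
        }
      }
    }
  }

  # --- axon ---
  soma_side <- hemisphere_of(soma, atlas$midline)
  stem_end_pt <- soma + c(0, 0, 2 * step)
  stem_id <- emit_chain(rbind(soma + c(0, 0, step), stem_end_pt), 1L, 2L)
  cc_box <- atlas$boxes[["cc"]]
  xm <- atlas$midline$coordinate

  targets <- names(spec$weights)
  shafts <- list()
  overhead <- 2 * step
  # the arbor is seeded where the shaft enters the target box (inset a
  # little), not at the box center: shorter, more realistic routing
  box_anchor <- function(b, from) {
    inset <- pmin(150, (b[c(2, 4, 6)] - b[c(1, 3, 5)]) / 4)
    pmin(pmax(from, b[c(1, 3, 5)] + inset), b[c(2, 4, 6)] - inset)
  }
  for (tg in targets) {
    b <- atlas$boxes[[tg]]
    center <- c(mean(b[1:2]), mean(b[3:4]), mean(b[5:6]))
    tg_side <- hemisphere_of(center, atlas$midline)
    wps <- list()
    last_wp <- stem_end_pt
    if (tg_side != soma_side && tg_side != "ON_MIDLINE") {
      cc_y <- min(max((soma[2] + center[2]) / 2, cc_box[3] + 100),
                  cc_box[4] - 100)
      wps[[1]] <- c(xm, cc_y, mean(cc_box[5:6]))
      last_wp <- wps[[1]]
    }
    anchor <- box_anchor(b, last_wp)
    wps[[length(wps) + 1]] <- anchor
    pts <- make_shaft(stem_end_pt, wps)
    shafts[[tg]] <- list(pts = pts, center = anchor)
    overhead <- overhead + chain_len(pts, stem_end_pt)
  }
  # each target's shaft is charged against that target's cable allocation,
  # so realized per-target fractions track the requested weights up to the
  # part of the shaft lying outside the target box
  w <- spec$weights / sum(spec$weights)
  alloc <- w * (spec$axon_total_um - 2 * step)
  shaft_len <- vapply(targets, function(tg)
    chain_len(shafts[[tg]]$pts, stem_end_pt), 0)
  # every target keeps at least a minimal arbor; what remains above the
  # floors is split in proportion to each target's allocation surplus, so
  # the total cable laid equals the spec total no matter how much routing
  # the geometry required
  min_arbor <- 8 * step
  arbor_total <- spec$axon_total_um - 2 * step - sum(shaft_len)
  if (arbor_total < min_arbor * length(targets)) {
    proj_error("unreachable_target",
               sprintf("axon budget %.0f um cannot cover %.0f um of routing to %d targets",
                       spec$axon_total_um, sum(shaft_len), length(targets)))
  }
  excess <- pmax(alloc[targets] - shaft_len - min_arbor, 0)
  slack <- arbor_total - min_arbor * length(targets)
  arbor_budget <- if (sum(excess) > 0) {
    min_arbor + excess * slack / sum(excess)
  } else {
    stats::setNames(rep(arbor_total / length(targets), length(targets)),
                    targets)
  }
  # routing cable is unbranched; raise the arbor branching rate so the
  # whole-cell branches-per-mm matches the requested rate
  eff_rate <- spec$axon_branch_rate_per_mm *
    spec$axon_total_um / max(sum(arbor_budget), 1)
  for (tg in targets) {
    sh <- shafts[[tg]]
    tip_id <- emit_chain(sh$pts, stem_id, 2L)
    grow_arbor(tip_id, sh$center, atlas$boxes[[tg]],
               arbor_budget[[tg]], eff_rate, 2L)
  }

  # --- dendrite: local arbor around the soma ---
  dbox <- c(max(extent_box[1], soma[1] - 250), min(extent_box[2], soma[1] + 250),
            max(extent_box[3], soma[2] - 250), min(extent_box[4], soma[2] + 250),
            max(extent_box[5], soma[3] - 150), min(extent_box[6], soma[3] + 250))
  grow_arbor(1L, soma, dbox, spec$dendrite_total_um,
             spec$dend_branch_rate_per_mm, 3L, tort = 0.9)

  mat <- do.call(rbind, acc$chunks)
  nodes <- data.frame(id = as.integer(mat[, 1]), type = as.integer(mat[, 2]),
                      x = mat[, 3], y = mat[, 4], z = mat[, 5],
                      radius = mat[, 6], parent = as.integer(mat[, 7]))
  m <- morphology(nodes, name = spec$name)

  # --- ground truth: fine-subdivision booking of the realized geometry ---
  gt_step <- min(atlas$volume$voxel_size) / 5
  pieces <- subdivide_cable(m, gt_step, "AXON")
  ids <- region_at(atlas$volume, cbind(pieces$mx, pieces$my, pieces$mz))
  lens <- rowsum(pieces$len, ids)
  total <- sum(lens)
  side <- hemisphere_of(cbind(pieces$mx, pieces$my, pieces$mz), atlas$midline)
  contra_side <- setdiff(c("LEFT", "RIGHT"), soma_side)
  truth <- list(
    name = spec$name, class = spec$class,
    weights = as.list(spec$weights),
    realized_fractions = stats::setNames(as.vector(lens) / total,
                                         rownames(lens)),
    realized_total_um = total,
    contra_um = sum(pieces$len[side == contra_side]),
    soma = soma, soma_side = soma_side, seed = spec$seed)
  list(morphology = m, truth = truth)
}

# Population presets ----------------------------------------------------

# Per-group regimes: printed group mean / sem / n give the truncated-normal
# draw (sd = sem * sqrt(n), location calibrated so the truncated mean equals
# the printed mean); branching rates are branches per mm of cable.
.presets <- function() {
  list(
    MOs_L5 = list(
      soma_leaf = "MOs5_R", cpn_frac = 1,
      axon_mm = c(mean = 270.58, sem = 58.93, n = 6),
      axon_range = c(180.04, 318.43),
      dend_mm = c(mean = 7.40, sem = 0.76, n = 6),
      axon_rate = 2964.33 / 270.58, dend_rate = 143.67 / 7.40,
      w_cpn = c(CP_R = 0.28, `MOs2/3_R` = 0.08, MOs5_R = 0.06, AI_R = 0.05,
                CP_L = 0.25, `MOs2/3_L` = 0.10, SS_L = 0.10, AI_L = 0.08),
      w_apn = c(CP_R = 0.40, `MOs2/3_R` = 0.20, MOs5_R = 0.10, AI_R = 0.15,
                BLA_R = 0.15)),
    MOs_L23 = list(
      soma_leaf = "MOs2/3_R", cpn_frac = 10 / 17,
      axon_mm = c(mean = 70.05, sem = 9.61, n = 17),
      axon_range = NULL,
      dend_mm = c(mean = 6.07, sem = 0.69, n = 17),
      axon_rate = 1054.71 / 70.05, dend_rate = 147.76 / 6.07,
      w_cpn = c(`MOs2/3_R` = 0.15, CP_R = 0.15, AI_R = 0.05, ACA_R = 0.05,
                `MOs2/3_L` = 0.25, CP_L = 0.20, SS_L = 0.10, AI_L = 0.05),
      w_apn = c(`MOs2/3_R` = 0.25, CP_R = 0.30, AI_R = 0.15, BLA_R = 0.10,
                ENT_R = 0.10, ACA_R = 0.10)),
    PL_L23 = list(
      soma_leaf = "PL2/3_R", cpn_frac = 1 / 6,
      axon_mm = c(mean = 65.47, sem = 12.24, n = 6),
      axon_range = NULL,
      dend_mm = c(mean = 5.77, sem = 1.09, n = 6),
      axon_rate = 820.17 / 65.47, dend_rate = 122.33 / 5.77,
      w_cpn = c(`PL2/3_R` = 0.15, ACA_R = 0.10, CP_R = 0.15, `ORBm2/3_R` = 0.10,
                `PL2/3_L` = 0.20, `MOs2/3_L` = 0.15, ACA_L = 0.15),
      w_apn = c(`PL2/3_R` = 0.25, `ORBm2/3_R` = 0.15, AI_R = 0.15, CP_R = 0.20,
                RSP_R = 0.10, ENT_R = 0.15)),
    ORBm_L23 = list(
      soma_leaf = "ORBm2/3_R", cpn_frac = 5 / 7,
      axon_mm = c(mean = 66.94, sem = 9.17, n = 7),
      axon_range = NULL,
      dend_mm = c(mean = 5.49, sem = 0.58, n = 7),
      axon_rate = 954.71 / 66.94, dend_rate = 121.71 / 5.49,
      w_cpn = c(`ORBm2/3_R` = 0.15, `PL2/3_R` = 0.10, CP_R = 0.15, AI_R = 0.05,
                `ORBm2/3_L` = 0.20, `MOs2/3_L` = 0.15, `PL2/3_L` = 0.10,
                AI_L = 0.05, ENT_L = 0.05),
      w_apn = c(`ORBm2/3_R` = 0.25, `PL2/3_R` = 0.15, `MOs2/3_R` = 0.10,
                CP_R = 0.20, AI_R = 0.15, VIS_R = 0.15)))
}

#' Names of the built-in population regimes
#' @return character vector of preset names.
#' @export
population_regimes <- function() names(.presets())

# truncated-normal draw whose TRUNCATED mean equals `mean`: the location is
# shifted by a monotone solve before drawing
.rtruncnorm_calibrated <- function(n, mean, sd, lower, upper) {
  tmean <- function(mu) {
    a <- (lower - mu) / sd; b <- (upper - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       interval = c(lower - 4 * sd, upper + 4 * sd))$root
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mu, sd)
      if (v >= lower && v <= upper) break
    }
    out[i] <- v
  }
  out
}

#' Simulate a population of IT neurons under a named regime
#'
#' Draws per-neuron specs from a preset parameterized by the printed
#' group statistics (axonal / dendritic totals as calibrated truncated
#' normals, branching rates, CPN fraction and target-weight profiles with
#' Dirichlet jitter) and grows each neuron with [simulate_neuron()]. The
#' first `round(n * cpn_frac)` neurons are CPNs, the rest APNs, so class
#' counts are exact for the study group sizes. Fully reproducible under
#' `seed`.
#'
#' @param n number of neurons (>= 1).
#' @param regime one of [population_regimes()].
#' @param seed integer seed; all per-neuron seeds derive from it.
#' @param atlas output of [make_atlas()]; built on the fly if `NULL`.
#' @return list of `n` elements, each as returned by [simulate_neuron()].
#' @export
simulate_population <- function(n, regime = "MOs_L5", seed = 1,
                                atlas = NULL) {
  stopifnot(n >= 1)
  preset <- .presets()[[regime]]
  if (is.null(preset)) {
    proj_error("bad_spec", sprintf("unknown regime '%s'", regime))
  }
  if (is.null(atlas)) atlas <- make_atlas()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  sb <- atlas$boxes[[preset$soma_leaf]]
  margin <- 50
  ax <- preset$axon_mm
  rng <- if (is.null(preset$axon_range)) {
    c(0.5 * ax[["mean"]], 2 * ax[["mean"]])
  } else preset$axon_range
  axon_mm <- .rtruncnorm_calibrated(n, ax[["mean"]],
                                    ax[["sem"]] * sqrt(ax[["n"]]),
                                    rng[1], rng[2])
  de <- preset$dend_mm
  dend_mm <- .rtruncnorm_calibrated(n, de[["mean"]],
                                    de[["sem"]] * sqrt(de[["n"]]),
                                    0.4 * de[["mean"]], 2 * de[["mean"]])
  n_cpn <- round(n * preset$cpn_frac)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- if (i <= n_cpn) "CPN" else "APN"
    base_w <- if (cls == "CPN") preset$w_cpn else preset$w_apn
    jw <- stats::rgamma(length(base_w), shape = base_w * 60)
    weights <- stats::setNames(jw / sum(jw), names(base_w))
    soma <- c(stats::runif(1, sb[1] + margin, sb[2] - margin),
              stats::runif(1, sb[3] + margin, sb[4] - margin),
              stats::runif(1, sb[5] + margin, sb[6] - margin))
    spec <- list(name = sprintf("%s_n%02d", regime, i), soma = soma,
                 class = cls, weights = weights,
                 axon_total_um = axon_mm[i] * 1000,
                 dendrite_total_um = dend_mm[i] * 1000,
                 axon_branch_rate_per_mm = preset$axon_rate,
                 dend_branch_rate_per_mm = preset$dend_rate,
                 step_um = 25, seed = seeds[i])
    out[[i]] <- simulate_neuron(spec, atlas)
  }
  out
}
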