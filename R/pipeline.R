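# End-to-end pipeline drivers: simulate study inputs to disk, analyze a
# directory of SWC reconstructions against an atlas, and render a
# markdown report. These are the functions the analysis/ scripts call;
# every run writes its effective configuration so results are exactly
# reproducible.

#' Default run configuration
#'
#' Flat key-value configuration for the pipeline. Unknown keys are
#' rejected by [run_config()].
#'
#' Keys: `outdir`; `seed`; `step_um` (cable subdivision, `NA` = smallest
#' voxel edge); `min_contra_mm` (CPN threshold); `theta` (target
#' binarization); `jaccard_cutoff` (category linkage); `downsample_factors`
#' (length 3); `welch`; `include_background`; `n_mos_l5`, `n_mos_l23`,
#' `n_pl_l23`, `n_orbm_l23` (demo population group sizes, defaulting to
#' the study's 6 + 17 + 6 + 7).
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(outdir = "results", seed = 1) {
  structure(list(
    outdir = outdir, seed = seed, step_um = NA_real_,
    min_contra_mm = 1.0, theta = 0.05, jaccard_cutoff = 0.5,
    downsample_factors = c(1L, 1L, 1L),
    welch = FALSE, include_background = TRUE,
    n_mos_l5 = 6L, n_mos_l23 = 17L, n_pl_l23 = 6L, n_orbm_l23 = 7L),
    class = "run_config")
}

#' Build and validate a run configuration
#'
#' @param ... overrides of [default_run_config()] keys; an unknown key is
#'   a configuration error.
#' @param outdir,seed as in [default_run_config()].
#' @return validated `run_config`.
#' @export
run_config <- function(outdir = "results", seed = 1, ...) {
  cfg <- default_run_config(outdir, seed)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    proj_error("config_error",
               paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  for (k in names(dots)) cfg[[k]] <- dots[[k]]
  with(cfg, {
    if (!is.na(step_um) && step_um <= 0)
      proj_error("config_error", "step_um must be > 0")
    if (min_contra_mm < 0) proj_error("config_error", "min_contra_mm < 0")
    if (theta < 0 || theta > 1) proj_error("config_error", "theta not in [0,1]")
    if (jaccard_cutoff < 0 || jaccard_cutoff > 1)
      proj_error("config_error", "jaccard_cutoff not in [0,1]")
    if (length(downsample_factors) != 3 || any(downsample_factors < 1))
      proj_error("config_error", "downsample_factors must be 3 values >= 1")
  })
  cfg
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.manifest <- function(dir, files) {
  data.frame(file = files,
             md5 = unname(tools::md5sum(file.path(dir, files))),
             stringsAsFactors = FALSE)
}

#' Simulate the demo study inputs to disk
#'
#' Builds the synthetic atlas and a demo population (default 6 MOs layer-5
#' + 17 MOs layer-2/3 + 6 PL + 7 ORBm neurons, the study's group sizes)
#' and writes: `atlas.nrrd`, `ontology.csv`, `swc/<name>.swc` per neuron,
#' `truth/<name>.json` ground-truth records, and a checksum manifest.
#' Fully deterministic for a given seed.
#'
#' @param config a [run_config()].
#' @return the manifest data.frame, invisibly.
#' @export
run_simulate <- function(config = default_run_config()) {
  out <- config$outdir
  for (d in c(out, file.path(out, "swc"), file.path(out, "truth"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  atlas <- make_atlas()
  write_nrrd(atlas$volume, file.path(out, "atlas.nrrd"))
  write_ontology_csv(atlas$ontology, file.path(out, "ontology.csv"))
  groups <- c(MOs_L5 = config$n_mos_l5, MOs_L23 = config$n_mos_l23,
              PL_L23 = config$n_pl_l23, ORBm_L23 = config$n_orbm_l23)
  files <- c("atlas.nrrd", "ontology.csv")
  for (gi in seq_along(groups)) {
    if (groups[gi] < 1) next
    pop <- simulate_population(groups[gi], names(groups)[gi],
                               seed = config$seed + gi, atlas = atlas)
    for (nr in pop) {
      swc_rel <- file.path("swc", paste0(nr$morphology$name, ".swc"))
      truth_rel <- file.path("truth", paste0(nr$morphology$name, ".json"))
      write_swc(nr$morphology, file.path(out, swc_rel))
      tr <- nr$truth
      tr$realized_fractions <- as.list(tr$realized_fractions)
      .write_json(tr, file.path(out, truth_rel))
      files <- c(files, swc_rel, truth_rel)
    }
  }
  .write_json(config[order(names(config))], file.path(out, "config.json"))
  manifest <- .manifest(out, files)
  utils::write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Run the full analysis over a directory of reconstructions
#'
#' Reads every `swc/*.swc` under `config$outdir` together with
#' `atlas.nrrd` and `ontology.csv` (as written by [run_simulate()], or
#' supplied by the user in the same layout), then computes and writes:
#' per-neuron morphometrics (`morphometrics.csv`), the neurons x regions
#' projection-strength matrix at area level (`projection_matrix.csv`),
#' per-neuron hemisphere splits (`hemisphere_split.csv`), CPN/APN class
#' records with profile categories (`class_records.csv`), group summaries
#' (`group_summary.csv`) and two-sample comparisons (`comparisons.csv`),
#' plus a `run_log.json` with parameters and package version. Re-running
#' on identical inputs reproduces identical tables.
#'
#' @param config a [run_config()].
#' @return invisible list of the computed tables.
#' @export
run_analyze <- function(config = default_run_config()) {
  out <- config$outdir
  vol <- read_nrrd(file.path(out, "atlas.nrrd"))
  ont <- read_ontology_csv(file.path(out, "ontology.csv"))
  if (any(config$downsample_factors > 1)) {
    vol <- downsample_labels(vol, config$downsample_factors)
  }
  mid <- midline_plane("x", 4000)
  step <- if (is.na(config$step_um)) min(vol$voxel_size) else config$step_um
  cc_id <- ont$region_id[match("cc", ont$acronym)]
  swcs <- sort(list.files(file.path(out, "swc"), pattern = "\\.swc$",
                          full.names = TRUE))
  if (length(swcs) == 0) proj_error("missing_upstream", "no SWC files found")
  neurons <- lapply(swcs, read_swc)

  morpho <- summarize_neurons(neurons)
  profiles <- lapply(neurons, projection_profile, vol = vol, mid = mid,
                     step = step)
  areas <- ont$acronym[is.na(ont$parent_id) |
                         ont$parent_id == ont$region_id[ont$acronym == "brain"]]
  areas <- setdiff(areas, "brain")
  pm <- projection_matrix(profiles, ont, level = areas,
                          include_background = config$include_background)
  splits <- do.call(rbind, lapply(neurons, function(m) {
    hs <- hemisphere_split(m, vol, mid, step)
    data.frame(name = m$name, soma_side = hs$soma_side,
               ipsi_mm = hs$ipsi_length / 1000,
               contra_mm = hs$contra_length / 1000,
               on_midline_mm = hs$on_midline_length / 1000,
               ipsi_fraction = hs$ipsi_fraction,
               contra_fraction = hs$contra_fraction,
               stringsAsFactors = FALSE)
  }))
  records <- do.call(rbind, lapply(neurons, classify_it, vol = vol, ont = ont,
                                   mid = mid, cc_region = cc_id,
                                   min_contra_mm = config$min_contra_mm,
                                   step = step))
  records$category_id <- unname(categorize_profiles(
    pm, theta = config$theta, jaccard_cutoff = config$jaccard_cutoff))

  # group = soma area + layer, as in the study's summary table
  area_of <- function(id) {
    chain <- c(id, region_ancestors(ont, id))
    acr <- ont$acronym[match(chain, ont$region_id)]
    hit <- acr[acr %in% areas]
    if (length(hit)) hit[1] else acr[1]
  }
  morpho$group <- paste0(vapply(records$soma_region, area_of, ""), "_",
                         gsub("[^0-9/]", "", records$soma_layer))
  morpho$it_subclass <- records$it_subclass
  metrics <- c("axon_length_mm", "axon_branches", "axon_tips",
               "dend_length_mm", "dend_branches", "dend_tips")
  summary <- summarize_groups(morpho, "group", metrics)

  comparisons <- list()
  l23 <- morpho[grepl("MOs_2/3", morpho$group), ]
  cpn <- l23[l23$it_subclass == "CPN", ]
  apn <- l23[l23$it_subclass == "APN", ]
  l5 <- morpho[grepl("MOs_5", morpho$group), ]
  cmp4 <- c("axon_length_mm", "dend_length_mm", "axon_branches",
            "dend_branches")
  for (mt in cmp4) {
    if (nrow(cpn) >= 2 && nrow(apn) >= 2) {
      comparisons[[length(comparisons) + 1]] <-
        compare_groups(cpn[[mt]], apn[[mt]], metric = mt,
                       labels = c("MOs_L2/3_CPN", "MOs_L2/3_APN"),
                       welch = config$welch)
    }
    if (nrow(cpn) >= 2 && nrow(l5) >= 2) {
      comparisons[[length(comparisons) + 1]] <-
        compare_groups(cpn[[mt]], l5[[mt]], metric = mt,
                       labels = c("MOs_L2/3_CPN", "MOs_L5_CPN"),
                       welch = config$welch)
    }
  }
  for (pair in list(c("MOs_2/3", "PL_2/3"), c("MOs_2/3", "ORBm_2/3"),
                    c("PL_2/3", "ORBm_2/3"))) {
    a <- morpho[morpho$group == pair[1], ]
    b <- morpho[morpho$group == pair[2], ]
    if (nrow(a) >= 2 && nrow(b) >= 2) {
      for (mt in cmp4) {
        comparisons[[length(comparisons) + 1]] <-
          compare_groups(a[[mt]], b[[mt]], metric = mt, labels = pair,
                         welch = config$welch)
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame()

  wcsv <- function(x, f) utils::write.csv(x, file.path(out, f),
                                          row.names = FALSE)
  wcsv(morpho, "morphometrics.csv")
  utils::write.csv(data.frame(name = rownames(pm), pm, check.names = FALSE),
                   file.path(out, "projection_matrix.csv"), row.names = FALSE)
  wcsv(splits, "hemisphere_split.csv")
  wcsv(records, "class_records.csv")
  wcsv(summary, "group_summary.csv")
  wcsv(comparisons, "comparisons.csv")
  .write_json(list(parameters = config[order(names(config))],
                   n_neurons = length(neurons),
                   step_um = step,
                   package_version = as.character(utils::packageVersion("projectome"))),
              file.path(out, "run_log.json"))
  invisible(list(morphometrics = morpho, projection_matrix = pm,
                 hemisphere_split = splits, class_records = records,
                 group_summary = summary, comparisons = comparisons))
}

#' Render a markdown report of the analysis
#'
#' Produces `report.md` under the output directory: the group summary in
#' the study's table layout (metrics x groups, mean ± s.e.m.), per-neuron
#' ipsilateral / contralateral fractions, class counts and the comparison
#' table. Requires [run_analyze()] outputs.
#'
#' @param config a [run_config()].
#' @return path to the report, invisibly.
#' @export
run_report <- function(config = default_run_config()) {
  out <- config$outdir
  need <- c("group_summary.csv", "hemisphere_split.csv", "class_records.csv",
            "comparisons.csv")
  missing <- need[!file.exists(file.path(out, need))]
  if (length(missing) > 0) {
    proj_error("missing_upstream",
               paste("run_analyze outputs missing:",
                     paste(missing, collapse = ", ")))
  }
  summary <- utils::read.csv(file.path(out, "group_summary.csv"))
  splits <- utils::read.csv(file.path(out, "hemisphere_split.csv"))
  records <- utils::read.csv(file.path(out, "class_records.csv"))
  comparisons <- utils::read.csv(file.path(out, "comparisons.csv"))
  lines <- c(
    "# Single-neuron projectome report", "",
    "## Group morphometrics (mean ± s.e.m.)", "",
    format_group_table(summary), "",
    "## Class counts", "",
    sprintf("- %s: %d neurons", names(table(records$it_subclass)),
            as.integer(table(records$it_subclass))), "",
    "## Per-neuron hemisphere decomposition", "",
    "| Neuron | Side | Ipsi (%) | Contra (%) |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.1f | %.1f |", splits$name, splits$soma_side,
            100 * splits$ipsi_fraction, 100 * splits$contra_fraction), "")
  if (nrow(comparisons) > 0) {
    lines <- c(lines,
      "## Two-sample comparisons (Student's t)", "",
      "| Metric | Groups | t | df | p | |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %s vs %s | %.3f | %.1f | %.4g | %s |",
              comparisons$metric, comparisons$group_a, comparisons$group_b,
              comparisons$t, comparisons$df, comparisons$p,
              comparisons$stars))
  }
  path <- file.path(out, "report.md")
  writeLines(lines, path)
  invisible(path)
}
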