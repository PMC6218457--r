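test_that("atlas rasterization produces mirror-symmetric hemispheres", {
  atlas <- make_atlas()
  ont <- atlas$ontology
  # swap map: L <-> R twins, everything else fixed
  swap <- stats::setNames(ont$region_id, ont$acronym)
  ids <- as.vector(atlas$volume$labels)
  swap_vec <- seq(0, max(ids))
  for (i in seq_len(nrow(ont))) {
    acr <- ont$acronym[i]
    twin <- if (grepl("_R$", acr)) sub("_R$", "_L", acr) else
      if (grepl("_L$", acr)) sub("_L$", "_R", acr) else acr
    swap_vec[ont$region_id[i] + 1] <- swap[[twin]]
  }
  reflected <- atlas$volume$labels[dim(atlas$volume$labels)[1]:1, , ]
  reflected[] <- swap_vec[reflected + 1]
  expect_identical(reflected, atlas$volume$labels)
})

test_that("atlas structure: single-box spec, cc band, ontology links", {
  spec <- default_atlas_spec()
  spec$regions <- list(list(acronym = "X", box = c(4300, 5500, 1000,
                                                   2800, 0, 1200)))
  atlas <- make_atlas(spec)
  ont <- atlas$ontology
  ids <- sort(unique(as.vector(atlas$volume$labels)))
  # background + left/right X + cc band
  expect_setequal(ids, c(0, ont$region_id[ont$acronym %in%
                                            c("X_L", "X_R", "cc")]))
  # mirror pair shares the bilateral area parent
  expect_equal(ont$parent_id[ont$acronym == "X_L"],
               ont$parent_id[ont$acronym == "X_R"])
  # cc voxels straddle the midline
  cc_id <- ont$region_id[ont$acronym == "cc"]
  cc_x <- which(apply(atlas$volume$labels == cc_id, 1, any))
  mid_index <- 4000 / atlas$volume$voxel_size[1]
  expect_true(any(cc_x <= mid_index) && any(cc_x > mid_index))

  bad <- default_atlas_spec()
  bad$regions[[1]]$box <- c(4300, 9500, 1000, 2800, 0, 1200)
  expect_error(make_atlas(bad), class = "box_out_of_bounds")
  ov <- default_atlas_spec()
  ov$regions[[1]]$layers <- list("L1" = c(0, 300), "L2/3" = c(200, 600))
  expect_error(make_atlas(ov), class = "overlapping_layer_slabs")
})

test_that("same spec and seed give byte-identical SWC output", {
  atlas <- make_atlas()
  spec <- list(name = "det", soma = c(4900, 1900, 900), class = "CPN",
               weights = c(CP_R = 0.5, `MOs2/3_L` = 0.5),
               axon_total_um = 30000, dendrite_total_um = 5000,
               axon_branch_rate_per_mm = 12, dend_branch_rate_per_mm = 20,
               seed = 99)
  a <- simulate_neuron(spec, atlas)
  b <- simulate_neuron(spec, atlas)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_swc(a$morphology, f1); write_swc(b$morphology, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_neuron(spec, atlas)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a single-target neuron concentrates its cable in that target", {
  atlas <- make_atlas()
  nr <- simulate_neuron(list(
    name = "solo", soma = c(4900, 1900, 900), class = "APN",
    weights = c(CP_R = 1), axon_total_um = 40000, dendrite_total_um = 5000,
    axon_branch_rate_per_mm = 12, dend_branch_rate_per_mm = 20, seed = 5),
    atlas)
  p <- projection_profile(nr$morphology, atlas$volume, atlas$midline)
  s <- projection_strengths(p, atlas$ontology, level = "CP")
  expect_gte(s[["CP"]], 0.9)
})

test_that("ground truth closure: quantifier matches the generator's booking", {
  atlas <- make_atlas()
  nr <- simulate_neuron(list(
    name = "gt", soma = c(4900, 1900, 900), class = "CPN",
    weights = c(CP_R = 0.3, CP_L = 0.3, `MOs2/3_L` = 0.25, AI_R = 0.15),
    axon_total_um = 60000, dendrite_total_um = 5000,
    axon_branch_rate_per_mm = 14, dend_branch_rate_per_mm = 20, seed = 8),
    atlas)
  p <- projection_profile(nr$morphology, atlas$volume, atlas$midline)
  measured <- p$region_lengths / p$total_axon_length
  truth <- nr$truth$realized_fractions
  keys <- union(names(measured), names(truth))
  mv <- ifelse(is.na(measured[keys]), 0, measured[keys])
  tv <- ifelse(is.na(truth[keys]), 0, truth[keys])
  expect_lt(max(abs(mv - tv)), 0.01)
})

test_that("CPN specs cross through the corpus callosum and classify as CPN", {
  atlas <- make_atlas()
  nr <- simulate_neuron(list(
    name = "cpn", soma = c(4900, 1900, 900), class = "CPN",
    weights = c(CP_R = 0.4, `MOs2/3_L` = 0.6), axon_total_um = 30000,
    dendrite_total_um = 5000, axon_branch_rate_per_mm = 12,
    dend_branch_rate_per_mm = 20, seed = 13), atlas)
  rec <- classify_it(nr$morphology, atlas$volume, atlas$ontology,
                     atlas$midline, "cc")
  expect_equal(rec$it_subclass, "CPN")
  expect_true(rec$crossed_via_cc)
})

test_that("population regimes are reproducible and distinct across seeds", {
  atlas <- make_atlas()
  one <- simulate_population(1, "PL_L23", seed = 4, atlas = atlas)
  expect_length(one, 1)
  again <- simulate_population(1, "PL_L23", seed = 4, atlas = atlas)
  expect_equal(one[[1]]$morphology$nodes, again[[1]]$morphology$nodes)
  other <- simulate_population(1, "PL_L23", seed = 5, atlas = atlas)
  expect_false(isTRUE(all.equal(one[[1]]$morphology$nodes,
                                other[[1]]$morphology$nodes)))
})

test_that("layer-5 regime lands in the printed axonal-length range", {
  atlas <- make_atlas()
  pop <- simulate_population(6, "MOs_L5", seed = 42, atlas = atlas)
  totals <- vapply(pop, function(nr) nr$truth$realized_total_um / 1000, 0)
  expect_true(all(totals >= 180.04 - 1 & totals <= 318.43))
  expect_gt(sum(totals), 1600)
  # every layer-5 neuron is callosal by design
  expect_true(all(vapply(pop, function(nr) nr$truth$class, "") == "CPN"))
})
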