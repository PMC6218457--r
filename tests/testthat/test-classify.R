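# classification tests run against the package's synthetic atlas
atlas_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_atlas()
    cache
  }
})

test_that("soma location resolves region and layer from the ontology", {
  atlas <- atlas_fixture()
  m <- make_path(3, step = 10)
  m$nodes$x <- m$nodes$x + 4900; m$nodes$y <- m$nodes$y + 1900
  m$nodes$z <- m$nodes$z + 400  # MOs L2/3 slab
  m <- morphology(m$nodes)
  loc <- assign_soma_location(m, atlas$volume, atlas$ontology)
  expect_equal(loc$soma_acronym, "MOs2/3_R")
  expect_equal(loc$soma_layer, "L2/3")

  # unlayered region (striatum) -> layer unknown
  m2 <- m
  m2$nodes$x <- m2$nodes$x - 4900 + 5800
  m2$nodes$z <- m2$nodes$z - 400 + 2000
  m2 <- morphology(m2$nodes)
  loc2 <- assign_soma_location(m2, atlas$volume, atlas$ontology)
  expect_equal(loc2$soma_acronym, "CP_R")
  expect_equal(loc2$soma_layer, "unknown")

  # soma in background -> classed error
  m3 <- m
  m3$nodes$x <- m3$nodes$x - 4900 + 100
  m3 <- morphology(m3$nodes)
  expect_error(assign_soma_location(m3, atlas$volume, atlas$ontology),
               class = "soma_outside_volume")
})

test_that("CPN/APN threshold semantics on constructed fixtures", {
  atlas <- atlas_fixture()
  soma <- c(4900, 1900, 400)
  # helper: soma + straight axon of given span along x at cc depth
  straight <- function(x_end, n = 300) {
    xs <- seq(soma[1], x_end, length.out = n + 1)
    morphology(data.frame(
      id = 1:(n + 1), type = c(1, rep(2, n)), x = xs,
      y = 1900, z = c(400, rep(1450, n)),
      radius = 1, parent = c(-1, 1:n)), name = "straight")
  }
  # all-ipsilateral axon -> APN with zero contra cable
  rec <- classify_it(straight(5500), atlas$volume, atlas$ontology,
                     atlas$midline, "cc")
  expect_equal(rec$it_subclass, "APN")
  expect_equal(rec$contra_axon_mm, 0, tolerance = 1e-9)

  # 5 mm of contralateral cable routed through the cc band -> CPN + crossed
  rec2 <- classify_it(straight(4000 - 5000), atlas$volume, atlas$ontology,
                      atlas$midline, "cc", step = 10)
  expect_equal(rec2$it_subclass, "CPN")
  expect_true(rec2$crossed_via_cc)
  expect_gt(rec2$contra_axon_mm, 4.9)

  # 0.5 mm contralateral at threshold 1 mm -> APN despite crossing
  rec3 <- classify_it(straight(3500), atlas$volume, atlas$ontology,
                      atlas$midline, "cc", min_contra_mm = 1, step = 10)
  expect_equal(rec3$it_subclass, "APN")
  expect_true(rec3$crossed_via_cc)
  expect_equal(rec3$contra_axon_mm, 0.5, tolerance = 0.02)
  # same cable, threshold 0.4 mm -> CPN
  rec4 <- classify_it(straight(3500), atlas$volume, atlas$ontology,
                      atlas$midline, "cc", min_contra_mm = 0.4, step = 10)
  expect_equal(rec4$it_subclass, "CPN")
})

test_that("classification is invariant to translation along the midline plane", {
  atlas <- atlas_fixture()
  pop <- simulate_population(2, "MOs_L23", seed = 3, atlas = atlas)
  for (nr in pop) {
    m <- nr$morphology
    rec <- classify_it(m, atlas$volume, atlas$ontology, atlas$midline, "cc")
    m2 <- m
    m2$nodes$y <- m2$nodes$y + 40  # shift within the plane
    m2 <- morphology(m2$nodes, name = m$name)
    rec2 <- classify_it(m2, atlas$volume, atlas$ontology, atlas$midline, "cc")
    expect_equal(rec2$it_subclass, rec$it_subclass)
    expect_equal(rec2$contra_axon_mm, rec$contra_axon_mm, tolerance = 1e-9)
  }
})

test_that("profile categorization groups by Jaccard similarity of target sets", {
  mk <- function(...) {
    rows <- list(...)
    mat <- do.call(rbind, rows)
    colnames(mat) <- c("A", "B", "C", "D", "0")
    rownames(mat) <- paste0("n", seq_len(nrow(mat)))
    mat
  }
  # identical target sets -> same category; disjoint -> different
  mat <- mk(c(.5, .4, 0, 0, .1), c(.45, .45, 0, 0, .1),
            c(0, 0, .5, .4, .1))
  cats <- categorize_profiles(mat, theta = 0.05)
  expect_equal(unname(cats), c(1, 1, 2))

  # {A,B} vs {A,B,C}: Jaccard 2/3 >= 0.5 -> same category
  mat2 <- mk(c(.5, .4, 0, 0, .1), c(.3, .3, .3, 0, .1))
  expect_equal(unname(categorize_profiles(mat2)), c(1, 1))
  # background column is never a target
  mat3 <- mk(c(.5, .4, 0, 0, .1), c(0, 0, .5, .4, .1))
  expect_equal(unname(categorize_profiles(mat3)), c(1, 2))

  # permutation equivariance
  set.seed(14)
  mat4 <- matrix(runif(8 * 5), 8)
  mat4 <- mat4 / rowSums(mat4)
  colnames(mat4) <- c("A", "B", "C", "D", "0")
  rownames(mat4) <- paste0("n", 1:8)
  cats4 <- categorize_profiles(mat4)
  perm <- sample(8)
  catsp <- categorize_profiles(mat4[perm, ])
  # same partition: co-membership must match
  same <- function(v) outer(v, v, "==")
  expect_equal(same(unname(catsp)), same(unname(cats4[perm])))

  expect_error(categorize_profiles(mat4[0, , drop = FALSE]),
               class = "empty_matrix")
})
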