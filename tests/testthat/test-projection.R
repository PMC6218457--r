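test_that("an axon confined to one region books all cable there", {
  ta <- tiny_atlas()
  m <- make_path(5, step = 10)  # x 0..50, inside region A (x < 100)
  lens <- segment_region_lengths(m, ta$volume)
  expect_equal(lens, c("1" = 50))
})

test_that("a boundary-crossing edge splits by the analytic clip within a step", {
  ta <- tiny_atlas()
  # single 40 um edge from x=80 to x=120, boundary at x=100
  m <- morphology(data.frame(id = 1:2, type = c(1, 2),
                             x = c(80, 120), y = 50, z = 50,
                             radius = 1, parent = c(-1, 1)))
  for (step in c(10, 5, 1)) {
    lens <- segment_region_lengths(m, ta$volume, step = step)
    expect_lt(abs(lens[["1"]] - 20), step)
    expect_lt(abs(lens[["2"]] - 20), step)
    expect_equal(sum(lens), 40, tolerance = 1e-9)
  }
})

test_that("cable outside the labeled volume lands in the background bucket", {
  ta <- tiny_atlas()
  m <- morphology(data.frame(id = 1:3, type = c(1, 2, 2),
                             x = c(50, 50, 50), y = c(50, 50, 50),
                             z = c(50, 250, 450), radius = 1,
                             parent = c(-1, 1, 2)))
  lens <- segment_region_lengths(m, ta$volume, step = 10)
  expect_gt(lens[["0"]], 0)
  expect_equal(sum(lens), 400, tolerance = 1e-9)
})

test_that("length is conserved exactly for arbitrary trees and volumes", {
  set.seed(55)
  for (rep in 1:10) {
    m <- random_tree(150, coord_sd = 120)
    vol <- label_volume(array(sample(0:4, 5^3, TRUE), c(5, 5, 5)),
                        c(40, 40, 40), origin = c(-100, -100, -100))
    lens <- segment_region_lengths(m, vol, step = 17)
    expect_equal(sum(lens), cable_length(m, "AXON"), tolerance = 1e-9)
  }
})

test_that("empty axon is a classed error", {
  dend <- morphology(data.frame(id = 1:2, type = c(1, 3), x = c(0, 10),
                                y = 0, z = 0, radius = 1, parent = c(-1, 1)))
  expect_error(segment_region_lengths(dend, tiny_atlas()$volume),
               class = "empty_axon")
})

test_that("strengths aggregate up the ontology and sum to one", {
  ta <- tiny_atlas()
  m <- make_path(5, step = 10)
  p <- projection_profile(m, ta$volume, ta$midline)
  s <- projection_strengths(p, ta$ontology)
  expect_equal(s, c(A = 1))
  s_root <- projection_strengths(p, ta$ontology, level = "brain")
  expect_equal(s_root, c(brain = 1))

  # constructed two-region even split: edge 60..140 centered on boundary
  m2 <- morphology(data.frame(id = 1:3, type = c(1, 2, 2),
                              x = c(60, 100, 140), y = 50, z = 50,
                              radius = 1, parent = c(-1, 1, 2)))
  p2 <- projection_profile(m2, ta$volume, ta$midline, step = 1)
  s2 <- projection_strengths(p2, ta$ontology)
  expect_equal(unname(s2[c("A", "B")]), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(s2), 1, tolerance = 1e-9)
})

test_that("hemisphere split conserves cable and swaps under mirroring", {
  ta <- tiny_atlas()
  # soma left of plane at x=100; 30 um left, 70 um right along one line
  m <- morphology(data.frame(
    id = 1:2 + c(0, 0), type = c(1, 2), x = c(70, 170), y = 50, z = 50,
    radius = 1, parent = c(-1, 1)))
  hs <- hemisphere_split(m, ta$volume, ta$midline, step = 0.5)
  expect_equal(hs$soma_side, "LEFT")
  expect_equal(hs$ipsi_length + hs$contra_length + hs$on_midline_length,
               hs$total_axon_length, tolerance = 1e-9)
  expect_equal(hs$ipsi_length, 30, tolerance = 0.5)
  expect_equal(hs$contra_length, 70, tolerance = 0.5)

  # all-ipsi case
  m_ipsi <- make_path(4, step = 10)
  hs2 <- hemisphere_split(m_ipsi, ta$volume, ta$midline, step = 1)
  expect_equal(hs2$ipsi_fraction, 1)

  # mirror symmetry: exact swap
  set.seed(66)
  mr <- random_tree(120, coord_sd = 60)
  mr$nodes$x <- mr$nodes$x + 100
  mr <- morphology(mr$nodes, name = "mr")
  hs_a <- hemisphere_split(mr, ta$volume, ta$midline, step = 3)
  hs_b <- hemisphere_split(mirror_morphology(mr, 100), ta$volume,
                           ta$midline, step = 3)
  expect_equal(hs_a$ipsi_length, hs_b$ipsi_length, tolerance = 1e-9)
  expect_equal(hs_a$contra_length, hs_b$contra_length, tolerance = 1e-9)
})

test_that("tips per region sum to the morphometric tip count", {
  set.seed(77)
  ta <- tiny_atlas()
  for (rep in 1:5) {
    m <- random_tree(80, coord_sd = 80)
    m$nodes$x <- m$nodes$x + 100
    m$nodes$y <- m$nodes$y + 50
    m$nodes$z <- m$nodes$z + 50
    m <- morphology(m$nodes)
    tpr <- tips_per_region(m, ta$volume)
    expect_equal(sum(tpr), count_tips(m, "AXON"))
  }
  y <- make_y_tree()
  y$nodes$x <- c(50, 50, 30, 150)  # tips in A (x=30) and B (x=150)
  y$nodes$y <- 50; y$nodes$z <- 50
  y <- morphology(y$nodes)
  expect_equal(tips_per_region(y, ta$volume), c("1" = 1L, "2" = 1L))
})

test_that("projection matrix rows sum to one with background included", {
  ta <- tiny_atlas()
  ms <- list(make_path(5, 10), make_path(8, 15))
  ms[[1]]$name <- "n1"; ms[[2]]$name <- "n2"
  profs <- lapply(ms, projection_profile, vol = ta$volume, mid = ta$midline)
  pm <- projection_matrix(profs, ta$ontology)
  expect_equal(rownames(pm), c("n1", "n2"))
  expect_equal(unname(rowSums(pm)), c(1, 1), tolerance = 1e-9)
  # one neuron wholly inside one region -> a 1.0 entry
  expect_equal(pm["n1", "A"], 1)
})

test_that("halving the step barely changes region lengths", {
  set.seed(88)
  ta <- tiny_atlas()
  m <- random_tree(200, coord_sd = 70)
  m$nodes$x <- m$nodes$x + 100; m$nodes$y <- m$nodes$y + 50
  m$nodes$z <- m$nodes$z + 50
  m <- morphology(m$nodes)
  a <- segment_region_lengths(m, ta$volume, step = 10)
  b <- segment_region_lengths(m, ta$volume, step = 5)
  keys <- union(names(a), names(b))
  av <- ifelse(is.na(a[keys]), 0, a[keys])
  bv <- ifelse(is.na(b[keys]), 0, b[keys])
  expect_lt(max(abs(av - bv)) / sum(a), 0.01)
})
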