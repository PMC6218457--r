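test_that("region lookup follows the half-open voxel convention", {
  ta <- tiny_atlas()
  expect_equal(region_at(ta$volume, c(50, 50, 50)), 1L)
  expect_equal(region_at(ta$volume, c(150, 50, 50)), 2L)
  # point exactly on the interior boundary x = 100 -> higher-index voxel
  expect_equal(region_at(ta$volume, c(100, 50, 50)), 2L)
  # outside the extent -> background
  expect_equal(region_at(ta$volume, c(-1, 50, 50)), 0L)
  expect_equal(region_at(ta$volume, c(50, 50, 1000)), 0L)
  # uniform volume returns its id anywhere inside
  uni <- label_volume(array(7L, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(region_at(uni, c(1.5, 0.2, 2.9)), 7L)
})

test_that("region lookup matches brute-force index arithmetic on random points", {
  set.seed(33)
  labels <- array(sample(0:9, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  vol <- label_volume(labels, c(2.5, 3, 4), origin = c(-10, 5, 0))
  p <- cbind(runif(1000, -20, 20), runif(1000, 0, 30), runif(1000, -5, 25))
  got <- region_at(vol, p)
  want <- vapply(seq_len(nrow(p)), function(r) {
    i <- floor((p[r, 1] + 10) / 2.5); j <- floor((p[r, 2] - 5) / 3)
    k <- floor(p[r, 3] / 4)
    if (i < 0 || i >= 6 || j < 0 || j >= 5 || k < 0 || k >= 4) 0L
    else labels[i + 1, j + 1, k + 1]
  }, 0L)
  expect_identical(got, want)
})

test_that("hemisphere assignment is antisymmetric about the plane", {
  mid <- midline_plane("x", 100)
  expect_equal(hemisphere_of(c(50, 0, 0), mid), "LEFT")
  expect_equal(hemisphere_of(c(150, 0, 0), mid), "RIGHT")
  expect_equal(hemisphere_of(c(100, 0, 0), mid), "ON_MIDLINE")
  set.seed(4)
  p <- cbind(runif(50, 0, 200), runif(50), runif(50))
  mirrored <- p
  mirrored[, 1] <- 200 - p[, 1]
  a <- hemisphere_of(p, mid)
  b <- hemisphere_of(mirrored, mid)
  swap <- c(LEFT = "RIGHT", RIGHT = "LEFT", ON_MIDLINE = "ON_MIDLINE")
  expect_equal(b, unname(swap[a]))
})

test_that("majority downsampling follows majority and smallest-id tie rules", {
  # constant volume stays constant at any factor
  uni <- label_volume(array(4L, c(4, 4, 2)), c(1, 1, 1))
  down <- downsample_labels(uni, c(2, 2, 2))
  expect_true(all(down$labels == 4L))
  expect_equal(down$voxel_size, c(2, 2, 2))
  expect_equal(dim(down$labels), c(2, 2, 1))

  # 2x2x1 block {1,1,2,3} -> majority 1
  lab <- array(c(1L, 1L, 2L, 3L), c(2, 2, 1))
  expect_equal(as.vector(downsample_labels(label_volume(lab, c(1, 1, 1)),
                                           c(2, 2, 1))$labels), 1L)
  # tie {1,1,2,2} -> smallest id
  lab2 <- array(c(1L, 2L, 1L, 2L), c(2, 2, 1))
  expect_equal(as.vector(downsample_labels(label_volume(lab2, c(1, 1, 1)),
                                           c(2, 2, 1))$labels), 1L)

  # no new ids; identity at factor 1; partial edge blocks allowed
  set.seed(9)
  vol <- label_volume(array(sample(0:5, 7 * 5 * 3, TRUE), c(7, 5, 3)),
                      c(1, 2, 3), origin = c(4, 5, 6))
  d2 <- downsample_labels(vol, c(2, 2, 2))
  expect_true(all(d2$labels %in% vol$labels))
  expect_equal(dim(d2$labels), c(4, 3, 2))
  expect_equal(d2$origin, vol$origin)
  expect_identical(downsample_labels(vol, c(1, 1, 1))$labels, vol$labels)
  expect_error(downsample_labels(vol, c(0, 1, 1)), class = "bad_factor")
})

test_that("ontology ancestors walk to the root and reject unknown ids", {
  ta <- tiny_atlas()
  expect_equal(region_ancestors(ta$ontology, 1L), 3L)
  expect_equal(region_ancestors(ta$ontology, 3L), integer(0))
  expect_error(region_ancestors(ta$ontology, 99L), class = "unknown_region")
})

test_that("NRRD and ontology CSV roundtrips preserve everything", {
  set.seed(12)
  vol <- label_volume(array(sample(0:30, 4 * 3 * 5, TRUE), c(4, 3, 5)),
                      c(4, 4, 40), origin = c(-8, 0, 12))
  for (enc in c("ascii", "raw")) {
    f <- withr::local_tempfile(fileext = ".nrrd")
    write_nrrd(vol, f, encoding = enc)
    back <- read_nrrd(f)
    expect_identical(back$labels, vol$labels)
    expect_equal(back$voxel_size, vol$voxel_size)
    expect_equal(back$origin, vol$origin)
  }
  ont <- make_atlas()$ontology
  f <- withr::local_tempfile(fileext = ".csv")
  write_ontology_csv(ont, f)
  back <- read_ontology_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(ont))
})
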