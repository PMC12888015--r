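test_that("shoelace area matches known polygons", {
  sq <- cbind(c(0, 4, 4, 0), c(0, 0, 3, 3))
  expect_equal(abs(poly_area(sq)), 12)
  tri <- cbind(c(0, 2, 0), c(0, 0, 2))
  expect_equal(abs(poly_area(tri)), 2)
})

test_that("point_in_polygon agrees with an independent winding-number oracle", {
  set.seed(42)
  for (k in 1:20) {
    ring <- random_convex_polygon(8, center = runif(2, 20, 80), radius = 15)
    px <- runif(50, 0, 100); py <- runif(50, 0, 100)
    got <- point_in_polygon(px, py, list(ring))
    want <- vapply(seq_along(px), function(i)
      winding_inside(px[i], py[i], ring), logical(1))
    expect_equal(got, want)
  }
})

test_that("point_in_polygon honours holes by even-odd parity", {
  outer <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  hole <- cbind(c(3, 7, 7, 3), c(3, 3, 7, 7))
  rings <- list(outer, hole)
  expect_true(point_in_polygon(1, 1, rings))
  expect_false(point_in_polygon(5, 5, rings))
  expect_false(point_in_polygon(20, 5, rings))
})

test_that("label_components distinguishes 4- and 8-connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # touch diagonally only
  expect_equal(max(label_components(m, 4)), 2)
  expect_equal(max(label_components(m, 8)), 1)
})

test_that("label_components matches EBImage bwlabel for 4-connectivity", {
  set.seed(3)
  for (k in 1:5) {
    m <- matrix(runif(900) < 0.4, 30, 30)
    ours <- label_components(m, 4)
    # EBImage images are x-major
    ref <- EBImage::imageData(EBImage::bwlabel(t(m)))
    expect_equal(max(ours), max(ref))
    # same partition: label maps are equal up to renumbering
    key <- paste(ours[m], t(ref)[m])
    expect_equal(length(unique(key)), max(ours))
  }
})

test_that("mask_to_polygons / polygons_to_mask round trip is exact", {
  set.seed(11)
  for (k in 1:10) {
    m <- matrix(runif(2500) < 0.45, 50, 50)
    m <- clean_mask(m, px_size = 1, min_object_um2 = 2, min_hole_um2 = 0)
    labs <- label_components(m, 8)
    polys <- mask_to_polygons(labs, px_size = 1)
    back <- polygons_to_mask(polys, dim(m), px_size = 1)
    expect_identical(back, m)
    # areas consistent with pixel counts per component
    for (p in polys)
      expect_equal(p$area, sum(labs == p$id))
  }
})

test_that("clean_mask removes small objects and fills small holes", {
  m <- matrix(FALSE, 20, 20)
  m[5:12, 5:12] <- TRUE   # 64 px object
  m[8, 8] <- FALSE        # 1 px hole
  m[18, 18] <- TRUE       # isolated pixel
  out <- clean_mask(m, px_size = 1, min_object_um2 = 7, min_hole_um2 = 7)
  expect_false(out[18, 18])
  expect_true(out[8, 8])
  expect_true(all(out[5:12, 5:12]))
})

test_that("dilate_disc grows a point into a disc of the requested radius", {
  m <- matrix(FALSE, 21, 21); m[11, 11] <- TRUE
  out <- dilate_disc(m, 5)
  expect_true(out[11, 16])
  expect_false(out[11, 18])
  expect_true(sum(out) > sum(m))
})
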