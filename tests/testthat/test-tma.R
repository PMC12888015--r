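test_that("roi_set enforces disjoint entries and reports sizes", {
  a <- data.frame(x = c(0, 1), y = c(0, 0))
  b <- data.frame(x = 2, y = 0)
  r <- roi_set("FC", list(PTC = a, FA = b))
  expect_equal(roi_size(r), 3)
  sp <- roi_spots(r)
  expect_setequal(names(sp), c("x", "y", "label"))
  expect_error(roi_set("FC", list(PTC = a, FA = a)), "disjoint|overlap")
})

test_that("dearray locates the 2x2 cores of the fixture in row-major order", {
  fx <- default_fixture()
  g <- dearray(fx$he$rgb, 2, 2)
  expect_equal(nrow(g), 4)
  expect_equal(g$row, c(1, 1, 2, 2))
  expect_equal(g$col, c(1, 2, 1, 2))
  ps <- fx$phantom$image_px_size
  for (k in 1:4) {
    ctr <- fx$phantom$cores[[k]]$center / ps  # um -> px
    expect_lt(sqrt((g$cx[k] - ctr[1])^2 + (g$cy[k] - ctr[2])^2), 25)
  }
})

test_that("validate_grid marks cores containing measured spots as valid", {
  fx <- default_fixture()
  g <- dearray(fx$he$rgb, 2, 2)
  v <- validate_grid(g, fx$msi, fx$phantom$transform)
  expect_true(all(v$valid))
})

test_that("tile_to_msi restricts to measured spots and resolves contested spots", {
  tr <- affine2d(diag(2), c(0, 0))
  # two overlapping squares in um units (px_size 1 here)
  polys <- list(
    list(outer = cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)), holes = list(),
         label = "b"),
    list(outer = cbind(c(50, 150, 150, 50), c(0, 0, 100, 100)), holes = list(),
         label = "a"))
  r <- tile_to_msi(polys, tr, pitch = 20, buffer_um = 0)
  sp <- roi_spots(r)
  expect_false(any(duplicated(sp[, c("x", "y")])))
  # contested spots (x in 50..100 band) go to label "a" (lexicographic)
  contested <- sp[sp$x == 3, ]
  expect_true(all(contested$label == "a"))
})

test_that("tiles_to_polygons covers exactly the spot squares", {
  spots <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1))
  polys <- tiles_to_polygons(spots, pitch = 20)
  total <- sum(vapply(polys, function(p)
    abs(poly_area(p$outer)) -
      sum(vapply(p$holes, function(h) abs(poly_area(h)), 0)), 0))
  expect_equal(total, 3 * 400)
})

test_that("transfer_labels splits detections by annotation and drops orphans", {
  labels <- matrix(0L, 40, 40)
  labels[5:15, 5:15] <- 1L    # straddles the annotation boundary
  labels[30:35, 30:35] <- 2L  # no annotation -> dropped
  det <- structure(list(labels = labels,
                        table = data.frame(id = 1:2,
                                           class = "cell_rich",
                                           area_um2 = c(121, 36)),
                        polygons = list(), px_size = 1),
                   class = "detection_set")
  ann <- annotation_set(list(
    list(outer = cbind(c(0, 10, 10, 0), c(0, 0, 40, 40)), holes = list(),
         label = "PTC"),
    list(outer = cbind(c(10, 25, 25, 10), c(0, 0, 40, 40)), holes = list(),
         label = "FA")), "pathologist")
  out <- transfer_labels(det, ann)
  expect_setequal(out$table$class, c("PTC", "FA"))
  expect_equal(sort(unique(out$table$source_detection)), 1)
  expect_true(all(out$labels[30:35, 30:35] == 0L))
})

test_that("build_roi_types yields nested spot sets on the fixture", {
  fx <- default_fixture()
  g <- dearray(fx$he$rgb, 2, 2)
  labeled <- transfer_labels(fx$detections, fx$he$pathologist)
  rois <- build_roi_types(g, fx$he$pathologist, labeled,
                          fx$phantom$transform, fx$msi)
  fc <- roi_spots(rois$FC); pc <- roi_spots(rois$PC)
  expect_true(all(paste(pc$x, pc$y) %in% paste(fc$x, fc$y)))  # PC inside FC
  expect_setequal(unique(fc$label), c("PTC", "FVPTC", "NIFTP", "FA"))
})
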