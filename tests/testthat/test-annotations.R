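test_that("GeoJSON annotations round trip including labels and holes", {
  polys <- list(
    list(outer = cbind(c(0, 50, 50, 0), c(0, 0, 40, 40)),
         holes = list(cbind(c(10, 20, 20, 10), c(10, 10, 20, 20))),
         label = "PTC"),
    list(outer = cbind(c(100, 140, 120), c(0, 0, 30)),
         holes = list(), label = "FA"))
  ann <- annotation_set(polys, "pathologist")
  path <- tempfile(fileext = ".geojson")
  write_geojson(ann, path)
  back <- read_geojson(path, "pathologist")
  expect_equal(length(back$polygons), 2)
  expect_setequal(annotation_labels(back), c("PTC", "FA"))
  # geometry preserved (rings may be closed/unclosed differently)
  r0 <- polys[[1]]$outer
  r1 <- back$polygons[[1]]$outer
  expect_equal(abs(poly_area(r1)), abs(poly_area(r0)))
  expect_equal(length(back$polygons[[1]]$holes), 1)
})

test_that("rasterization fills polygons by pixel-centre and overwrites in order", {
  polys <- list(
    list(outer = cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), holes = list(),
         label = "a"),
    list(outer = cbind(c(5, 15, 15, 5), c(5, 5, 15, 15)), holes = list(),
         label = "b"))
  ann <- annotation_set(polys, "training")
  r <- rasterize_annotations(ann, c(20, 20))
  expect_equal(r[2, 2], 1L)     # inside first only
  expect_equal(r[8, 8], 2L)     # overlap: later polygon wins
  expect_equal(r[18, 18], 0L)   # outside both
  # pixel count of a 10x10 unit square at px_size 1
  expect_equal(sum(r == 1L) + sum(r == 2L & rasterize_annotations(
    annotation_set(polys[1], "x"), c(20, 20)) == 1L), 100)
})
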