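test_that("pixel classifier trains on the fixture with high accuracy", {
  fx <- default_fixture()
  m <- fx$model
  expect_s3_class(m, "pixel_classifier")
  expect_gt(m$train_accuracy, 0.95)
  expect_equal(m$class_order, c("cell_rich", "non_cell_rich"))
  expect_equal(length(coef(m)), 32)  # 16 features x 2 classes, no bias
})

test_that("predict returns per-class probabilities that sum to one", {
  fx <- default_fixture()
  p <- fx$prob
  expect_equal(dim(p)[3], 2)
  expect_equal(dim(p)[1:2], dim(fx$he$rgb)[1:2])
  s <- p[, , 1] + p[, , 2]
  expect_equal(range(s), c(1, 1), tolerance = 1e-9)
})

test_that("predict refuses a mismatched feature configuration", {
  fx <- default_fixture()
  set.seed(4)
  rgb <- array(runif(30 * 30 * 3, 0, 255), c(30, 30, 3))
  other <- compute_features(rgb, feature_config(sigmas = c(1, 3)),
                            px_size = 0.44)
  expect_error(predict(fx$model, other), "mismatch")
})

test_that("classifier JSON serialisation round-trips and predicts identically", {
  fx <- default_fixture()
  path <- tempfile(fileext = ".json")
  write_pixel_classifier(fx$model, path)
  back <- read_pixel_classifier(path)
  expect_equal(back$weights, fx$model$weights, tolerance = 1e-12)
  expect_equal(back$class_order, fx$model$class_order)
  expect_equal(back$feature_names, fx$model$feature_names)
})

test_that("print and summary describe the model", {
  fx <- default_fixture()
  expect_output(print(fx$model), "[Pp]ixel classifier")
  expect_output(print(summary(fx$model)), "")
})

test_that("postprocessing removes objects and holes under the area floor", {
  px <- 1
  p <- matrix(0, 40, 40)
  p[10:25, 10:25] <- 1   # big object
  p[15, 15] <- 0         # 1 um^2 hole -> filled
  p[35, 35] <- 1         # 1 um^2 object -> removed
  det <- postprocess_detections(p, px, min_object_um2 = 7, min_hole_um2 = 7)
  expect_equal(nrow(det$table), 1)
  expect_true(det$labels[15, 15] > 0)
  expect_equal(det$labels[35, 35], 0L)
})
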