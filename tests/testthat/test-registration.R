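test_that("fit_affine recovers a planted transform exactly from landmarks", {
  A <- 0.44 * matrix(c(cos(0.1), sin(0.1), -sin(0.1), cos(0.1)), 2, 2)
  b <- c(24, 12)
  tr <- affine2d(A, b)
  set.seed(8)
  pts <- cbind(runif(6, 0, 1000), runif(6, 0, 1000))
  fit <- fit_affine(pts, affine_apply(tr, pts))
  expect_equal(fit$A, A, tolerance = 1e-10)
  expect_equal(fit$b, b, tolerance = 1e-8)
  expect_lt(attr(fit, "rms_residual_um"), 1e-8)
})

test_that("fit_affine rejects degenerate landmark sets", {
  pts <- cbind(c(0, 1), c(0, 1))
  expect_error(fit_affine(pts, pts), "3 control-point")
  col <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_error(fit_affine(col, col + 1), "collinear")
})

test_that("affine invert and compose satisfy the group identities", {
  t1 <- affine2d(matrix(c(0.4, 0.1, -0.1, 0.4), 2, 2), c(5, -3))
  t2 <- affine2d(matrix(c(1, 0.2, 0, 1), 2, 2), c(-2, 7))
  set.seed(6)
  p <- cbind(runif(10, -50, 50), runif(10, -50, 50))
  expect_equal(affine_apply(affine_invert(t1), affine_apply(t1, p)), p,
               tolerance = 1e-10)
  expect_equal(affine_apply(affine_compose(t2, t1), p),
               affine_apply(t2, affine_apply(t1, p)), tolerance = 1e-10)
})

test_that("control points read back from CSV reproduce the fit", {
  tr <- affine2d(matrix(c(0.44, 0, 0, 0.44), 2, 2), c(10, 20))
  pts <- cbind(c(0, 1000, 0, 1000), c(0, 0, 1000, 1000))
  um <- affine_apply(tr, pts)
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(img_x = pts[, 1], img_y = pts[, 2],
                       msi_x_um = um[, 1], msi_y_um = um[, 2]),
            path, row.names = FALSE)
  cp <- read_control_points(path)
  fit <- fit_affine(cp$img_px, cp$msi_um)
  expect_equal(fit$A, tr$A, tolerance = 1e-10)
  expect_equal(fit$b, tr$b, tolerance = 1e-8)
})

test_that("ion image extracts the reference ion and errors out of range", {
  fx <- default_fixture()
  ion <- ion_image(fx$msi, 1459.688, 20)
  expect_equal(length(ion), nrow(fx$msi$spots))
  expect_gt(sd(ion), 0)
  expect_error(ion_image(fx$msi, 5000), "range")
})
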