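test_that("phantom layout matches its stated geometry", {
  ph <- fixture_phantom(seed = 1)
  expect_equal(length(ph$cores), 4)
  expect_setequal(vapply(ph$cores, `[[`, "", "diagnosis"),
                  c("PTC", "FVPTC", "NIFTP", "FA"))
  for (core in ph$cores) {
    expect_equal(core$radius, 100)
    # all follicle centres fall inside the core
    d <- sqrt(rowSums(sweep(core$follicles, 2, core$center)^2))
    expect_true(all(d <= core$radius))
  }
})

test_that("phantom masks are consistent strata", {
  ph <- fixture_phantom(seed = 1)
  he <- default_fixture()$he
  m <- he$masks
  expect_false(any(m$cell_rich & m$colloid))
  expect_true(all(m$cell_rich | !m$cell_rich))  # logical masks
  expect_true(all((m$cell_rich | m$colloid) <= m$tissue))
  frac_cell <- sum(m$cell_rich) / sum(m$tissue)
  expect_gt(frac_cell, 0.15); expect_lt(frac_cell, 0.6)
})

test_that("spectrum model plants the documented peak families", {
  sm <- spectrum_model()
  expect_equal(sm$structural_peaks$mz, 1459.688)
  expect_equal(length(sm$interferent_peaks$mz), 10)
  expect_equal(sm$trypsin_peaks$mz, c(842.51, 1045.56, 1220.64))
  pd <- planted_discriminative_mz(sm)
  expect_equal(nrow(pd), 8)              # 2 unique non-trace per diagnosis
  expect_true(all(pd$amplitude >= 1))
  # shared peptides are excluded from the discriminative set
  expect_false(any(pd$mz %in% c(944.53, 1325.75)))
})

test_that("fixture generation is deterministic for a fixed seed", {
  ph1 <- fixture_phantom(seed = 5)
  ph2 <- fixture_phantom(seed = 5)
  expect_equal(ph1$cores, ph2$cores)
  ph3 <- fixture_phantom(seed = 6)
  expect_false(identical(ph1$cores, ph3$cores))
})

test_that("simulate_fixture writes a complete, readable file set", {
  dir <- file.path(tempdir(), "fixsim")
  ph <- fixture_phantom(n_rows = 1, n_cols = 1, seed = 2)
  fx <- simulate_fixture(ph, spectrum_model(), dir)
  expect_true(all(file.exists(unlist(fx$paths))))
  img <- png::readPNG(fx$paths$image)
  expect_equal(dim(img)[1:2], ph$dim_px)
  msi <- read_imzml(fx$paths$imzml, pitch = ph$msi_pitch)
  expect_identical(msi$intensities, fx$msi$intensities)
  tr <- read_geojson(fx$paths$training, "training")
  expect_setequal(unique(annotation_labels(tr)),
                  c("cell_rich", "non_cell_rich"))
  man <- jsonlite::fromJSON(fx$paths$manifest)
  expect_equal(man$seed, 2)
  expect_equal(unlist(man$transform$b), ph$transform$b, ignore_attr = TRUE)
})

test_that("spot fractions carry tissue composition per spot", {
  fx <- default_fixture()
  fr <- attr(fx$msi, "spot_fractions")
  expect_equal(nrow(fr), nrow(fx$msi$spots))
  expect_true(all(fr$cell + fr$colloid <= fr$tissue + 1e-9))
  expect_true(all(fr$tissue > 0))
})
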