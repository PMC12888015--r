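test_that("continuous imzML round trip is bit-exact", {
  msi <- small_msi()
  path <- file.path(tempdir(), "rt.imzML")
  write_imzml(msi, path, mode = "continuous", uuid_seed = 1)
  back <- read_imzml(path, pitch = msi$pitch)
  expect_identical(back$intensities, msi$intensities)
  expect_identical(back$mz, msi$mz)
  expect_true(all(back$spots$x == msi$spots$x))
  expect_true(all(back$spots$y == msi$spots$y))
})

test_that("processed imzML reads back onto a union axis", {
  msi <- small_msi()
  path <- file.path(tempdir(), "proc.imzML")
  write_imzml(msi, path, mode = "processed", uuid_seed = 1)
  back <- read_imzml(path, pitch = msi$pitch)
  # all spots share one axis here, so no interpolation error
  expect_equal(back$intensities, msi$intensities, ignore_attr = TRUE)
  expect_equal(back$mz, msi$mz)
})

test_that("a corrupted ibd is rejected by the checksum", {
  msi <- small_msi()
  path <- file.path(tempdir(), "bad.imzML")
  write_imzml(msi, path, mode = "continuous", uuid_seed = 1)
  ibd <- sub("\\.imzML$", ".ibd", path)
  raw <- readBin(ibd, "raw", file.info(ibd)$size)
  raw[length(raw)] <- as.raw(bitwXor(as.integer(raw[length(raw)]), 255L))
  writeBin(raw, ibd)
  expect_error(read_imzml(path, pitch = 20), "checksum|MD5|md5")
})

test_that("imzML written here parses with pyimzml (independent reader)", {
  msi <- small_msi()
  path <- file.path(tempdir(), "pyoracle.imzML")
  write_imzml(msi, path, mode = "continuous", uuid_seed = 1)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "mz, ints = p.getspectrum(0)",
    "print(json.dumps({'n': len(p.coordinates),",
    "                  'coord0': list(p.coordinates[0]),",
    "                  'mz0': mz[0], 'int0': float(ints[0])}))"
  ), script)
  out <- suppressWarnings(
    system2("python3", c(script, path), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  res <- jsonlite::fromJSON(out[length(out)])
  expect_equal(res$n, nrow(msi$spots))
  # imzML coordinates are 1-based
  expect_equal(res$coord0[1:2], c(msi$spots$x[1] + 1, msi$spots$y[1] + 1))
  expect_equal(res$mz0, msi$mz[1])
  expect_equal(res$int0, unname(msi$intensities[1, 1]))
})

test_that("msi_dataset validates its inputs", {
  expect_error(msi_dataset(data.frame(x = c(0, 0), y = c(0, 0)),
                           c(1, 2), matrix(0, 2, 2)), "duplicate")
  expect_error(msi_dataset(data.frame(x = 0, y = 0),
                           c(2, 1), matrix(0, 1, 2)), "increasing")
})
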