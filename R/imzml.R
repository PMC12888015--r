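#' MSI dataset container
#'
#' Spot-indexed mass spectra on a shared m/z axis with grid coordinates.
#' Spot indices are 0-based integers on the 20 x 20 um acquisition raster;
#' the spot centre in stage micrometres is `(i + 0.5) * pitch`.
#'
#' @param spots data.frame with integer columns `x`, `y` (0-based indices).
#' @param mz numeric m/z axis (Da), strictly increasing.
#' @param intensities numeric matrix, `nrow(spots)` x `length(mz)`, >= 0.
#' @param pitch spot pitch in micrometres (default 20).
#' @param normalization `"none"` or `"rms"`.
#' @return an object of class `msi_dataset`.
#' @export
msi_dataset <- function(spots, mz, intensities, pitch = 20,
                        normalization = "none") {
  spots <- as.data.frame(spots)
  stopifnot(all(c("x", "y") %in% names(spots)))
  if (anyDuplicated(spots[, c("x", "y")]))
    stop("duplicate spot indices")
  if (is.unsorted(mz, strictly = TRUE))
    stop("mz axis must be strictly increasing")
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == nrow(spots),
            ncol(intensities) == length(mz))
  structure(list(spots = spots, mz = as.numeric(mz),
                 intensities = intensities, pitch = pitch,
                 normalization = normalization),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("MSI dataset: %d spots, m/z %.2f-%.2f (%d bins), pitch %g um, normalization: %s\n",
              nrow(x$spots), min(x$mz), max(x$mz), length(x$mz),
              x$pitch, x$normalization))
  invisible(x)
}

# deterministic RFC4122-shaped UUID from an RNG-independent integer seed
.make_uuid_bytes <- function(seed) {
  set.seed(seed %% .Machine$integer.max)
  b <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  b[7] <- as.raw(bitwOr(bitwAnd(as.integer(b[7]), 0x0F), 0x40))
  b[9] <- as.raw(bitwOr(bitwAnd(as.integer(b[9]), 0x3F), 0x80))
  b
}

.uuid_string <- function(b) {
  h <- format(b)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

.cv <- function(cvref, acc, name, value = NULL, extra = "") {
  v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s%s/>', cvref, acc, name, v, extra)
}

#' Write an MSI dataset to imzML 1.1
#'
#' Continuous mode (default) stores the shared m/z axis once in the `.ibd`
#' binary and one intensity array per spot; processed mode stores both
#' arrays per spot. Arrays are 64-bit floats, uncompressed, so the
#' continuous-mode round trip through [read_imzml()] is bit-exact. The ibd
#' MD5 checksum and UUID are recorded in the XML.
#'
#' @param msi an [msi_dataset()].
#' @param path output path ending in `.imzML` (the `.ibd` is written next
#'   to it).
#' @param mode `"continuous"` or `"processed"`.
#' @param uuid_seed integer used to derive the dataset UUID.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(msi, path, mode = c("continuous", "processed"),
                        uuid_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(msi, "msi_dataset"))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  uuid <- .make_uuid_bytes(uuid_seed)
  n <- nrow(msi$spots); L <- length(msi$mz)

  con <- file(ibd_path, "wb")
  writeBin(uuid, con)
  offset <- 16
  mz_off <- int_off <- numeric(n)
  mz_len <- int_len <- integer(n)
  if (mode == "continuous") {
    writeBin(as.numeric(msi$mz), con, size = 8, endian = "little")
    mz_off[] <- offset; mz_len[] <- L
    offset <- offset + 8 * L
    for (k in seq_len(n)) {
      writeBin(as.numeric(msi$intensities[k, ]), con, size = 8, endian = "little")
      int_off[k] <- offset; int_len[k] <- L
      offset <- offset + 8 * L
    }
  } else {
    for (k in seq_len(n)) {
      writeBin(as.numeric(msi$mz), con, size = 8, endian = "little")
      mz_off[k] <- offset; mz_len[k] <- L
      offset <- offset + 8 * L
      writeBin(as.numeric(msi$intensities[k, ]), con, size = 8, endian = "little")
      int_off[k] <- offset; int_len[k] <- L
      offset <- offset + 8 * L
    }
  }
  close(con)
  md5 <- toupper(unname(tools::md5sum(ibd_path)))

  mode_cv <- if (mode == "continuous")
    .cv("IMS", "IMS:1000030", "continuous") else .cv("IMS", "IMS:1000031", "processed")
  max_x <- max(msi$spots$x) + 1L; max_y <- max(msi$spots$y) + 1L

  spec_xml <- character(n)
  for (k in seq_len(n)) {
    spec_xml[k] <- paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">', k - 1L, k, L),
      '<scanList count="1">', .cv("MS", "MS:1000795", "no combination"),
      '<scan>',
      .cv("IMS", "IMS:1000050", "position x", msi$spots$x[k] + 1L),
      .cv("IMS", "IMS:1000051", "position y", msi$spots$y[k] + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      .cv("IMS", "IMS:1000103", "external array length", mz_len[k]),
      .cv("IMS", "IMS:1000104", "external encoded length", 8 * mz_len[k]),
      .cv("IMS", "IMS:1000102", "external offset", format(mz_off[k], scientific = FALSE)),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      .cv("IMS", "IMS:1000103", "external array length", int_len[k]),
      .cv("IMS", "IMS:1000104", "external encoded length", 8 * int_len[k]),
      .cv("IMS", "IMS:1000102", "external offset", format(int_off[k], scientific = FALSE)),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }

  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    .cv("MS", "MS:1000579", "MS1 spectrum"),
    mode_cv,
    .cv("IMS", "IMS:1000080", "universally unique identifier",
        paste0("{", .uuid_string(uuid), "}")),
    .cv("IMS", "IMS:1000090", "ibd MD5", md5),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    .cv("MS", "MS:1000514", "m/z array", "", ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"'),
    .cv("MS", "MS:1000523", "64-bit float"),
    .cv("MS", "MS:1000576", "no compression"),
    .cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    .cv("MS", "MS:1000515", "intensity array", "", ' unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"'),
    .cv("MS", "MS:1000523", "64-bit float"),
    .cv("MS", "MS:1000576", "no compression"),
    .cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1"><software id="morphomsi" version="0.1.0">',
    .cv("MS", "MS:1000799", "custom unreleased software tool", "morphomsi"),
    '</software></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    .cv("IMS", "IMS:1000042", "max count of pixels x", max_x),
    .cv("IMS", "IMS:1000043", "max count of pixels y", max_y),
    .cv("IMS", "IMS:1000046", "pixel size (x)", msi$pitch,
        ' unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"'),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="morphomsi">',
    .cv("MS", "MS:1000544", "Conversion to mzML"),
    '</processingMethod></dataProcessing></dataProcessingList>',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1"><spectrumList count="%d" defaultDataProcessingRef="export">', n),
    paste(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Read an imzML 1.1 dataset
#'
#' Supports continuous and processed binary modes, 32/64-bit float arrays,
#' uncompressed only. The ibd UUID and (when present) MD5 checksum are
#' verified. Processed-mode spectra are resampled onto the union m/z grid
#' by linear interpolation and the result is flagged with
#' `attr(, "resampled")`.
#'
#' @param path path to the `.imzML` file; the `.ibd` must sit next to it.
#' @param pitch spot pitch in micrometres; when `NULL`, taken from the
#'   `pixel size` scan setting if present, else 20.
#' @return an [msi_dataset()].
#' @export
read_imzml <- function(path, pitch = NULL) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path))
    stop("missing ibd file: ", ibd_path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  cv_of <- function(node, acc)
    xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", acc))
  has_cv <- function(node, acc) !inherits(cv_of(node, acc), "xml_missing")

  fc <- xml2::xml_find_first(doc, ".//fileContent")
  mode <- if (has_cv(fc, "IMS:1000030")) "continuous"
          else if (has_cv(fc, "IMS:1000031")) "processed"
          else stop("imzML binary mode (continuous/processed) not declared")

  # UUID check
  uuid_xml <- xml2::xml_attr(cv_of(fc, "IMS:1000080"), "value")
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  uuid_ibd <- readBin(con, "raw", 16)
  if (!is.na(uuid_xml)) {
    canon <- tolower(gsub("[{}-]", "", uuid_xml))
    if (nchar(canon) == 32 && canon != paste(format(uuid_ibd), collapse = ""))
      stop("ibd UUID does not match the imzML header")
  }
  md5_node <- cv_of(fc, "IMS:1000090")
  if (!inherits(md5_node, "xml_missing")) {
    want <- toupper(xml2::xml_attr(md5_node, "value"))
    got <- toupper(unname(tools::md5sum(ibd_path)))
    if (nzchar(want) && want != got)
      stop("ibd MD5 checksum mismatch: expected ", want, ", got ", got)
  }

  group_dtype <- function(gid) {
    g <- xml2::xml_find_first(doc, sprintf(".//referenceableParamGroup[@id='%s']", gid))
    if (has_cv(g, "MS:1000574") || has_cv(g, "MS:1002746"))
      stop("compressed binary arrays are not supported")
    if (has_cv(g, "MS:1000523")) list(size = 8)
    else if (has_cv(g, "MS:1000521")) list(size = 4)
    else stop("unsupported binary data type in group ", gid)
  }

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  n <- length(spectra)
  if (n == 0) stop("imzML contains no spectra")
  pos <- matrix(NA_integer_, n, 2)
  arr <- vector("list", n)
  dtypes <- list()
  for (k in seq_len(n)) {
    sp <- spectra[[k]]
    pos[k, 1] <- as.integer(xml2::xml_attr(cv_of(sp, "IMS:1000050"), "value"))
    pos[k, 2] <- as.integer(xml2::xml_attr(cv_of(sp, "IMS:1000051"), "value"))
    bdas <- xml2::xml_find_all(sp, ".//binaryDataArray")
    info <- list()
    for (b in bdas) {
      ref <- xml2::xml_attr(xml2::xml_find_first(b, ".//referenceableParamGroupRef"), "ref")
      if (is.null(dtypes[[ref]])) dtypes[[ref]] <- group_dtype(ref)
      info[[ref]] <- list(
        len = as.numeric(xml2::xml_attr(cv_of(b, "IMS:1000103"), "value")),
        off = as.numeric(xml2::xml_attr(cv_of(b, "IMS:1000102"), "value")))
    }
    arr[[k]] <- info
  }
  read_arr <- function(off, len, size) {
    seek(con, where = off, origin = "start")
    readBin(con, "numeric", n = len, size = size, endian = "little")
  }
  if (mode == "continuous") {
    a1 <- arr[[1]]
    mz <- read_arr(a1$mzArray$off, a1$mzArray$len, dtypes$mzArray$size)
    ints <- matrix(0, n, length(mz))
    for (k in seq_len(n))
      ints[k, ] <- read_arr(arr[[k]]$intensityArray$off, arr[[k]]$intensityArray$len,
                            dtypes$intensityArray$size)
    resampled <- FALSE
  } else {
    mzl <- vector("list", n); il <- vector("list", n)
    for (k in seq_len(n)) {
      mzl[[k]] <- read_arr(arr[[k]]$mzArray$off, arr[[k]]$mzArray$len, dtypes$mzArray$size)
      il[[k]] <- read_arr(arr[[k]]$intensityArray$off, arr[[k]]$intensityArray$len,
                          dtypes$intensityArray$size)
    }
    mz <- sort(unique(unlist(mzl)))
    ints <- matrix(0, n, length(mz))
    for (k in seq_len(n)) {
      if (length(mzl[[k]]) == length(mz) && all(mzl[[k]] == mz)) {
        ints[k, ] <- il[[k]]
      } else {
        ints[k, ] <- stats::approx(mzl[[k]], il[[k]], xout = mz,
                                   yleft = 0, yright = 0, ties = "ordered")$y
      }
    }
    resampled <- TRUE
  }
  if (is.null(pitch)) {
    ps <- xml2::xml_find_first(doc, ".//cvParam[@accession='IMS:1000046']")
    pitch <- if (!inherits(ps, "xml_missing")) as.numeric(xml2::xml_attr(ps, "value")) else 20
  }
  out <- msi_dataset(data.frame(x = pos[, 1] - 1L, y = pos[, 2] - 1L),
                     mz, ints, pitch = pitch, normalization = "none")
  attr(out, "resampled") <- resampled
  attr(out, "mode") <- mode
  out
}
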