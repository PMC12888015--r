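#' TMA dearraying, label transfer and tiling to the MSI grid
#'
#' @name tma_roi
#' @keywords internal
NULL

#' ROI set: diagnosis labels mapped to MSI spot sets
#'
#' @param roi_type one of `"FC"` (full core), `"PAT"` (pathologist
#'   annotation), `"PC"` (pixel classifier).
#' @param entries named list, label -> data.frame with spot indices `x`,
#'   `y` (0-based); spot sets must be disjoint across labels.
#' @param provenance optional data.frame (`x`, `y`, `label`, `core`).
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(roi_type = c("FC", "PAT", "PC"), entries = list(),
                    provenance = NULL) {
  roi_type <- match.arg(roi_type)
  entries <- entries[order(names(entries))]
  keys <- unlist(lapply(entries, function(d) paste(d$x, d$y)), use.names = FALSE)
  if (anyDuplicated(keys))
    stop("spot sets must be disjoint across labels within one ROI set")
  structure(list(roi_type = roi_type, entries = entries,
                 provenance = provenance),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  n <- vapply(x$entries, nrow, 0L)
  cat(sprintf("ROI set [%s]: %d spots in %d labels\n", x$roi_type, sum(n),
              length(n)))
  if (length(n)) print(n)
  invisible(x)
}

#' Total number of spots in an ROI set
#' @param x an `roi_set`.
#' @return integer.
#' @export
roi_size <- function(x) sum(vapply(x$entries, nrow, 0L))

#' All spots of an ROI set as one data.frame
#' @param x an `roi_set`.
#' @return data.frame with columns `x`, `y`, `label`.
#' @export
roi_spots <- function(x) {
  if (!length(x$entries))
    return(data.frame(x = integer(0), y = integer(0), label = character(0)))
  do.call(rbind, lapply(names(x$entries), function(l)
    cbind(x$entries[[l]][, c("x", "y")], label = l)))
}

#' Write ROI spot membership to CSV
#' @param rois list of `roi_set`s.
#' @param path output CSV.
#' @return `path` invisibly.
#' @export
write_roi_csv <- function(rois, path) {
  rows <- do.call(rbind, lapply(rois, function(r) {
    s <- roi_spots(r)
    if (!nrow(s)) return(NULL)
    core <- if (!is.null(r$provenance)) {
      m <- match(paste(s$x, s$y), paste(r$provenance$x, r$provenance$y))
      r$provenance$core[m]
    } else NA
    data.frame(spot_x = s$x, spot_y = s$y, roi_type = r$roi_type,
               label = s$label, core = core)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Locate TMA cores on an H&E image
#'
#' Tissue is segmented by thresholding the mean optical density; large
#' connected components are candidate cores; the grid is fitted by 1-D
#' clustering of component centres in x and y (largest gaps split the
#' sorted centres into the expected number of rows/columns); labels are
#' assigned row-major. Manual overrides replace fitted entries verbatim.
#'
#' @param rgb H&E image array `H x W x 3` in `[0, 255]`.
#' @param expected_rows,expected_cols expected grid shape.
#' @param od_threshold tissue threshold on mean optical density.
#' @param min_core_frac components smaller than this fraction of the
#'   largest candidate are discarded.
#' @param overrides optional data.frame (`row`, `col`, `cx`, `cy`,
#'   optionally `radius`) applied after fitting (pixel units).
#' @return a `tma_grid`: data.frame with `row`, `col`, `cx`, `cy`,
#'   `radius` (pixels) and `valid` (set by [validate_grid()]).
#' @export
dearray <- function(rgb, expected_rows, expected_cols,
                    od_threshold = 0.06, min_core_frac = 0.2,
                    overrides = NULL) {
  od <- -log10(pmax((rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3, 1) / 255)
  mask <- od > od_threshold
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) == 0) stop("no tissue found above the optical-density threshold")
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_core_frac * max(sizes))
  cx <- cy <- radius <- numeric(length(keep))
  for (k in seq_along(keep)) {
    idx <- which(lab == keep[k])
    j <- (idx - 1L) %% nrow(lab); i <- (idx - 1L) %/% nrow(lab)
    cx[k] <- mean(i) + 0.5; cy[k] <- mean(j) + 0.5
    radius[k] <- sqrt(length(idx) / pi)
  }
  if (length(keep) != expected_rows * expected_cols)
    warning(sprintf("detected %d cores but expected %d; best-effort grid assignment",
                    length(keep), expected_rows * expected_cols))
  cluster_1d <- function(v, k) {
    if (k <= 1 || length(v) <= k) {
      if (k <= 1) return(rep(1L, length(v)))
    }
    o <- order(v)
    gaps <- diff(v[o])
    cuts <- sort(order(gaps, decreasing = TRUE)[seq_len(min(k - 1, length(gaps)))])
    grp <- integer(length(v))
    grp[o] <- findInterval(seq_along(o), cuts + 1) + 1L
    grp
  }
  colg <- cluster_1d(cx, expected_cols)
  rowg <- cluster_1d(cy, expected_rows)
  col_rank <- rank(tapply(cx, colg, mean))
  row_rank <- rank(tapply(cy, rowg, mean))
  grid <- data.frame(row = as.integer(row_rank[as.character(rowg)]),
                     col = as.integer(col_rank[as.character(colg)]),
                     cx = cx, cy = cy, radius = radius, valid = NA)
  grid <- grid[order(grid$row, grid$col), ]
  rownames(grid) <- NULL
  if (!is.null(overrides)) {
    for (k in seq_len(nrow(overrides))) {
      i <- which(grid$row == overrides$row[k] & grid$col == overrides$col[k])
      if (!length(i)) {
        grid <- rbind(grid, data.frame(row = overrides$row[k], col = overrides$col[k],
                                       cx = overrides$cx[k], cy = overrides$cy[k],
                                       radius = overrides$radius[k] %||% mean(grid$radius),
                                       valid = NA))
      } else {
        grid$cx[i] <- overrides$cx[k]; grid$cy[i] <- overrides$cy[k]
        if (!is.null(overrides$radius)) grid$radius[i] <- overrides$radius[k]
      }
    }
  }
  class(grid) <- c("tma_grid", "data.frame")
  grid
}

#' Mark cores that contain measured MSI spots
#'
#' A core is valid iff at least one measured spot centre maps inside its
#' circle under the given transform.
#'
#' @param grid a [dearray()] grid.
#' @param msi an [msi_dataset()].
#' @param transform `affine2d`, image px -> MSI um.
#' @return the grid with the `valid` column filled.
#' @export
validate_grid <- function(grid, msi, transform) {
  spot_px <- affine_apply(affine_invert(transform),
                          cbind((msi$spots$x + 0.5) * msi$pitch,
                                (msi$spots$y + 0.5) * msi$pitch))
  for (k in seq_len(nrow(grid))) {
    d2 <- (spot_px[, 1] - grid$cx[k])^2 + (spot_px[, 2] - grid$cy[k])^2
    grid$valid[k] <- any(d2 <= grid$radius[k]^2)
  }
  grid
}

#' Transfer pathologist labels onto detections
#'
#' Each detection is split along pathologist-annotation boundaries and every
#' part takes the label of the annotation containing it; parts outside all
#' annotations (and whole detections with zero overlap) are dropped. On an
#' exact area tie between annotations sharing a boundary pixel, the
#' annotation rasterised last wins, which with label-sorted input makes the
#' lexicographically smallest label deterministic.
#'
#' @param detections a `detection_set`.
#' @param pat an [annotation_set()] with diagnosis labels.
#' @return a relabelled `detection_set` (components renumbered; `table$class`
#'   carries the transferred labels).
#' @export
transfer_labels <- function(detections, pat) {
  d <- dim(detections$labels)
  if (!length(pat$polygons)) {
    warning("empty pathologist annotation set: all detections dropped")
    return(postprocess_empty(detections))
  }
  ord <- order(annotation_labels(pat), decreasing = TRUE)
  pat_sorted <- annotation_set(pat$polygons[ord], pat$provenance)
  ann <- rasterize_annotations(pat_sorted, d)
  ann_labels <- annotation_labels(pat_sorted)

  det <- detections$labels
  both <- det > 0L & ann > 0L
  if (!any(both)) {
    warning("no detection overlaps any pathologist annotation")
    return(postprocess_empty(detections))
  }
  pair <- (det * (max(ann) + 1L) + ann) * both
  ids <- sort(unique(pair[pair > 0L]))
  newlab <- matrix(match(pair, ids, nomatch = 0L), d[1], d[2])
  polys <- mask_to_polygons(newlab, px_size = 1)
  px2 <- detections$px_size^2
  tab <- data.frame(id = seq_along(ids),
                    class = ann_labels[ids %% (max(ann) + 1L)],
                    area_um2 = vapply(polys, `[[`, 0, "area") * px2,
                    source_detection = ids %/% (max(ann) + 1L))
  structure(list(labels = newlab, table = tab, polygons = polys,
                 px_size = detections$px_size),
            class = "detection_set")
}

postprocess_empty <- function(detections) {
  structure(list(labels = matrix(0L, nrow(detections$labels), ncol(detections$labels)),
                 table = data.frame(id = integer(0), class = character(0),
                                    area_um2 = numeric(0)),
                 polygons = list(), px_size = detections$px_size),
            class = "detection_set")
}

# grid spot indices whose centres fall inside a set of rings (um frame)
.spots_in_rings <- function(rings, pitch) {
  allv <- do.call(rbind, rings)
  ix <- seq(floor(min(allv[, 1]) / pitch) - 1L, ceiling(max(allv[, 1]) / pitch) + 1L)
  iy <- seq(floor(min(allv[, 2]) / pitch) - 1L, ceiling(max(allv[, 2]) / pitch) + 1L)
  g <- expand.grid(x = ix, y = iy)
  ctr <- cbind((g$x + 0.5) * pitch, (g$y + 0.5) * pitch)
  g[point_in_polygon(ctr[, 1], ctr[, 2], rings), , drop = FALSE]
}

#' Tile labelled detections onto the MSI spot grid
#'
#' Buffers each labelled detection slightly outward, maps it to the MSI
#' micrometre frame, and includes every spot whose centre lies inside the
#' buffered geometry -- the polygon-simplification step that bridges the
#' resolution gap between the H&E (sub-micrometre) and the 20 um MSI
#' raster.
#'
#' @param x a labelled `detection_set` (buffering applied as a raster
#'   dilation before vectorisation), or a list of polygons
#'   `list(outer, holes, label)` in image-pixel units (buffer must then be
#'   0).
#' @param transform `affine2d` mapping image px -> MSI um.
#' @param pitch MSI spot pitch in micrometres (default 20).
#' @param buffer_um outward buffer (default 4).
#' @param msi optional [msi_dataset()]; when given, spots are restricted to
#'   measured spots.
#' @return an `roi_set` of type `"PC"`.
#' @export
tile_to_msi <- function(x, transform, pitch = 20, buffer_um = 4, msi = NULL) {
  if (inherits(x, "detection_set")) {
    labs <- unique(x$table$class)
    polys <- list()
    for (l in labs) {
      ids <- x$table$id[x$table$class == l]
      m <- matrix(x$labels %in% ids, nrow(x$labels), ncol(x$labels))
      if (buffer_um > 0) m <- dilate_disc(m, buffer_um / x$px_size)
      for (p in mask_to_polygons(m, px_size = 1))
        polys[[length(polys) + 1L]] <- list(outer = p$outer, holes = p$holes,
                                            label = l)
    }
  } else {
    if (buffer_um > 0)
      stop("buffering is only supported for detection sets; pass buffer_um = 0")
    polys <- x
  }
  entries <- list()
  for (p in polys) {
    rings <- lapply(c(list(p$outer), p$holes %||% list()),
                    function(r) affine_apply(transform, as.matrix(r)))
    s <- .spots_in_rings(rings, pitch)
    if (!nrow(s)) next
    l <- as.character(p$label %||% "PC")
    entries[[l]] <- unique(rbind(entries[[l]], s))
  }
  if (!is.null(msi) && length(entries)) {
    key <- paste(msi$spots$x, msi$spots$y)
    entries <- lapply(entries, function(d) d[paste(d$x, d$y) %in% key, , drop = FALSE])
    entries <- entries[vapply(entries, nrow, 0L) > 0]
  }
  # a spot claimed by several labels goes to the lexicographically smallest
  if (length(entries) > 1) {
    seen <- character(0)
    for (l in sort(names(entries))) {
      d <- entries[[l]]
      k <- paste(d$x, d$y)
      entries[[l]] <- d[!(k %in% seen), , drop = FALSE]
      seen <- c(seen, k[!(k %in% seen)])
    }
    entries <- entries[vapply(entries, nrow, 0L) > 0]
  }
  roi_set("PC", entries)
}

#' Merge tiled spots into simplified tile polygons
#'
#' Renders the spot set of an ROI as merged axis-aligned `pitch`-sized
#' squares -- the reduced-vertex export geometry.
#'
#' @param spots data.frame with `x`, `y` spot indices.
#' @param pitch spot pitch in micrometres.
#' @return list of polygons (`outer`, `holes`) in micrometre units.
#' @export
tiles_to_polygons <- function(spots, pitch = 20) {
  if (!nrow(spots)) return(list())
  x0 <- min(spots$x); y0 <- min(spots$y)
  m <- matrix(FALSE, max(spots$y) - y0 + 1L, max(spots$x) - x0 + 1L)
  m[cbind(spots$y - y0 + 1L, spots$x - x0 + 1L)] <- TRUE
  polys <- mask_to_polygons(m, px_size = pitch)
  lapply(polys, function(p) {
    p$outer <- sweep(p$outer, 2, c(x0, y0) * pitch, "+")
    p$holes <- lapply(p$holes, function(h) sweep(h, 2, c(x0, y0) * pitch, "+"))
    p
  })
}

#' Build the three ROI types (FC, PAT, PC)
#'
#' FC: every measured spot inside each valid core circle, labelled by the
#' core diagnosis (the label of the pathologist annotations overlapping the
#' core, by area). PAT: measured spots whose centres fall inside
#' pathologist polygons. PC: the tiled pixel-classifier detections,
#' restricted spot-wise to FC so that PC is contained in FC per core.
#'
#' @param grid a validated [dearray()] grid.
#' @param pat pathologist [annotation_set()] (image px frame).
#' @param labeled_detections output of [transfer_labels()].
#' @param transform `affine2d`, image px -> MSI um.
#' @param msi an [msi_dataset()].
#' @param buffer_um tiling buffer (default 4).
#' @return named list of `roi_set`s: `FC`, `PAT`, `PC`.
#' @export
build_roi_types <- function(grid, pat, labeled_detections, transform, msi,
                            buffer_um = 4) {
  grid <- validate_grid(grid, msi, transform)
  if (!any(grid$valid)) stop("no valid cores: no MSI spots map inside any core")
  gridv <- grid[grid$valid, , drop = FALSE]
  spot_px <- affine_apply(affine_invert(transform),
                          cbind((msi$spots$x + 0.5) * msi$pitch,
                                (msi$spots$y + 0.5) * msi$pitch))
  pat_labels <- annotation_labels(pat)

  # core diagnosis: label of overlapping pathologist annotations, by area
  core_label <- character(nrow(gridv))
  for (k in seq_len(nrow(gridv))) {
    areas <- stats::setNames(numeric(0), character(0))
    for (i in seq_along(pat$polygons)) {
      ctr <- colMeans(pat$polygons[[i]]$outer)
      if ((ctr[1] - gridv$cx[k])^2 + (ctr[2] - gridv$cy[k])^2 <= gridv$radius[k]^2) {
        a <- abs(poly_area(pat$polygons[[i]]$outer))
        l <- pat_labels[i]
        areas[l] <- if (l %in% names(areas)) areas[l] + a else a
      }
    }
    core_label[k] <- if (length(areas)) names(which.max(areas))[1] else "unlabeled"
  }

  fc_entries <- list(); fc_prov <- NULL
  for (k in seq_len(nrow(gridv))) {
    d2 <- (spot_px[, 1] - gridv$cx[k])^2 + (spot_px[, 2] - gridv$cy[k])^2
    inside <- which(d2 <= gridv$radius[k]^2)
    if (!length(inside)) next
    s <- data.frame(x = msi$spots$x[inside], y = msi$spots$y[inside])
    l <- core_label[k]
    fc_entries[[l]] <- unique(rbind(fc_entries[[l]], s))
    fc_prov <- rbind(fc_prov, data.frame(x = s$x, y = s$y, label = l,
                                         core = sprintf("r%d_c%d", gridv$row[k], gridv$col[k])))
  }
  fc <- roi_set("FC", fc_entries, fc_prov)

  pat_entries <- list()
  for (i in seq_along(pat$polygons)) {
    p <- pat$polygons[[i]]
    inside <- point_in_polygon(spot_px[, 1], spot_px[, 2],
                               c(list(p$outer), p$holes %||% list()))
    if (!any(inside)) next
    s <- data.frame(x = msi$spots$x[inside], y = msi$spots$y[inside])
    l <- pat_labels[i]
    pat_entries[[l]] <- unique(rbind(pat_entries[[l]], s))
  }
  # disjointness across labels: smallest label keeps contested spots
  if (length(pat_entries) > 1) {
    seen <- character(0)
    for (l in sort(names(pat_entries))) {
      d <- pat_entries[[l]]; k <- paste(d$x, d$y)
      pat_entries[[l]] <- d[!(k %in% seen), , drop = FALSE]
      seen <- c(seen, k[!(k %in% seen)])
    }
    pat_entries <- pat_entries[vapply(pat_entries, nrow, 0L) > 0]
  }
  patset <- roi_set("PAT", pat_entries)

  pc <- tile_to_msi(labeled_detections, transform, pitch = msi$pitch,
                    buffer_um = buffer_um, msi = msi)
  fc_keys <- paste(roi_spots(fc)$x, roi_spots(fc)$y)
  pc$entries <- lapply(pc$entries, function(d)
    d[paste(d$x, d$y) %in% fc_keys, , drop = FALSE])
  pc$entries <- pc$entries[vapply(pc$entries, nrow, 0L) > 0]

  list(FC = fc, PAT = patset, PC = pc)
}
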