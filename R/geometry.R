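#' Polygon and raster geometry primitives
#'
#' Lightweight 2-D geometry used throughout the pipeline: signed polygon
#' areas, even-odd point-in-polygon tests, connected-component labelling
#' with selectable connectivity, and exact conversion between binary masks
#' and polygons with holes (pixel-edge tracing / scanline rasterisation).
#'
#' Conventions: image pixels are 0-based with the pixel-centre convention,
#' pixel `(i, j)` (column `i`, row `j`) occupies the unit square
#' `[i, i+1] x [j, j+1]` with its centre at `(i + 0.5, j + 0.5)`; the y axis
#' points down the rows. Physical coordinates are pixel units times
#' `px_size` (micrometres per pixel).
#'
#' @name geometry
#' @keywords internal
NULL

#' Signed area of a polygon ring
#'
#' Shoelace formula; sign depends on vertex orientation. Use `abs()` for the
#' geometric area.
#'
#' @param xy two-column matrix of vertices (closed or open ring).
#' @return signed area, in squared units of `xy`.
#' @export
poly_area <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(2:n, 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Even-odd point-in-polygon test
#'
#' Crossing-number (even-odd) rule over one or more rings. Passing the outer
#' ring together with its hole rings classifies hole interiors as outside.
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param rings a two-column vertex matrix, or a list of such matrices.
#' @return logical vector, `TRUE` where the point lies inside.
#' @export
point_in_polygon <- function(px, py, rings) {
  if (is.matrix(rings) || is.data.frame(rings)) rings <- list(as.matrix(rings))
  crossings <- integer(length(px))
  for (ring in rings) {
    ring <- as.matrix(ring)
    n <- nrow(ring)
    x1 <- ring[, 1]; y1 <- ring[, 2]
    i2 <- c(2:n, 1)
    x2 <- ring[i2, 1]; y2 <- ring[i2, 2]
    keep <- y1 != y2
    x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
    for (e in seq_along(x1)) {
      # half-open in y so shared vertices are counted once
      hit <- (py >= pmin(y1[e], y2[e])) & (py < pmax(y1[e], y2[e]))
      if (any(hit)) {
        xc <- x1[e] + (py[hit] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
        inc <- xc > px[hit]
        crossings[hit] <- crossings[hit] + as.integer(inc)
      }
    }
  }
  crossings %% 2L == 1L
}

#' Label connected components of a binary mask
#'
#' Run-based two-pass labelling with union-find, supporting 4- or
#' 8-connectivity (EBImage's labeller is fixed at 4-connectivity, which does
#' not match the object/hole topology pairing used here).
#'
#' @param mask logical or 0/1 matrix (rows = y, columns = x).
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; 0 is background, components are
#'   numbered 1..k in raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  if (!any(m)) return(out)

  # runs of foreground along each row
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (j in seq_len(nr)) {
    r <- rle(m[j, ])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    fg <- which(r$values)
    run_row <- c(run_row, rep.int(j, length(fg)))
    run_s <- c(run_s, starts[fg])
    run_e <- c(run_e, ends[fg])
  }
  nruns <- length(run_row)
  parent <- seq_len(nruns)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8) 1L else 0L
  prev <- integer(0)  # run indices of previous row
  row_of <- split(seq_len(nruns), run_row)
  rows_present <- as.integer(names(row_of))
  for (ri in seq_along(rows_present)) {
    cur <- row_of[[ri]]
    if (ri > 1L && rows_present[ri] - rows_present[ri - 1L] == 1L) {
      prev <- row_of[[ri - 1L]]
      for (a in cur) {
        for (b in prev) {
          if (run_s[a] <= run_e[b] + slack && run_e[a] >= run_s[b] - slack) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(nruns), find, integer(1))
  labels <- match(roots, unique(roots[order(run_row, run_s)]))
  for (k in seq_len(nruns)) {
    out[run_row[k], run_s[k]:run_e[k]] <- labels[k]
  }
  out
}

#' Remove small objects and fill small holes in a binary mask
#'
#' Objects are 8-connected foreground components; holes are 4-connected
#' background components not touching the image border. Components below the
#' area threshold (in square micrometres) are removed or filled.
#'
#' @param mask logical matrix.
#' @param px_size micrometres per pixel.
#' @param min_object_um2,min_hole_um2 area thresholds in square micrometres.
#' @return cleaned logical matrix.
#' @export
clean_mask <- function(mask, px_size, min_object_um2 = 7, min_hole_um2 = 7) {
  px_area <- px_size^2
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) > 0) {
    sizes <- tabulate(lab)
    drop <- which(sizes * px_area < min_object_um2)
    if (length(drop)) mask <- mask & !(lab %in% drop)
    mask <- matrix(mask, nrow(lab), ncol(lab))
  }
  holes <- label_components(!mask, connectivity = 4)
  if (max(holes) > 0) {
    border_ids <- unique(c(holes[1, ], holes[nrow(holes), ],
                           holes[, 1], holes[, ncol(holes)]))
    sizes <- tabulate(holes)
    fill <- setdiff(which(sizes * px_area < min_hole_um2), border_ids)
    if (length(fill)) mask <- mask | matrix(holes %in% fill, nrow(holes), ncol(holes))
  }
  mask
}

# Trace all boundary loops of a single-component binary mask by pixel-edge
# chaining. Returns list(outer = matrix, holes = list of matrices) with
# vertices at pixel corners (0-based units). Exact: rasterising the result
# with the pixel-centre rule reproduces the mask.
trace_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(NULL)
  j <- ((idx - 1L) %% nr)            # 0-based row (y)
  i <- ((idx - 1L) %/% nr)           # 0-based col (x)
  pad <- function(di, dj) {
    ii <- i + di; jj <- j + dj
    ok <- ii >= 0L & ii < nc & jj >= 0L & jj < nr
    nb <- logical(length(idx))
    nb[ok] <- mask[cbind(jj[ok] + 1L, ii[ok] + 1L)]
    nb
  }
  up <- pad(0L, -1L); dn <- pad(0L, 1L); lf <- pad(-1L, 0L); rt <- pad(1L, 0L)
  # directed edges, interior on the left (y-down frame)
  sx <- c(i[!up],      i[!rt] + 1L, i[!dn] + 1L, i[!lf])
  sy <- c(j[!up],      j[!rt],      j[!dn] + 1L, j[!lf] + 1L)
  ex <- c(i[!up] + 1L, i[!rt] + 1L, i[!dn],      i[!lf])
  ey <- c(j[!up],      j[!rt] + 1L, j[!dn] + 1L, j[!lf])
  ne <- length(sx)
  key <- function(x, y) x + y * (nc + 2L)
  skey <- key(sx, sy)
  ord <- order(skey)
  skey_sorted <- skey[ord]
  used <- logical(ne)
  loops <- list()
  first_of <- function(k) {
    lo <- findInterval(k - 0.5, skey_sorted) + 1L
    hi <- findInterval(k + 0.5, skey_sorted)
    if (lo > hi) return(integer(0))
    ord[lo:hi]
  }
  for (e0 in seq_len(ne)) {
    if (used[e0]) next
    verts_x <- sx[e0]; verts_y <- sy[e0]
    cur <- e0
    repeat {
      used[cur] <- TRUE
      vx <- ex[cur]; vy <- ey[cur]
      verts_x <- c(verts_x, vx); verts_y <- c(verts_y, vy)
      if (vx == sx[e0] && vy == sy[e0]) break
      cand <- first_of(key(vx, vy))
      cand <- cand[!used[cand]]
      if (!length(cand)) break  # should not happen on valid masks
      if (length(cand) > 1L) {
        # ambiguous corner (diagonal touch): keep 8-connected foreground by
        # taking the outgoing edge equal to the incoming direction rotated -90
        dx <- ex[cur] - sx[cur]; dy <- ey[cur] - sy[cur]
        wx <- dy; wy <- -dx
        pick <- cand[(ex[cand] - sx[cand]) == wx & (ey[cand] - sy[cand]) == wy]
        cur <- if (length(pick)) pick[1L] else cand[1L]
      } else cur <- cand
    }
    loops[[length(loops) + 1L]] <- cbind(x = verts_x[-length(verts_x)],
                                         y = verts_y[-length(verts_y)])
  }
  areas <- vapply(loops, poly_area, numeric(1))
  outer_i <- which.max(areas)
  list(outer = loops[[outer_i]],
       holes = loops[areas < 0])
}

#' Convert a labelled mask to polygons with holes
#'
#' Traces pixel edges of each labelled component, producing polygons whose
#' rasterisation (pixel-centre rule) reproduces the mask exactly. Vertices
#' are scaled by `px_size` to physical units.
#'
#' @param labels integer label matrix (from [label_components()]) or a
#'   logical mask (treated as a single label).
#' @param px_size micrometres per pixel (default 1: pixel units).
#' @return list of `list(id, outer, holes, area)` per component; `area` in
#'   squared physical units (holes subtracted).
#' @export
mask_to_polygons <- function(labels, px_size = 1) {
  if (is.logical(labels)) labels <- label_components(labels, 8)
  ids <- sort(unique(labels[labels > 0]))
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    comp <- trace_component(labels == ids[k])
    outer <- comp$outer * px_size
    holes <- lapply(comp$holes, function(h) h * px_size)
    area <- abs(poly_area(outer)) - sum(vapply(holes, function(h) abs(poly_area(h)), numeric(1)))
    out[[k]] <- list(id = ids[k], outer = outer, holes = holes, area = area)
  }
  out
}

#' Rasterise polygons onto a pixel grid
#'
#' Scanline even-odd fill with the pixel-centre rule: a pixel is set when its
#' centre lies inside the polygon (outer ring minus holes).
#'
#' @param polys output of [mask_to_polygons()], or a single two-column matrix.
#' @param dim `c(nrow, ncol)` of the target mask.
#' @param px_size micrometres per pixel of the target grid.
#' @return logical matrix.
#' @export
polygons_to_mask <- function(polys, dim, px_size = 1) {
  if (is.matrix(polys)) polys <- list(list(outer = polys, holes = list()))
  nr <- dim[1]; nc <- dim[2]
  mask <- matrix(FALSE, nr, nc)
  yc <- (seq_len(nr) - 0.5) * px_size
  for (p in polys) {
    rings <- c(list(p$outer), p$holes)
    cross <- vector("list", nr)
    for (ring in rings) {
      ring <- as.matrix(ring)
      n <- nrow(ring); i2 <- c(2:n, 1)
      x1 <- ring[, 1]; y1 <- ring[, 2]; x2 <- ring[i2, 1]; y2 <- ring[i2, 2]
      for (e in seq_len(n)) {
        if (y1[e] == y2[e]) next
        ylo <- min(y1[e], y2[e]); yhi <- max(y1[e], y2[e])
        jj <- which(yc >= ylo & yc < yhi)
        if (!length(jj)) next
        xc <- x1[e] + (yc[jj] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
        for (t in seq_along(jj)) {
          cross[[jj[t]]] <- c(cross[[jj[t]]], xc[t])
        }
      }
    }
    for (jr in seq_len(nr)) {
      xs <- cross[[jr]]
      if (is.null(xs) || length(xs) < 2) next
      xs <- sort(xs) / px_size  # to pixel units
      for (k in seq(1, length(xs) - 1, by = 2)) {
        lo <- ceiling(xs[k] + 0.5); hi <- floor(xs[k + 1] + 0.5)
        if (hi >= lo) {
          lo <- max(lo, 1L); hi <- min(hi, nc)
          if (hi >= lo) mask[jr, lo:hi] <- TRUE
        }
      }
    }
  }
  mask
}

#' Binary dilation with a disc
#'
#' @param mask logical matrix.
#' @param radius_px disc radius in pixels; 0 returns the mask unchanged.
#' @return dilated logical matrix.
#' @export
dilate_disc <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  sz <- 2L * as.integer(ceiling(radius_px)) + 1L
  brush <- EBImage::makeBrush(sz, shape = "disc")
  out <- EBImage::dilate(EBImage::Image(mask * 1), brush)
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}
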