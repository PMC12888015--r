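#' Affine transforms between H&E pixel and MSI micrometre coordinates
#'
#' An `affine2d` maps image pixel coordinates (0-based, pixel-centre
#' convention) to the MSI stage frame in micrometres:
#' `msi = A %*% px + b`.
#'
#' @param A 2x2 linear part.
#' @param b length-2 translation (micrometres).
#' @return an object of class `affine2d`.
#' @export
affine2d <- function(A = diag(2), b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  b <- as.numeric(b)
  if (abs(det(A)) < .Machine$double.eps * 100)
    stop("degenerate affine transform: determinant is (near) zero")
  structure(list(A = A, b = b), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("Affine transform (image px -> MSI um)\n")
  cat(sprintf("  [%9.4f %9.4f]   [%9.3f]\n", x$A[1, 1], x$A[1, 2], x$b[1]))
  cat(sprintf("  [%9.4f %9.4f] + [%9.3f]\n", x$A[2, 1], x$A[2, 2], x$b[2]))
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param tr an `affine2d`.
#' @param xy two-column matrix (or length-2 vector) of points.
#' @return transformed two-column matrix.
#' @export
affine_apply <- function(tr, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy <- as.matrix(xy)
  t(tr$A %*% t(xy) + tr$b)
}

#' Invert an affine transform
#' @param tr an `affine2d`.
#' @return the inverse `affine2d` (MSI um -> image px).
#' @export
affine_invert <- function(tr) {
  Ai <- solve(tr$A)
  affine2d(Ai, -Ai %*% tr$b)
}

#' Compose two affine transforms (`t2` after `t1`)
#' @param t2,t1 `affine2d` objects.
#' @return `affine2d` equal to `x -> t2(t1(x))`.
#' @export
affine_compose <- function(t2, t1) {
  affine2d(t2$A %*% t1$A, t2$A %*% t1$b + t2$b)
}

#' Fit an affine transform to control-point pairs
#'
#' Least-squares estimate of the 6-parameter affine mapping image pixels to
#' MSI micrometres from landmark pairs, as used in place of manual
#' coregistration. Requires at least 3 non-collinear pairs.
#'
#' @param img_px n x 2 matrix of image points (pixels).
#' @param msi_um n x 2 matrix of corresponding MSI points (micrometres).
#' @return an `affine2d` with attribute `rms_residual_um`.
#' @export
fit_affine <- function(img_px, msi_um) {
  img_px <- as.matrix(img_px); msi_um <- as.matrix(msi_um)
  n <- nrow(img_px)
  if (n < 3 || nrow(msi_um) != n)
    stop("need >= 3 control-point pairs")
  X <- cbind(img_px, 1)
  if (qr(X)$rank < 3)
    stop("control points are collinear; affine transform is not identifiable")
  beta <- qr.solve(X, msi_um)           # 3 x 2: rows = (a_x, a_y, b)
  tr <- affine2d(t(beta[1:2, ]), beta[3, ])
  res <- affine_apply(tr, img_px) - msi_um
  attr(tr, "rms_residual_um") <- sqrt(mean(rowSums(res^2)))
  tr
}

#' Read control points from CSV
#'
#' Expected columns: `img_x, img_y, msi_x_um, msi_y_um`.
#' @param path CSV file path.
#' @return list with `img_px` and `msi_um` matrices.
#' @export
read_control_points <- function(path) {
  d <- utils::read.csv(path)
  need <- c("img_x", "img_y", "msi_x_um", "msi_y_um")
  if (!all(need %in% names(d)))
    stop("control-point CSV must have columns: ", paste(need, collapse = ", "))
  list(img_px = as.matrix(d[, c("img_x", "img_y")]),
       msi_um = as.matrix(d[, c("msi_x_um", "msi_y_um")]))
}

#' Render a reference-ion image from an MSI dataset
#'
#' Per-spot maximum intensity within a ppm window of a reference m/z, the
#' way ion images are rendered for visual coregistration.
#'
#' @param msi an [msi_dataset()].
#' @param ref_mz reference m/z (Da); the default is the collagen-derived
#'   peptide signal used as a spatial reference for fine alignment.
#' @param tol_ppm half-window in parts per million.
#' @return numeric vector of intensities, one per spot (order of `msi$spots`).
#' @export
ion_image <- function(msi, ref_mz = 1459.688, tol_ppm = 20) {
  tol <- ref_mz * tol_ppm * 1e-6
  sel <- which(msi$mz >= ref_mz - tol & msi$mz <= ref_mz + tol)
  if (!length(sel))
    stop(sprintf("reference m/z %.4f outside dataset m/z range", ref_mz))
  apply(msi$intensities[, sel, drop = FALSE], 1, max)
}

#' Refine a coregistration against a reference-ion image
#'
#' Exhaustive search over translations (and optionally small rotations)
#' around an initial transform, maximising the Pearson correlation between
#' the reference-ion intensity image and the H&E tissue mask resampled to
#' the MSI spot grid. Stands in for the manual fine alignment done against
#' the spatial distribution of the reference ion.
#'
#' @param t0 initial `affine2d` (image px -> MSI um).
#' @param tissue_mask logical matrix from the H&E (rows = y).
#' @param msi an [msi_dataset()].
#' @param ref_mz,tol_ppm reference ion and matching window.
#' @param search_radius_um translation search half-range (default 60).
#' @param step_um translation step (default 5).
#' @param rotations_deg vector of candidate rotations in degrees about the
#'   tissue-mask centre (default 0: translations only).
#' @return the best `affine2d`, with attributes `score` (Pearson r) and
#'   `shift_um` (applied translation).
#' @export
refine_by_ion_image <- function(t0, tissue_mask, msi,
                                ref_mz = 1459.688, tol_ppm = 20,
                                search_radius_um = 60, step_um = 5,
                                rotations_deg = 0) {
  ion <- ion_image(msi, ref_mz, tol_ppm)
  if (stats::sd(ion) == 0) {
    warning("reference-ion image has zero variance; returning t0 unchanged")
    attr(t0, "score") <- NA_real_
    return(t0)
  }
  spot_um <- cbind((msi$spots$x + 0.5) * msi$pitch,
                   (msi$spots$y + 0.5) * msi$pitch)
  nr <- nrow(tissue_mask); nc <- ncol(tissue_mask)
  sample_mask <- function(tr) {
    px <- affine_apply(affine_invert(tr), spot_um)
    i <- floor(px[, 1]) + 1L; j <- floor(px[, 2]) + 1L
    v <- numeric(nrow(px))
    ok <- i >= 1L & i <= nc & j >= 1L & j <= nr
    v[ok] <- as.numeric(tissue_mask[cbind(j[ok], i[ok])])
    v
  }
  shifts <- if (search_radius_um > 0)
    seq(-search_radius_um, search_radius_um, by = step_um) else 0
  ctr_px <- c(nc, nr) / 2
  best <- list(score = -Inf, tr = t0, shift = c(0, 0))
  for (th in rotations_deg * pi / 180) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    ctr_um <- as.numeric(t0$A %*% ctr_px + t0$b)
    # rotate about the tissue centre: msi' = R (t0(px) - ctr) + ctr
    t_rot <- affine2d(R %*% t0$A, as.numeric(R %*% (t0$b - ctr_um)) + ctr_um)
    for (dx in shifts) for (dy in shifts) {
      tr <- affine2d(t_rot$A, t_rot$b + c(dx, dy))
      v <- sample_mask(tr)
      if (stats::sd(v) == 0) next
      r <- stats::cor(v, ion)
      if (r > best$score) best <- list(score = r, tr = tr, shift = c(dx, dy))
    }
  }
  if (!is.finite(best$score)) {
    warning("tissue mask resampled to constant at every candidate; returning t0")
    attr(t0, "score") <- NA_real_
    return(t0)
  }
  out <- best$tr
  attr(out, "score") <- best$score
  attr(out, "shift_um") <- best$shift
  out
}
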