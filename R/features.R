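#' Multiscale H&E pixel features
#'
#' Converts an RGB H&E raster into the per-pixel feature stack consumed by
#' the pixel classifier: Gaussian (smoothed intensity/colour) and weighted
#' deviation (Gaussian-weighted local standard deviation, a texture measure)
#' features of the Red, Green, Blue and Hematoxylin channels at standard
#' deviations 2 and 4 px -- 16 features with the defaults.
#'
#' @name histology_features
#' @keywords internal
NULL

#' Standard H&E stain vectors (Ruifrok-Johnston)
#'
#' Rows are unit-norm optical-density vectors for hematoxylin, eosin and a
#' residual channel.
#' @return 3x3 numeric matrix.
#' @export
he_stain_vectors <- function() {
  m <- rbind(hematoxylin = c(0.65, 0.70, 0.29),
             eosin       = c(0.07, 0.99, 0.11),
             residual    = c(0.27, 0.57, 0.78))
  m / sqrt(rowSums(m^2))
}

#' Colour deconvolution of an RGB image into stain concentrations
#'
#' Beer-Lambert unmixing: per-pixel optical density
#' `OD = -log10(I / 255)` is projected onto the inverse of the stain matrix.
#' Concentrations are returned unclamped so that remixing reproduces the OD.
#'
#' @param rgb numeric array `H x W x 3` with values in `[0, 255]`.
#' @param stain_vectors 3x3 matrix, rows = unit-norm stain OD vectors.
#' @return array `H x W x 3` of stain concentrations (hematoxylin first for
#'   the default vectors).
#' @export
deconvolve_stains <- function(rgb, stain_vectors = he_stain_vectors()) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  M <- as.matrix(stain_vectors)
  if (abs(det(M)) < 1e-10) stop("singular stain matrix")
  d <- dim(rgb)
  od <- -log10(pmax(rgb, 1) / 255)
  odm <- matrix(od, ncol = 3)
  conc <- odm %*% solve(M)
  array(conc, dim = d)
}

#' Hematoxylin channel of an H&E image
#'
#' Non-negative hematoxylin concentration from [deconvolve_stains()];
#' pure-white pixels map to zero.
#'
#' @inheritParams deconvolve_stains
#' @return numeric matrix `H x W`.
#' @export
deconvolve_hematoxylin <- function(rgb, stain_vectors = he_stain_vectors()) {
  pmax(deconvolve_stains(rgb, stain_vectors)[, , 1], 0)
}

#' Feature configuration
#'
#' @param channels subset of `"Red"`, `"Green"`, `"Blue"`, `"Hematoxylin"`.
#' @param feature_kinds subset of `"gaussian"`, `"weighted_deviation"`.
#' @param sigmas Gaussian standard deviations in pixels at the working
#'   resolution (default `c(2, 4)`).
#' @param stain_vectors stain matrix for the hematoxylin channel.
#' @return a `feature_config` list.
#' @export
feature_config <- function(channels = c("Red", "Green", "Blue", "Hematoxylin"),
                           feature_kinds = c("gaussian", "weighted_deviation"),
                           sigmas = c(2, 4),
                           stain_vectors = he_stain_vectors()) {
  channels <- match.arg(channels, c("Red", "Green", "Blue", "Hematoxylin"),
                        several.ok = TRUE)
  feature_kinds <- match.arg(feature_kinds, c("gaussian", "weighted_deviation"),
                             several.ok = TRUE)
  if (any(sigmas <= 0)) stop("sigmas must be > 0")
  structure(list(channels = channels, feature_kinds = feature_kinds,
                 sigmas = as.numeric(sigmas), stain_vectors = stain_vectors),
            class = "feature_config")
}

# reflect-pad a matrix by w pixels on every side (edge row/col duplicated)
.pad_reflect <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(w, nr))), seq_len(nr),
          nr + 1 - seq_len(min(w, nr)))
  ci <- c(rev(seq_len(min(w, nc))), seq_len(nc),
          nc + 1 - seq_len(min(w, nc)))
  m[ri, ci, drop = FALSE]
}

#' Gaussian filter with reflective boundaries
#'
#' Separable Gaussian kernel truncated at 4 sigma, applied by FFT
#' convolution on a reflect-padded copy to avoid border artefacts.
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels (> 0).
#' @return filtered matrix of the same size.
#' @export
gaussian_filter <- function(m, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  k <- outer(g, g)
  p <- .pad_reflect(m, r)
  out <- EBImage::filter2(p, k, boundary = "circular")
  out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

#' Gaussian-weighted local standard deviation
#'
#' `sqrt(max(0, G_sigma(I^2) - G_sigma(I)^2))`: the "weighted deviation"
#' texture feature, zero on locally constant images and invariant to adding
#' a constant.
#'
#' @inheritParams gaussian_filter
#' @return matrix of local weighted standard deviations.
#' @export
weighted_deviation_filter <- function(m, sigma) {
  mu <- gaussian_filter(m, sigma)
  v <- gaussian_filter(m^2, sigma) - mu^2
  sqrt(pmax(v, 0))
}

#' Compute the multiscale feature stack of an H&E image
#'
#' @param rgb numeric array `H x W x 3`, values in `[0, 255]`.
#' @param cfg a [feature_config()].
#' @return a `feature_stack`: list with `data` (array `H x W x F`),
#'   `feature_names` (`<channel>_<kind>_s<sigma>`, channel-major order) and
#'   `px_size` (attached by the caller via the `px_size` argument).
#' @param px_size micrometres per pixel, carried along for area bookkeeping.
#' @export
compute_features <- function(rgb, cfg = feature_config(), px_size = 0.44) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3, all(dim(rgb)[1:2] > 0))
  chans <- list()
  for (ch in cfg$channels) {
    chans[[ch]] <- switch(ch,
      Red = rgb[, , 1], Green = rgb[, , 2], Blue = rgb[, , 3],
      Hematoxylin = deconvolve_hematoxylin(rgb, cfg$stain_vectors))
  }
  nf <- length(cfg$channels) * length(cfg$feature_kinds) * length(cfg$sigmas)
  data <- array(0, dim = c(dim(rgb)[1], dim(rgb)[2], nf))
  nms <- character(nf)
  f <- 0L
  for (ch in cfg$channels) for (kind in cfg$feature_kinds) for (s in cfg$sigmas) {
    f <- f + 1L
    data[, , f] <- if (kind == "gaussian") gaussian_filter(chans[[ch]], s)
                   else weighted_deviation_filter(chans[[ch]], s)
    nms[f] <- sprintf("%s_%s_s%g", ch, kind, s)
  }
  structure(list(data = data, feature_names = nms, px_size = px_size,
                 config = cfg),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("Feature stack: %d x %d px, %d features, %.3g um/px\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$px_size))
  cat("  ", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}
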