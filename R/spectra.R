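#' Spectral processing: normalisation, mean spectra, peak picking
#'
#' @name spectra
#' @keywords internal
NULL

#' Root-mean-square normalisation
#'
#' Divides every spectrum by its own RMS intensity `sqrt(mean(I^2))`, the
#' normalisation applied to the whole dataset before any comparison.
#' All-zero spectra are left unchanged with a warning.
#'
#' @param msi an [msi_dataset()] with `normalization == "none"`.
#' @return the normalised [msi_dataset()] (`normalization == "rms"`).
#' @export
rms_normalize <- function(msi) {
  stopifnot(inherits(msi, "msi_dataset"))
  if (msi$normalization != "none")
    stop("dataset is already normalized (", msi$normalization,
         "); refusing to normalize twice")
  rms <- sqrt(rowMeans(msi$intensities^2))
  zero <- rms == 0
  if (any(zero)) {
    warning("all-zero spectra left unchanged at spots: ",
            paste(sprintf("(%d,%d)", msi$spots$x[zero], msi$spots$y[zero]),
                  collapse = " "))
    rms[zero] <- 1
  }
  msi$intensities <- msi$intensities / rms
  msi$normalization <- "rms"
  msi
}

# resolve a spot selection (integer rows, logical, or data.frame x/y) to rows
.spot_rows <- function(msi, spots) {
  if (is.logical(spots)) return(which(spots))
  if (is.data.frame(spots) || is.matrix(spots)) {
    spots <- as.data.frame(spots)
    key <- paste(msi$spots$x, msi$spots$y)
    rows <- match(paste(spots$x, spots$y), key)
    if (anyNA(rows)) stop("selection contains spots absent from the dataset")
    return(rows)
  }
  as.integer(spots)
}

#' Mean spectrum over a set of spots
#'
#' @param msi an [msi_dataset()].
#' @param spots spot selection: integer row indices, logical vector, or a
#'   data.frame with `x`, `y` indices.
#' @return list with `mz` and `intensity` (the arithmetic mean spectrum).
#' @export
mean_spectrum <- function(msi, spots) {
  rows <- .spot_rows(msi, spots)
  if (!length(rows)) stop("empty spot set")
  list(mz = msi$mz,
       intensity = colMeans(msi$intensities[rows, , drop = FALSE]),
       n_spots = length(rows))
}

# piecewise baseline and noise over fixed-width m/z windows.
# baseline: low percentile per window, linearly interpolated at window
# centres, then debiased by the expected offset of that quantile under the
# noise model (the q-quantile of pure noise sits qnorm(q) * sigma below the
# true baseline, so the raw percentile systematically underestimates it);
# noise: 1.4826 * MAD of baseline-subtracted residuals per window (shift
# invariant, so unaffected by the debiasing).
.baseline_noise <- function(mz, intensity, window_da = 50, baseline_q = 0.1) {
  # last window absorbs the remainder so no window is degenerately narrow
  edges <- seq(min(mz), max(mz), by = window_da)
  if (length(edges) > 1 && max(mz) - edges[length(edges)] < window_da / 2)
    edges <- edges[-length(edges)]
  w <- findInterval(mz, edges)
  ctr <- tapply(mz, w, mean)
  blo <- tapply(intensity, w, stats::quantile, probs = baseline_q, names = FALSE)
  baseline <- if (length(ctr) > 1)
    stats::approx(ctr, blo, xout = mz, rule = 2)$y
  else rep(blo[[1]], length(mz))
  resid <- intensity - baseline
  nz <- tapply(resid, w, stats::mad)
  noise <- if (length(ctr) > 1)
    stats::approx(ctr, nz, xout = mz, rule = 2)$y
  else rep(nz[[1]], length(mz))
  list(baseline = baseline - stats::qnorm(baseline_q) * noise, noise = noise)
}

#' Pick peaks from a spectrum by signal-to-noise and relative intensity
#'
#' Apex heights are estimated on a lightly Savitzky-Golay-smoothed signal
#' (quadratic, 5-point window) above a debiased low-percentile baseline,
#' while the noise floor is the windowed 1.4826*MAD of the raw
#' baseline-subtracted residuals, so the measured S/N of a sub-threshold
#' peak stays well below the threshold even under noise fluctuations. A peak is reported when its baseline-subtracted apex has
#' S/N >= `snr_min` and height >= `rel_int_min` times the base peak. The
#' apex m/z is refined by a three-point parabola.
#'
#' @param mz,intensity the spectrum (strictly increasing m/z axis).
#' @param snr_min signal-to-noise threshold (default 6).
#' @param rel_int_min relative-intensity threshold as a fraction of the base
#'   peak (default 0.003, i.e. 0.3 percent).
#' @param baseline_window,noise_window window width in Da for the baseline
#'   percentile and noise MAD (both default 50).
#' @param min_sep_da minimum separation between reported apexes (default
#'   0.25); of two candidates closer than this the stronger wins.
#' @param smooth logical; disable the Savitzky-Golay smoothing.
#' @return a `peak_list`: data.frame with columns `mz`, `intensity`, `snr`,
#'   sorted by m/z, with picking parameters in attributes.
#' @export
pick_peaks <- function(mz, intensity, snr_min = 6, rel_int_min = 0.003,
                       baseline_window = 50, noise_window = baseline_window,
                       min_sep_da = 0.25, smooth = TRUE) {
  if (is.list(mz) && is.null(dim(mz))) { intensity <- mz$intensity; mz <- mz$mz }
  n <- length(mz)
  stopifnot(length(intensity) == n)
  empty <- data.frame(mz = numeric(0), intensity = numeric(0), snr = numeric(0))
  attr(empty, "picking_params") <- list(snr_min = snr_min, rel_int_min = rel_int_min)
  class(empty) <- c("peak_list", "data.frame")
  if (n < 3 || stats::sd(intensity) == 0) return(empty)

  sm <- if (smooth && n >= 5) signal::sgolayfilt(intensity, p = 2, n = 5) else intensity
  bn <- .baseline_noise(mz, intensity, window_da = baseline_window)
  sig <- sm - bn$baseline
  noise <- pmax(bn$noise, .Machine$double.eps)

  i <- 2:(n - 1)
  cand <- i[sig[i] > sig[i - 1] & sig[i] >= sig[i + 1]]
  if (!length(cand)) return(empty)
  snr <- sig[cand] / noise[cand]
  keep <- snr >= snr_min & sig[cand] >= rel_int_min * max(sig)
  cand <- cand[keep]; snr <- snr[keep]
  if (!length(cand)) return(empty)

  # enforce minimum apex separation, strongest first
  ord <- order(sig[cand], decreasing = TRUE)
  acc <- integer(0)
  for (k in ord) {
    if (!length(acc) || all(abs(mz[cand[k]] - mz[cand[acc]]) >= min_sep_da))
      acc <- c(acc, k)
  }
  cand <- cand[sort(acc)]; snr <- sig[cand] / noise[cand]

  # parabolic apex refinement on the smoothed, baseline-subtracted signal
  y0 <- sig[cand - 1]; y1 <- sig[cand]; y2 <- sig[cand + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- ifelse(abs(denom) > 0, 0.5 * (y0 - y2) / denom, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  step <- c(diff(mz), mz[n] - mz[n - 1])[cand]
  out <- data.frame(mz = mz[cand] + delta * step,
                    intensity = sig[cand],
                    snr = snr)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "picking_params") <- list(snr_min = snr_min, rel_int_min = rel_int_min,
                                      baseline_window = baseline_window,
                                      min_sep_da = min_sep_da, smooth = smooth)
  class(out) <- c("peak_list", "data.frame")
  out
}

#' @export
print.peak_list <- function(x, ...) {
  p <- attr(x, "picking_params")
  cat(sprintf("Peak list: %d peaks (S/N >= %g, rel. intensity >= %g%%)\n",
              nrow(x), p$snr_min, 100 * p$rel_int_min))
  print.data.frame(x, ...)
  invisible(x)
}

#' Match two peak lists within a ppm tolerance
#'
#' Greedy nearest-neighbour one-to-one matching: candidate pairs within
#' `tol_ppm` are accepted in order of increasing ppm distance, each peak
#' used at most once. Partition sizes conserve the list lengths.
#'
#' @param a,b peak lists (data.frames with an `mz` column) or numeric m/z
#'   vectors.
#' @param tol_ppm matching tolerance in parts per million (default 20).
#' @return list with data.frame `common` (`mz_a`, `mz_b`, `ppm`) and numeric
#'   vectors `only_a`, `only_b` of unmatched m/z values.
#' @export
match_peaks <- function(a, b, tol_ppm = 20) {
  mza <- if (is.data.frame(a)) a$mz else as.numeric(a)
  mzb <- if (is.data.frame(b)) b$mz else as.numeric(b)
  na <- length(mza); nb <- length(mzb)
  pairs <- data.frame(mz_a = numeric(0), mz_b = numeric(0), ppm = numeric(0))
  ua <- logical(na); ub <- logical(nb)
  if (na && nb) {
    d <- abs(outer(mza, mzb, "-")) / matrix(mza, na, nb) * 1e6
    idx <- which(d <= tol_ppm, arr.ind = TRUE)
    if (nrow(idx)) {
      idx <- idx[order(d[idx]), , drop = FALSE]
      keep <- logical(nrow(idx))
      for (k in seq_len(nrow(idx))) {
        ia <- idx[k, 1]; ib <- idx[k, 2]
        if (!ua[ia] && !ub[ib]) { ua[ia] <- ub[ib] <- TRUE; keep[k] <- TRUE }
      }
      idx <- idx[keep, , drop = FALSE]
      pairs <- data.frame(mz_a = mza[idx[, 1]], mz_b = mzb[idx[, 2]],
                          ppm = d[idx])
    }
  }
  list(common = pairs[order(pairs$mz_a), , drop = FALSE],
       only_a = mza[!ua],
       only_b = mzb[!ub])
}

#' Extract per-spot feature intensities at given m/z values
#'
#' For each spot and each target m/z, the maximum of the baseline-subtracted
#' signal within a ppm window -- the same quantity an ion image renders.
#' Values never go below zero; targets outside the dataset m/z range are
#' dropped with a warning. When the ppm window is narrower than the local
#' m/z grid spacing and contains no grid point, the nearest bin is used so
#' a feature never silently reads as zero for purely numerical reasons.
#'
#' @param msi an [msi_dataset()].
#' @param mz_targets numeric vector of feature m/z values (Da).
#' @param tol_ppm half-window in ppm (default 20).
#' @param spots optional spot selection (see [mean_spectrum()]); default all.
#' @param baseline_window baseline window in Da.
#' @return numeric matrix, spots x features, with m/z values as column names.
#' @export
extract_intensity_matrix <- function(msi, mz_targets, tol_ppm = 20,
                                     spots = NULL, baseline_window = 50) {
  rows <- if (is.null(spots)) seq_len(nrow(msi$spots)) else .spot_rows(msi, spots)
  inside <- mz_targets >= min(msi$mz) & mz_targets <= max(msi$mz)
  if (any(!inside)) {
    warning("feature m/z outside dataset range dropped: ",
            paste(format(mz_targets[!inside]), collapse = ", "))
    mz_targets <- mz_targets[inside]
  }
  sel <- lapply(mz_targets, function(t) {
    tol <- t * tol_ppm * 1e-6
    w <- which(msi$mz >= t - tol & msi$mz <= t + tol)
    if (!length(w)) w <- which.min(abs(msi$mz - t))
    w
  })
  out <- matrix(0, length(rows), length(mz_targets),
                dimnames = list(NULL, format(mz_targets)))
  for (r in seq_along(rows)) {
    y <- msi$intensities[rows[r], ]
    bl <- .baseline_noise(msi$mz, y, window_da = baseline_window)$baseline
    res <- y - bl
    for (f in seq_along(sel))
      if (length(sel[[f]])) out[r, f] <- max(0, res[sel[[f]]])
  }
  out
}
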