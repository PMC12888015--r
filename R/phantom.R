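#' Synthetic TMA fixtures: paired H&E-like images and MSI cubes
#'
#' The fixture generator emulates the structure the pipeline is built for:
#' a tissue-microarray of thyroid-like cores, each packed with follicles
#' whose cell-rich epithelial rims surround smooth colloid-filled lumens.
#' Peptide signals scale with the cell-rich fraction of each MSI spot,
#' matrix-adduct interferents are enriched in colloid, and trypsin
#' autolysis peaks are spatially uniform -- so every downstream claim about
#' interferent suppression and peptide recovery has a known ground truth.
#'
#' @name synthetic_fixtures
#' @keywords internal
NULL

#' Define a fixture phantom
#'
#' Geometry of the synthetic TMA: core layout, follicle structure, image
#' and MSI resolutions, and the planted affine between image pixels and the
#' MSI stage frame.
#'
#' @param n_rows,n_cols TMA grid shape (default 2 x 2).
#' @param diagnoses diagnosis label per core, row-major (defaults to the
#'   four thyroid-nodule classes PTC, FVPTC, NIFTP, FA).
#' @param core_radius_um core radius (default 100).
#' @param core_spacing_um centre-to-centre spacing (default 250).
#' @param lumen_radius_um,rim_um follicle lumen radius and epithelial rim
#'   thickness (defaults 18 and 12).
#' @param image_px_size micrometres per image pixel (default 0.44, the
#'   working resolution of the pixel classifier).
#' @param msi_pitch MSI spot pitch in micrometres (default 20).
#' @param mz_range,mz_step shared m/z axis (defaults 700-3000 Da, 0.05 Da).
#' @param rotation_deg planted rotation of the image-to-MSI transform.
#' @param shift_um planted translation (micrometres).
#' @param seed integer seed governing all randomness of the fixture.
#' @param max_px refuse images larger than this in either dimension.
#' @return a `fixture_phantom` list, including `transform` (the planted
#'   `affine2d`) and the per-core follicle layout.
#' @export
fixture_phantom <- function(n_rows = 2, n_cols = 2,
                            diagnoses = c("PTC", "FVPTC", "NIFTP", "FA"),
                            core_radius_um = 100, core_spacing_um = 250,
                            lumen_radius_um = 18, rim_um = 12,
                            image_px_size = 0.44, msi_pitch = 20,
                            mz_range = c(700, 3000), mz_step = 0.05,
                            rotation_deg = 0, shift_um = c(24, 12),
                            seed = 1L, max_px = 4096L) {
  stopifnot(msi_pitch / image_px_size > 1)
  n_cores <- n_rows * n_cols
  diagnoses <- if (n_cores > 0) rep_len(diagnoses, n_cores) else character(0)
  w_um <- max(n_cols, 1) * core_spacing_um
  h_um <- max(n_rows, 1) * core_spacing_um
  nc <- as.integer(round(w_um / image_px_size))
  nr <- as.integer(round(h_um / image_px_size))
  if (nc > max_px || nr > max_px)
    stop(sprintf("image %d x %d px exceeds the cap of %d px; shrink the phantom",
                 nr, nc, max_px))
  set.seed(seed)
  cores <- list()
  k <- 0L
  for (r in seq_len(n_rows)) for (cc in seq_len(n_cols)) {
    k <- k + 1L
    ctr <- c((cc - 0.5) * core_spacing_um, (r - 0.5) * core_spacing_um)
    if (ctr[1] + core_radius_um > w_um || ctr[2] + core_radius_um > h_um ||
        any(ctr - core_radius_um < 0))
      stop("core footprint outside image bounds")
    fr <- lumen_radius_um + rim_um
    pitch <- 2 * fr + 6
    kx <- floor(core_radius_um / pitch); ky <- floor(core_radius_um / (pitch * 0.87))
    fol <- NULL
    for (j in -ky:ky) for (i in -kx:kx) {
      fx <- i * pitch + (abs(j) %% 2) * pitch / 2 + stats::runif(1, -2, 2)
      fy <- j * pitch * 0.87 + stats::runif(1, -2, 2)
      if (sqrt(fx^2 + fy^2) <= core_radius_um - fr)
        fol <- rbind(fol, c(ctr[1] + fx, ctr[2] + fy))
    }
    cores[[k]] <- list(center = ctr, radius = core_radius_um,
                       diagnosis = diagnoses[k],
                       row = r, col = cc,
                       follicles = fol,
                       lumen_radius = lumen_radius_um, rim = rim_um)
  }
  th <- rotation_deg * pi / 180
  A <- image_px_size * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  structure(list(cores = cores, image_px_size = image_px_size,
                 msi_pitch = msi_pitch, mz_range = mz_range, mz_step = mz_step,
                 dim_px = c(nr, nc), seed = seed,
                 transform = affine2d(A, shift_um)),
            class = "fixture_phantom")
}

#' Default spectral model for the fixture
#'
#' Planted peaks: per-diagnosis tryptic-peptide signatures (amplitudes
#' scale with the cell-rich fraction of a spot), matrix-adduct interferents
#' from the default interferent panel (enriched in colloid by
#' `1 + enrichment * colloid_fraction`), uniform trypsin autolysis peaks,
#' and a tissue-wide collagen-like structural peak at m/z 1459.688 used as
#' the coregistration reference ion. Each diagnosis carries two shared
#' peptides, two strong unique peptides (the planted discriminative
#' features) and one trace peptide whose relative intensity is designed to
#' survive the 0.3 percent threshold only in cell-rich regions.
#'
#' @param peak_sigma Gaussian peak width in Da (default 0.06).
#' @param baseline_level flat baseline (default 1).
#' @param noise_sd white-noise standard deviation (default 0.2).
#' @param interferent_amp,interferent_enrichment HCCA adduct base amplitude
#'   and colloid enrichment factor (defaults 20 and 3).
#' @param trypsin_amp trypsin autolysis amplitude (default 10).
#' @return a `spectrum_model` list.
#' @export
spectrum_model <- function(peak_sigma = 0.06, baseline_level = 1,
                           noise_sd = 0.2, interferent_amp = 20,
                           interferent_enrichment = 3, trypsin_amp = 10) {
  stopifnot(peak_sigma > 0, noise_sd >= 0, interferent_amp >= 0,
            interferent_enrichment >= 1)
  shared <- data.frame(mz = c(944.53, 1325.75), amplitude = c(40, 35))
  uniq <- list(
    PTC   = data.frame(mz = c(1198.70, 1105.58, 2211.10), amplitude = c(60, 25, 0.85)),
    FVPTC = data.frame(mz = c(1274.66, 1533.78, 2378.35), amplitude = c(60, 25, 0.85)),
    NIFTP = data.frame(mz = c(1620.82, 1790.90, 2455.42), amplitude = c(60, 25, 0.85)),
    FA    = data.frame(mz = c(1865.98, 2045.07, 2602.55), amplitude = c(60, 25, 0.85)))
  peptide <- lapply(uniq, function(u) rbind(shared, u))
  panel <- interferent_panel()
  structure(list(
    peptide_peaks = peptide,
    interferent_peaks = data.frame(mz = panel$hcca_mz,
                                   amplitude = interferent_amp,
                                   enrichment = interferent_enrichment),
    trypsin_peaks = data.frame(mz = panel$trypsin_mz, amplitude = trypsin_amp),
    structural_peaks = data.frame(mz = 1459.688, amplitude = 30),
    peak_sigma = peak_sigma, baseline_level = baseline_level,
    noise_sd = noise_sd),
    class = "spectrum_model")
}

#' Planted discriminative m/z features of a spectrum model
#'
#' The unique, non-trace peptides of each diagnosis: the features an ROC
#' analysis should flag.
#'
#' @param model a [spectrum_model()].
#' @param min_amplitude amplitude floor separating discriminative from trace
#'   peptides (default 1).
#' @return data.frame with `mz`, `diagnosis`, `amplitude`.
#' @export
planted_discriminative_mz <- function(model, min_amplitude = 1) {
  all_mz <- table(unlist(lapply(model$peptide_peaks, `[[`, "mz")))
  shared <- as.numeric(names(all_mz)[all_mz == length(model$peptide_peaks)])
  out <- NULL
  for (dx in names(model$peptide_peaks)) {
    p <- model$peptide_peaks[[dx]]
    p <- p[!(p$mz %in% shared) & p$amplitude >= min_amplitude, , drop = FALSE]
    if (nrow(p)) out <- rbind(out, data.frame(mz = p$mz, diagnosis = dx,
                                              amplitude = p$amplitude))
  }
  out[order(out$mz), ]
}

# per-pixel region masks of the phantom (rows = y)
.phantom_masks <- function(phantom) {
  nr <- phantom$dim_px[1]; nc <- phantom$dim_px[2]
  ps <- phantom$image_px_size
  cell <- colloid <- tissue <- matrix(FALSE, nr, nc)
  xs <- (seq_len(nc) - 0.5) * ps
  ys <- (seq_len(nr) - 0.5) * ps
  for (core in phantom$cores) {
    ci <- which(xs >= core$center[1] - core$radius & xs <= core$center[1] + core$radius)
    ri <- which(ys >= core$center[2] - core$radius & ys <= core$center[2] + core$radius)
    dx <- xs[ci] - core$center[1]; dy <- ys[ri] - core$center[2]
    d2 <- outer(dy^2, dx^2, "+")
    incore <- d2 <= core$radius^2
    tissue[ri, ci] <- tissue[ri, ci] | incore
    if (is.null(core$follicles)) next
    for (f in seq_len(nrow(core$follicles))) {
      fc <- core$follicles[f, ]
      fd2 <- outer((ys[ri] - fc[2])^2, (xs[ci] - fc[1])^2, "+")
      lum <- fd2 <= core$lumen_radius^2
      rim <- fd2 <= (core$lumen_radius + core$rim)^2 & !lum
      colloid[ri, ci] <- colloid[ri, ci] | (lum & incore)
      cell[ri, ci] <- cell[ri, ci] | (rim & incore)
    }
  }
  cell <- cell & !colloid
  list(cell_rich = cell, colloid = colloid, tissue = tissue)
}

# sample n small square annotations fully inside a mask; centres optionally
# restricted to a sub-mask (e.g. a boundary band)
.sample_squares <- function(mask, n, half, label, centers = mask) {
  idx <- which(centers & mask)
  if (!length(idx)) return(list())
  nr <- nrow(mask); nc <- ncol(mask)
  out <- list(); tries <- 0L
  while (length(out) < n && tries < 50L * n) {
    tries <- tries + 1L
    p <- idx[sample.int(length(idx), 1L)]
    j <- (p - 1L) %% nr + 1L; i <- (p - 1L) %/% nr + 1L
    if (i - half < 1 || i + half > nc || j - half < 1 || j + half > nr) next
    if (!all(mask[(j - half):(j + half), (i - half):(i + half)])) next
    # polygon in 0-based pixel-corner units
    x0 <- i - 1L - half; x1 <- i + half
    y0 <- j - 1L - half; y1 <- j + half
    out[[length(out) + 1L]] <- list(
      outer = cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)),
      holes = list(), label = label)
  }
  out
}

#' Render the H&E-like image, ground-truth masks and annotation sets
#'
#' Cell-rich rims are rendered hematoxylin-dominant with high-frequency
#' texture, colloid lumens as smooth eosin-dominant fills, inter-follicular
#' stroma as pale eosin, background near-white. Masks are pixel-exact
#' ground truth. Training annotations are small squares sampled inside the
#' ground-truth regions (about 15 per class); pathologist-style polygons
#' are deliberately coarse -- a morphological closing of each core's
#' follicle union that engulfs the colloid lumens, labelled with the core
#' diagnosis.
#'
#' @param phantom a [fixture_phantom()].
#' @param n_training_per_class training squares per class (default 15).
#' @return list with `rgb` (array `H x W x 3`, 0-255), `masks`
#'   (`cell_rich`, `colloid`, `tissue`), `training` and `pathologist`
#'   [annotation_set()]s, and `px_size`.
#' @export
render_he_image <- function(phantom, n_training_per_class = 15) {
  set.seed(phantom$seed + 1L)
  m <- .phantom_masks(phantom)
  nr <- phantom$dim_px[1]; nc <- phantom$dim_px[2]
  stroma <- m$tissue & !m$cell_rich & !m$colloid
  R <- matrix(252, nr, nc); G <- matrix(250, nr, nc); B <- matrix(252, nr, nc)
  R[stroma] <- 238; G[stroma] <- 200; B[stroma] <- 216
  R[m$colloid] <- 228; G[m$colloid] <- 160; B[m$colloid] <- 196
  R[m$cell_rich] <- 118; G[m$cell_rich] <- 82; B[m$cell_rich] <- 160
  ncell <- sum(m$cell_rich)
  # high-frequency nuclear texture in the rims; gentle noise elsewhere
  R[m$cell_rich] <- R[m$cell_rich] + stats::rnorm(ncell, 0, 28)
  G[m$cell_rich] <- G[m$cell_rich] + stats::rnorm(ncell, 0, 24)
  B[m$cell_rich] <- B[m$cell_rich] + stats::rnorm(ncell, 0, 28)
  npx <- nr * nc
  R <- R + stats::rnorm(npx, 0, 2); G <- G + stats::rnorm(npx, 0, 2)
  B <- B + stats::rnorm(npx, 0, 2)
  rgb <- array(0, c(nr, nc, 3))
  rgb[, , 1] <- pmin(pmax(R, 0), 255)
  rgb[, , 2] <- pmin(pmax(G, 0), 255)
  rgb[, , 3] <- pmin(pmax(B, 0), 255)

  if (length(phantom$cores)) {
    half <- max(2L, as.integer(round(3 / phantom$image_px_size / 2)))
    tr_cell <- .sample_squares(m$cell_rich, n_training_per_class, half, "cell_rich")
    # negatives cover colloid, stroma, background and, as a pathologist
    # would, the band hugging the epithelial rims
    band <- dilate_disc(m$cell_rich, 2L * half + 2L) & !m$cell_rich
    n4 <- ceiling(n_training_per_class / 4)
    tr_non <- c(.sample_squares(m$colloid, n4, half, "non_cell_rich"),
                .sample_squares(stroma, n4, half, "non_cell_rich"),
                .sample_squares(!m$tissue, n4, half, "non_cell_rich"),
                .sample_squares(!m$cell_rich, n_training_per_class - 3 * n4,
                                half, "non_cell_rich", centers = band))
    training <- annotation_set(c(tr_cell, tr_non), "training")
  } else training <- annotation_set(list(), "training")

  pat <- list()
  close_r <- as.integer(round(15 / phantom$image_px_size))
  for (core in phantom$cores) {
    if (is.null(core$follicles)) next
    ps <- phantom$image_px_size
    ci <- range(which((seq_len(nc) - 0.5) * ps >= core$center[1] - core$radius - 20 &
                      (seq_len(nc) - 0.5) * ps <= core$center[1] + core$radius + 20))
    ri <- range(which((seq_len(nr) - 0.5) * ps >= core$center[2] - core$radius - 20 &
                      (seq_len(nr) - 0.5) * ps <= core$center[2] + core$radius + 20))
    sub <- (m$cell_rich | m$colloid)[ri[1]:ri[2], ci[1]:ci[2]]
    closed <- dilate_disc(sub, close_r)
    closed <- .erode_disc(closed, close_r)
    lab <- label_components(closed, 8)
    if (max(lab) == 0) next
    keep <- which.max(tabulate(lab))
    polys <- mask_to_polygons(lab == keep, px_size = 1)
    outer <- polys[[1]]$outer
    outer[, 1] <- outer[, 1] + ci[1] - 1L
    outer[, 2] <- outer[, 2] + ri[1] - 1L
    pat[[length(pat) + 1L]] <- list(outer = outer, holes = list(),
                                    label = core$diagnosis)
  }
  list(rgb = rgb, masks = m,
       training = training,
       pathologist = annotation_set(pat, "pathologist"),
       px_size = phantom$image_px_size)
}

.erode_disc <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  !dilate_disc(!mask, radius_px)
}

#' Render the MSI cube of a phantom
#'
#' One spectrum per MSI spot whose footprint overlaps tissue. Each spectrum
#' is `baseline + sum of Gaussian peaks + white noise` (clipped at zero);
#' peptide amplitudes scale with the spot's cell-rich fraction, interferents
#' with `1 + enrichment * colloid_fraction`, structural peaks with the
#' tissue fraction, trypsin peaks are uniform. Fractions are measured on
#' the ground-truth masks through the planted affine, sampling each spot
#' footprint on a regular sub-grid.
#'
#' @param phantom a [fixture_phantom()].
#' @param model a [spectrum_model()].
#' @param masks masks from [render_he_image()] at the same seed (recomputed
#'   from the phantom when omitted).
#' @param footprint_n sub-grid sampling density per spot side (default 7).
#' @return an [msi_dataset()] with attribute `spot_fractions` (data.frame
#'   `x`, `y`, `cell`, `colloid`, `tissue`, `diagnosis`).
#' @export
render_msi_cube <- function(phantom, model = spectrum_model(), masks = NULL,
                            footprint_n = 7) {
  if (is.null(masks)) masks <- .phantom_masks(phantom)
  pitch <- phantom$msi_pitch
  inv <- affine_invert(phantom$transform)
  nr <- phantom$dim_px[1]; nc <- phantom$dim_px[2]
  corners_px <- cbind(c(0, nc, nc, 0), c(0, 0, nr, nr))
  corners_um <- affine_apply(phantom$transform, corners_px)
  ix <- max(0L, floor(min(corners_um[, 1]) / pitch)):ceiling(max(corners_um[, 1]) / pitch)
  iy <- max(0L, floor(min(corners_um[, 2]) / pitch)):ceiling(max(corners_um[, 2]) / pitch)
  off <- (seq_len(footprint_n) - 0.5) / footprint_n
  sub <- as.matrix(expand.grid(ox = off, oy = off))

  frac <- NULL
  for (sy in iy) for (sx in ix) {
    pts_um <- cbind((sx + sub[, 1]) * pitch, (sy + sub[, 2]) * pitch)
    pts_px <- affine_apply(inv, pts_um)
    i <- floor(pts_px[, 1]) + 1L; j <- floor(pts_px[, 2]) + 1L
    ok <- i >= 1L & i <= nc & j >= 1L & j <= nr
    if (!any(ok)) next
    ij <- cbind(j[ok], i[ok])
    tf <- sum(masks$tissue[ij]) / nrow(sub)
    if (tf == 0) next
    cf <- sum(masks$cell_rich[ij]) / nrow(sub)
    lf <- sum(masks$colloid[ij]) / nrow(sub)
    ctr_px <- affine_apply(inv, cbind((sx + 0.5) * pitch, (sy + 0.5) * pitch))
    ctr_um <- ctr_px * phantom$image_px_size
    dx <- NA_character_
    for (core in phantom$cores) {
      if (sum((ctr_um - core$center)^2) <= (core$radius + pitch)^2) {
        dx <- core$diagnosis; break
      }
    }
    frac <- rbind(frac, data.frame(x = sx, y = sy, cell = cf, colloid = lf,
                                   tissue = tf, diagnosis = dx))
  }
  if (is.null(frac))
    stop("no MSI spot overlaps tissue: registration/footprint mismatch between the planted transform and the phantom")

  mz <- seq(phantom$mz_range[1], phantom$mz_range[2], by = phantom$mz_step)
  nmz <- length(mz)
  sig <- model$peak_sigma
  add_peak <- function(spec, mz0, amp) {
    if (amp <= 0) return(spec)
    lo <- findInterval(mz0 - 5 * sig, mz) + 1L
    hi <- findInterval(mz0 + 5 * sig, mz)
    if (hi < lo) return(spec)
    w <- lo:hi
    spec[w] <- spec[w] + amp * exp(-(mz[w] - mz0)^2 / (2 * sig^2))
    spec
  }
  set.seed(phantom$seed + 2L)
  ints <- matrix(0, nrow(frac), nmz)
  for (k in seq_len(nrow(frac))) {
    spec <- rep(model$baseline_level, nmz)
    if (!is.na(frac$diagnosis[k]) && frac$diagnosis[k] %in% names(model$peptide_peaks)) {
      pp <- model$peptide_peaks[[frac$diagnosis[k]]]
      for (q in seq_len(nrow(pp)))
        spec <- add_peak(spec, pp$mz[q], pp$amplitude[q] * frac$cell[k])
    }
    ip <- model$interferent_peaks
    for (q in seq_len(nrow(ip)))
      spec <- add_peak(spec, ip$mz[q],
                       ip$amplitude[q] * (1 + ip$enrichment[q] * frac$colloid[k]))
    tp <- model$trypsin_peaks
    for (q in seq_len(nrow(tp)))
      spec <- add_peak(spec, tp$mz[q], tp$amplitude[q])
    sp <- model$structural_peaks
    for (q in seq_len(nrow(sp)))
      spec <- add_peak(spec, sp$mz[q], sp$amplitude[q] * frac$tissue[k])
    if (model$noise_sd > 0)
      spec <- spec + stats::rnorm(nmz, 0, model$noise_sd)
    ints[k, ] <- pmax(spec, 0)
  }
  out <- msi_dataset(frac[, c("x", "y")], mz, ints, pitch = pitch)
  attr(out, "spot_fractions") <- frac
  out
}

#' Generate and write a complete fixture to disk
#'
#' Writes the H&E PNG, imzML + ibd, training and pathologist GeoJSON, and a
#' JSON ground-truth manifest (planted transform, planted peak signatures,
#' mask areas).
#'
#' @param phantom a [fixture_phantom()].
#' @param model a [spectrum_model()].
#' @param out_dir output directory (created if needed).
#' @return invisible list of the in-memory fixture pieces (`he`, `msi`,
#'   `paths`).
#' @export
simulate_fixture <- function(phantom = fixture_phantom(),
                             model = spectrum_model(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  he <- render_he_image(phantom)
  msi <- render_msi_cube(phantom, model, he$masks)
  paths <- list(
    image = file.path(out_dir, "he.png"),
    imzml = file.path(out_dir, "msi.imzML"),
    training = file.path(out_dir, "training_annotations.geojson"),
    pathologist = file.path(out_dir, "pathologist_annotations.geojson"),
    manifest = file.path(out_dir, "ground_truth.json"))
  png::writePNG(he$rgb / 255, paths$image)
  write_imzml(msi, paths$imzml, uuid_seed = phantom$seed)
  write_geojson(he$training, paths$training)
  write_geojson(he$pathologist, paths$pathologist)
  fr <- attr(msi, "spot_fractions")
  manifest <- list(
    seed = phantom$seed,
    image_px_size = phantom$image_px_size,
    msi_pitch = phantom$msi_pitch,
    transform = list(A = phantom$transform$A, b = phantom$transform$b),
    mask_areas_um2 = lapply(he$masks, function(m) sum(m) * phantom$image_px_size^2),
    planted_discriminative_mz = planted_discriminative_mz(model),
    spot_fractions = fr)
  jsonlite::write_json(manifest, paths$manifest, digits = NA, auto_unbox = TRUE)
  invisible(list(he = he, msi = msi, phantom = phantom, model = model,
                 paths = paths))
}
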