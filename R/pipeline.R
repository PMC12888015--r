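#' End-to-end pipeline orchestration
#'
#' @name cli_pipeline
#' @keywords internal
NULL

#' Default run configuration
#'
#' All stage parameters with their standard values: feature scales
#' `sigmas = c(2, 4)` px at 0.44 um/px, minimum object/hole size 7 um^2,
#' MSI pitch 20 um, peak picking at S/N 6 and 0.3 percent relative
#' intensity, 20 ppm matching tolerance, AUC bounds 0.7/0.3, 5 PCA
#' components, tiling buffer 4 um.
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = TRUE,
    paths = list(image = NULL, imzml = NULL, training = NULL,
                 pathologist = NULL, control_points = NULL, panel = NULL),
    image_px_size = 0.44,
    msi_pitch = 20,
    sigmas = c(2, 4),
    min_object_um2 = 7, min_hole_um2 = 7,
    threshold = 0.5,
    expected_rows = 2, expected_cols = 2,
    buffer_um = 4,
    snr_min = 6, rel_int_min = 0.003,
    tol_ppm = 20,
    auc_hi = 0.7, auc_lo = 0.3,
    pca_components = 5,
    ref_mz = 1459.688,
    refine = TRUE, search_radius_um = 30, refine_step_um = 5,
    epochs = 500, learning_rate = 1)
  over <- list(...)
  for (n in names(over)) cfg[[n]] <- over[[n]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return a `run_config` with file values overriding the defaults.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Executes: (optional) fixture simulation, feature extraction, pixel
#' classifier training and prediction, detection post-processing,
#' dearraying, coregistration (control-point fit plus reference-ion
#' refinement), label transfer and tiling, ROI construction, RMS
#' normalisation, per-ROI mean spectra and peak picking, and the ROI-type
#' comparison (interferent panel, PCA, per-feature ROC). All outputs and a
#' provenance manifest are written under `out_dir`.
#'
#' @param config a [run_config()] (or YAML path).
#' @param out_dir output directory.
#' @return invisible list with the main in-memory results (`rois`,
#'   `peak_lists`, `comparison`, `summary`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  phantom <- NULL
  if (isTRUE(config$simulate)) {
    .stage_log("simulate", "generating fixture (seed %d)", config$seed)
    phantom <- fixture_phantom(n_rows = config$expected_rows,
                               n_cols = config$expected_cols,
                               image_px_size = config$image_px_size,
                               msi_pitch = config$msi_pitch,
                               seed = config$seed)
    fx <- simulate_fixture(phantom, spectrum_model(),
                           file.path(out_dir, "fixture"))
    config$paths$image <- fx$paths$image
    config$paths$imzml <- fx$paths$imzml
    config$paths$training <- fx$paths$training
    config$paths$pathologist <- fx$paths$pathologist
  }
  for (p in c("image", "imzml", "training", "pathologist")) {
    if (is.null(config$paths[[p]]))
      stop("missing required input path: paths$", p)
    if (!file.exists(config$paths[[p]]))
      stop("input does not exist: paths$", p, " = ", config$paths[[p]])
  }

  .stage_log("inputs", "reading image, imzML and annotations")
  rgb <- png::readPNG(config$paths$image) * 255
  if (length(dim(rgb)) == 3 && dim(rgb)[3] > 3) rgb <- rgb[, , 1:3]
  msi <- read_imzml(config$paths$imzml, pitch = config$msi_pitch)
  training <- read_geojson(config$paths$training, "training")
  pat <- read_geojson(config$paths$pathologist, "pathologist")

  .stage_log("features", "computing %d-scale feature stack", length(config$sigmas))
  cfg_feat <- feature_config(sigmas = config$sigmas)
  feats <- compute_features(rgb, cfg_feat, px_size = config$image_px_size)

  .stage_log("classifier", "training pixel classifier")
  model <- pixel_classifier(feats, training, seed = config$seed,
                            learning_rate = config$learning_rate,
                            epochs = config$epochs)
  .stage_log("classifier", "train accuracy %.3f", model$train_accuracy)
  prob <- predict(model, feats)
  det <- postprocess_detections(prob, config$image_px_size,
                                target_class = "cell_rich",
                                min_object_um2 = config$min_object_um2,
                                min_hole_um2 = config$min_hole_um2,
                                threshold = config$threshold)
  .stage_log("classifier", "%d detections after post-processing", nrow(det$table))

  grid <- dearray(rgb, config$expected_rows, config$expected_cols)

  .stage_log("register", "fitting and refining the coregistration")
  if (!is.null(config$paths$control_points)) {
    cp <- read_control_points(config$paths$control_points)
    t0 <- fit_affine(cp$img_px, cp$msi_um)
  } else if (!is.null(phantom)) {
    corners <- rbind(c(0, 0), c(phantom$dim_px[2], 0),
                     c(0, phantom$dim_px[1]), c(phantom$dim_px[2], phantom$dim_px[1]))
    t0 <- fit_affine(corners, affine_apply(phantom$transform, corners))
  } else stop("missing required input path: paths$control_points")
  transform <- t0
  if (isTRUE(config$refine)) {
    od <- -log10(pmax((rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3, 1) / 255)
    transform <- refine_by_ion_image(t0, od > 0.06, msi,
                                     ref_mz = config$ref_mz,
                                     tol_ppm = config$tol_ppm,
                                     search_radius_um = config$search_radius_um,
                                     step_um = config$refine_step_um)
    .stage_log("register", "refinement score %.3f", attr(transform, "score"))
  }

  .stage_log("rois", "transferring labels and building FC/PAT/PC ROI sets")
  labeled <- transfer_labels(det, pat)
  rois <- build_roi_types(grid, pat, labeled, transform, msi,
                          buffer_um = config$buffer_um)
  .stage_log("rois", "spots: FC=%d PAT=%d PC=%d",
             roi_size(rois$FC), roi_size(rois$PAT), roi_size(rois$PC))

  .stage_log("spectra", "normalising and picking peaks per ROI type")
  msin <- rms_normalize(msi)
  peak_lists <- list(); mean_spectra <- list()
  for (t in names(rois)) {
    sp <- roi_spots(rois[[t]])
    ms <- mean_spectrum(msin, sp[, c("x", "y")])
    mean_spectra[[t]] <- ms
    peak_lists[[t]] <- pick_peaks(ms$mz, ms$intensity,
                                  snr_min = config$snr_min,
                                  rel_int_min = config$rel_int_min)
  }

  .stage_log("compare", "interferent panel, PCA and ROC per ROI type")
  panel <- if (!is.null(config$paths$panel))
    read_interferent_panel(config$paths$panel, config$tol_ppm)
  else interferent_panel(tol_ppm = config$tol_ppm)
  panel_mz <- c(panel$hcca_mz, panel$trypsin_mz)
  imats <- lapply(rois, function(r)
    extract_intensity_matrix(msin, panel_mz, tol_ppm = config$tol_ppm,
                             spots = roi_spots(r)[, c("x", "y")]))
  interferents <- score_interferents(imats, panel)

  pcas <- list(); rocs <- list(); counts <- list(); fmat <- list()
  for (t in names(rois)) {
    sp <- roi_spots(rois[[t]])
    if (!nrow(peak_lists[[t]])) next
    m <- extract_intensity_matrix(msin, peak_lists[[t]]$mz,
                                  tol_ppm = config$tol_ppm,
                                  spots = sp[, c("x", "y")])
    fmat[[t]] <- list(matrix = m, labels = sp$label)
    pcas[[t]] <- tryCatch(roi_pca(m, config$pca_components),
                          error = function(e) NULL)
    rocs[[t]] <- tryCatch(
      roc_analysis(m, sp$label, auc_hi = config$auc_hi, auc_lo = config$auc_lo),
      error = function(e) NULL)
    if (!is.null(rocs[[t]])) counts[[t]] <- count_discriminatory(rocs[[t]])
  }

  summary <- list(
    seed = config$seed,
    spot_counts = vapply(rois, roi_size, 0L),
    n_peaks = vapply(peak_lists, nrow, 0L),
    interferent_percent_change = interferents$percent_change,
    discriminatory_counts = vapply(counts, function(x) x$n, 0L),
    pca_explained_variance = lapply(pcas, function(p)
      if (is.null(p)) NULL else p$explained_variance),
    classifier_train_accuracy = model$train_accuracy)

  .stage_log("write", "writing results to %s", out_dir)
  write_roi_csv(rois, file.path(out_dir, "roi_spots.csv"))
  for (t in names(peak_lists))
    utils::write.csv(peak_lists[[t]], file.path(out_dir, sprintf("peaks_%s.csv", t)),
                     row.names = FALSE)
  utils::write.csv(interferents$table, file.path(out_dir, "interferent_table.csv"),
                   row.names = FALSE)
  for (t in names(rocs)) if (!is.null(rocs[[t]]))
    utils::write.csv(rocs[[t]], file.path(out_dir, sprintf("roc_%s.csv", t)),
                     row.names = FALSE)
  write_pixel_classifier(model, file.path(out_dir, "pixel_classifier.json"))
  jsonlite::write_json(list(A = transform$A, b = transform$b),
                       file.path(out_dir, "transform.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest <- list(
    config = config[setdiff(names(config), "paths")],
    paths = config$paths,
    input_md5 = as.list(tools::md5sum(unlist(config$paths[
      !vapply(config$paths, is.null, TRUE)]))),
    summary = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)

  invisible(list(rois = rois, peak_lists = peak_lists,
                 mean_spectra = mean_spectra,
                 feature_matrices = fmat,
                 comparison = list(interferents = interferents, pca = pcas,
                                   roc = rocs, counts = counts),
                 model = model, detections = det, labeled = labeled,
                 transform = transform, grid = grid, msi = msin,
                 summary = summary))
}
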