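# Shared default fixture, built lazily once per test run.
.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    ph <- fixture_phantom(seed = 1)
    he <- render_he_image(ph)
    feats <- compute_features(he$rgb, feature_config(), px_size = ph$image_px_size)
    model <- pixel_classifier(feats, he$training, seed = 1)
    prob <- predict(model, feats)
    det <- postprocess_detections(prob, ph$image_px_size,
                                  target_class = "cell_rich")
    msi <- render_msi_cube(ph, spectrum_model(), he$masks)
    .fixture_cache$fx <- list(phantom = ph, he = he, features = feats,
                              model = model, prob = prob, detections = det,
                              msi = msi)
  }
  .fixture_cache$fx
}

# Small synthetic MSI dataset for fast I/O and normalisation tests.
small_msi <- function(seed = 7, n_spots = 6, n_mz = 400) {
  set.seed(seed)
  g <- expand.grid(x = 0:2, y = 0:1)[seq_len(n_spots), ]
  mz <- seq(700, by = 0.05, length.out = n_mz)
  ints <- matrix(abs(rnorm(n_spots * n_mz, 1, 0.3)), n_spots, n_mz)
  msi_dataset(g, mz, ints, pitch = 20)
}

# Independent point-in-polygon oracle: winding-number by signed angles.
winding_inside <- function(px, py, ring) {
  vx <- ring[, 1] - px; vy <- ring[, 2] - py
  n <- nrow(ring)
  a <- atan2(vy, vx)
  d <- diff(c(a, a[1]))
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  abs(sum(d)) > pi
}

# Random convex polygon (hull of random points), image-pixel units.
random_convex_polygon <- function(n_pts = 8, center, radius) {
  th <- sort(runif(n_pts, 0, 2 * pi))
  r <- runif(n_pts, 0.4 * radius, radius)
  pts <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  pts[chull(pts), , drop = FALSE]
}

# Synthetic single spectrum with planted Gaussian peaks on a flat baseline.
plant_spectrum <- function(mz, peaks_mz, peaks_amp, sigma = 0.06,
                           baseline = 1, noise_sd = 0.2) {
  y <- rep(baseline, length(mz))
  for (k in seq_along(peaks_mz))
    y <- y + peaks_amp[k] * exp(-0.5 * ((mz - peaks_mz[k]) / sigma)^2)
  y + rnorm(length(mz), 0, noise_sd)
}
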