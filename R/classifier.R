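#' Pixel classifier: a small multilayer perceptron over multiscale features
#'
#' With the default configuration the model is a single linear layer with
#' softmax over 16 standardized features and 2 classes -- 32 parameters,
#' bias disabled. Training is deterministic full-batch gradient descent on
#' the cross-entropy, on the pixels covered by the training annotations.
#'
#' @param features a [compute_features()] stack.
#' @param annotations an [annotation_set()] whose labels are the class
#'   names (e.g. `cell_rich` / `non_cell_rich`), one or more polygons per
#'   class.
#' @param class_order character vector fixing the class order; defaults to
#'   `c("cell_rich", "non_cell_rich")` when those are the labels present,
#'   otherwise the sorted unique labels.
#' @param bias include a bias term (default `FALSE`, keeping the parameter
#'   count at `features x classes`).
#' @param learning_rate,epochs gradient-descent hyper-parameters.
#' @param max_pixels_per_class cap on training pixels per class (sampled
#'   deterministically from `seed`).
#' @param seed integer seed controlling pixel subsampling and any weight
#'   initialisation (weights start at zero, so training is deterministic).
#' @return an object of class `pixel_classifier` with elements `weights`
#'   (F x C, plus a `bias` row when enabled), `class_order`,
#'   `standardization` (per-feature mean/sd), `feature_names`,
#'   `train_accuracy`.
#' @export
pixel_classifier <- function(features, annotations, class_order = NULL,
                             bias = FALSE, learning_rate = 1, epochs = 500,
                             max_pixels_per_class = 10000, seed = 1L) {
  stopifnot(inherits(features, "feature_stack"))
  d <- dim(features$data)
  labs <- annotation_labels(annotations)
  classes <- sort(unique(labs))
  if (length(classes) < 2)
    stop("training annotations must contain at least two classes")
  if (is.null(class_order)) {
    class_order <- if (setequal(classes, c("cell_rich", "non_cell_rich")))
      c("cell_rich", "non_cell_rich") else classes
  }
  stopifnot(setequal(class_order, classes))

  idmap <- rasterize_annotations(annotations, d[1:2])
  if (!any(idmap > 0))
    stop("annotations do not intersect the image")
  X <- matrix(features$data, ncol = d[3])
  colnames(X) <- features$feature_names
  pix <- which(idmap > 0)
  y <- labs[idmap[pix]]
  if (length(unique(y)) < 2)
    stop("annotation pixels cover a single class only")

  set.seed(seed)
  keep <- unlist(lapply(split(seq_along(pix), y), function(ii) {
    if (length(ii) > max_pixels_per_class)
      sort(sample(ii, max_pixels_per_class)) else ii
  }), use.names = FALSE)
  pix <- pix[keep]; y <- y[keep]
  Xt <- X[pix, , drop = FALSE]

  mu <- colMeans(Xt)
  sdv <- apply(Xt, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(Xt, 2, mu), 2, sdv, "/")
  if (bias) Xs <- cbind(Xs, bias = 1)
  C <- length(class_order)
  Y <- matrix(0, nrow(Xs), C)
  Y[cbind(seq_along(y), match(y, class_order))] <- 1

  W <- matrix(0, ncol(Xs), C,
              dimnames = list(colnames(Xs), class_order))
  n <- nrow(Xs)
  for (e in seq_len(epochs)) {
    Z <- Xs %*% W
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    W <- W - learning_rate * crossprod(Xs, P - Y) / n
  }
  Z <- Xs %*% W
  pred <- class_order[max.col(Z, ties.method = "first")]
  acc <- mean(pred == y)
  if (acc < 0.6)
    warning(sprintf("degenerate training: classes look inseparable (train accuracy %.2f)", acc))

  structure(list(weights = W, class_order = class_order, bias = bias,
                 standardization = list(mean = mu, sd = sdv),
                 feature_names = features$feature_names,
                 config = features$config,
                 train_accuracy = acc,
                 n_train = n, seed = seed,
                 hyper = list(learning_rate = learning_rate, epochs = epochs)),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("Pixel classifier: %d features x %d classes (%d parameters%s)\n",
              length(x$feature_names), length(x$class_order),
              length(x$weights), if (x$bias) ", incl. bias" else ", no bias"))
  cat(sprintf("  classes: %s\n  train accuracy: %.3f on %d pixels\n",
              paste(x$class_order, collapse = ", "), x$train_accuracy, x$n_train))
  invisible(x)
}

#' @export
summary.pixel_classifier <- function(object, ...) {
  print(object)
  cat("\nWeights (standardized features):\n")
  print(round(object$weights, 4))
  invisible(object)
}

#' @export
coef.pixel_classifier <- function(object, ...) object$weights

#' Per-pixel class probabilities
#'
#' @param object a [pixel_classifier()].
#' @param features a feature stack computed with the same configuration.
#' @param ... unused.
#' @return array `H x W x C` of softmax probabilities (classes in
#'   `object$class_order`), summing to 1 per pixel.
#' @export
predict.pixel_classifier <- function(object, features, ...) {
  stopifnot(inherits(features, "feature_stack"))
  if (!identical(features$feature_names, object$feature_names))
    stop("feature configuration mismatch: model has [",
         paste(object$feature_names, collapse = ", "), "], input has [",
         paste(features$feature_names, collapse = ", "), "]")
  d <- dim(features$data)
  X <- matrix(features$data, ncol = d[3])
  Xs <- sweep(sweep(X, 2, object$standardization$mean),
              2, object$standardization$sd, "/")
  if (object$bias) Xs <- cbind(Xs, 1)
  Z <- Xs %*% object$weights
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z); P <- P / rowSums(P)
  array(P, dim = c(d[1], d[2], length(object$class_order)),
        dimnames = list(NULL, NULL, object$class_order))
}

#' Serialise / restore a pixel classifier as JSON
#' @param model a `pixel_classifier`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_pixel_classifier` returns the model.
#' @export
write_pixel_classifier <- function(model, path) {
  obj <- list(weights = model$weights, class_order = model$class_order,
              bias = model$bias,
              standardization = model$standardization,
              feature_names = model$feature_names,
              train_accuracy = model$train_accuracy,
              channels = model$config$channels,
              feature_kinds = model$config$feature_kinds,
              sigmas = model$config$sigmas,
              stain_vectors = model$config$stain_vectors)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pixel_classifier
#' @export
read_pixel_classifier <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(o$weights, ncol = length(o$class_order),
              dimnames = list(NULL, o$class_order))
  fn <- o$feature_names
  rownames(W) <- if (o$bias) c(fn, "bias") else fn
  structure(list(weights = W, class_order = o$class_order, bias = o$bias,
                 standardization = list(mean = stats::setNames(o$standardization$mean, fn),
                                        sd = stats::setNames(o$standardization$sd, fn)),
                 feature_names = fn,
                 config = feature_config(o$channels, o$feature_kinds, o$sigmas,
                                         matrix(o$stain_vectors, 3, 3)),
                 train_accuracy = o$train_accuracy),
            class = "pixel_classifier")
}

#' Post-process a probability map into a detection set
#'
#' Binarises the target-class probability at a threshold, removes
#' 8-connected objects below the minimum object size, fills 4-connected
#' holes below the minimum hole size, and vectorises the surviving
#' components into polygons (holes preserved).
#'
#' @param prob_map output of [predict.pixel_classifier()] (or a probability
#'   matrix for the target class).
#' @param px_size micrometres per pixel.
#' @param target_class class to detect (default the first class).
#' @param min_object_um2,min_hole_um2 size thresholds in square micrometres
#'   (default 7).
#' @param threshold probability threshold (default 0.5).
#' @return a `detection_set`: list with `labels` (integer component raster),
#'   `table` (data.frame `id`, `class`, `area_um2`), `polygons` (pixel-unit
#'   polygons with holes), `px_size`.
#' @export
postprocess_detections <- function(prob_map, px_size,
                                   target_class = NULL,
                                   min_object_um2 = 7, min_hole_um2 = 7,
                                   threshold = 0.5) {
  p <- if (length(dim(prob_map)) == 3) {
    cls <- dimnames(prob_map)[[3]]
    k <- if (is.null(target_class)) 1L else match(target_class, cls)
    if (is.na(k)) stop("unknown target class: ", target_class)
    prob_map[, , k]
  } else prob_map
  mask <- p >= threshold
  mask <- clean_mask(mask, px_size, min_object_um2, min_hole_um2)
  labels <- label_components(mask, connectivity = 8)
  polys <- mask_to_polygons(labels, px_size = 1)
  n <- length(polys)
  cls <- if (is.null(target_class)) "detection" else target_class
  tab <- data.frame(id = if (n) vapply(polys, `[[`, 0L, "id") else integer(0),
                    class = rep(cls, n),
                    area_um2 = if (n) vapply(polys, `[[`, 0, "area") * px_size^2 else numeric(0))
  structure(list(labels = labels, table = tab, polygons = polys,
                 px_size = px_size),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("Detection set: %d objects, %.3g um/px\n", nrow(x$table), x$px_size))
  if (nrow(x$table))
    print(stats::aggregate(area_um2 ~ class, x$table,
                           function(a) c(n = length(a), total = sum(a))))
  invisible(x)
}

#' Convert a detection set to an annotation set
#' @param x a `detection_set`.
#' @return an [annotation_set()] with provenance `"detection"`.
#' @export
detections_to_annotations <- function(x) {
  polys <- lapply(seq_along(x$polygons), function(k) {
    p <- x$polygons[[k]]
    list(outer = p$outer, holes = p$holes, label = x$table$class[k])
  })
  annotation_set(polys, provenance = "detection")
}
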