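#' ROI-type comparison: interferents, PCA, ROC
#'
#' @name discriminate
#' @keywords internal
NULL

#' Default interferent panel
#'
#' Reference m/z values of the matrix-adduct (HCCA) and trypsin-autolysis
#' interferent peaks scored across ROI types. Extra values can be appended
#' through the arguments.
#'
#' @param extra_hcca,extra_trypsin optional additional m/z values.
#' @param tol_ppm matching tolerance carried with the panel (default 20).
#' @return an `interferent_panel` list with sorted `hcca_mz`, `trypsin_mz`,
#'   `tol_ppm`.
#' @export
interferent_panel <- function(extra_hcca = numeric(0),
                              extra_trypsin = numeric(0), tol_ppm = 20) {
  hcca <- sort(c(839.08, 845.09, 855.05, 861.06, 867.08,
                 1036.13, 1044.09, 1054.08, 1060.06, 1066.08, extra_hcca))
  tryp <- sort(c(842.51, 1045.56, 1220.64, extra_trypsin))
  structure(list(hcca_mz = hcca, trypsin_mz = tryp, tol_ppm = tol_ppm),
            class = "interferent_panel")
}

#' Read an interferent panel from CSV
#'
#' Expected columns `mz` and `type` (`hcca` or `trypsin`).
#' @param path CSV path.
#' @param tol_ppm tolerance to attach.
#' @return an `interferent_panel`.
#' @export
read_interferent_panel <- function(path, tol_ppm = 20) {
  d <- utils::read.csv(path)
  structure(list(hcca_mz = sort(d$mz[d$type == "hcca"]),
                 trypsin_mz = sort(d$mz[d$type == "trypsin"]),
                 tol_ppm = tol_ppm),
            class = "interferent_panel")
}

#' Score the interferent panel across ROI types
#'
#' Mean extracted intensity of each panel m/z per ROI type, scaled per m/z
#' so the maximum across ROI types is 1, plus the percent change of the
#' pixel-classifier ROI against every other type
#' (`100 * (PC - other) / other`).
#'
#' @param matrices named list of feature matrices (one per ROI type, e.g.
#'   `FC`, `PAT`, `PC`), all built from the same normalised dataset with
#'   [extract_intensity_matrix()] on the panel m/z values.
#' @param panel an [interferent_panel()].
#' @return list with `table` (data.frame: `mz`, `type`, one relative-mean
#'   column per ROI type) and `percent_change` (named vector per other ROI
#'   type, mean over panel m/z).
#' @export
score_interferents <- function(matrices, panel = interferent_panel()) {
  mzs <- as.numeric(colnames(matrices[[1]]))
  if (anyNA(mzs)) mzs <- c(panel$hcca_mz, panel$trypsin_mz)[seq_len(ncol(matrices[[1]]))]
  types <- ifelse(vapply(mzs, function(m)
    any(abs(m - panel$hcca_mz) < 0.01), logical(1)), "hcca", "trypsin")
  means <- sapply(matrices, function(m) colMeans(m))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(NULL, names(matrices)))
  scale <- apply(means, 1, max)
  rel <- sweep(means, 1, pmax(scale, .Machine$double.eps), "/")
  tab <- data.frame(mz = mzs, type = types, rel)
  others <- setdiff(colnames(means), "PC")
  pc <- means[, "PC"]
  pct <- vapply(others, function(o) {
    ok <- means[, o] > 0
    100 * mean((pc[ok] - means[ok, o]) / means[ok, o])
  }, numeric(1))
  list(table = tab, percent_change = pct)
}

#' Principal component analysis of a feature matrix
#'
#' Columns are mean-centred and scaled to unit variance (zero-variance
#' columns dropped with a warning); at most `n_components` components are
#' returned. Component signs follow the convention that the
#' largest-magnitude loading of each component is positive.
#'
#' @param x numeric matrix, spots x features.
#' @param n_components maximum number of components (default 5).
#' @return list with `scores`, `loadings`, `explained_variance`
#'   (fractions of total variance, non-increasing), `kept_columns`.
#' @export
roi_pca <- function(x, n_components = 5) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 observations")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (!ncol(x)) stop("no non-degenerate columns left for PCA")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  sc <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = sc, loadings = rot,
       explained_variance = ev[seq_len(k)],
       kept_columns = colnames(x))
}

#' Rank-sum AUC of one feature for one class pair
#'
#' Mann-Whitney formulation with midrank tie correction:
#' `AUC = (R_pos - n_pos (n_pos + 1) / 2) / (n_pos n_neg)` where `R_pos` is
#' the rank sum of the positive class in the pooled sample. Equals the
#' proportion of (pos, neg) pairs with pos > neg, ties counted one half.
#'
#' @param pos,neg numeric intensity vectors for the two classes.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (!n1 || !n2) stop("both classes must be non-empty")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Per-feature ROC analysis across class pairs
#'
#' For every feature (column) and every unordered pair of class labels, the
#' rank-sum AUC with the first label of the pair as positive class. A
#' feature is flagged discriminatory for a pair when AUC > `auc_hi` or
#' AUC < `auc_lo`. No multiple-testing adjustment is applied.
#'
#' @param x numeric matrix, spots x features (column names = m/z).
#' @param labels class label per row.
#' @param class_pairs optional list of `c(a, b)` pairs; default all
#'   unordered pairs of observed labels.
#' @param auc_hi,auc_lo discriminatory bounds (defaults 0.7 / 0.3).
#' @return a `roc_result` data.frame: `feature`, `class_a`, `class_b`,
#'   `auc`, `n_pos`, `n_neg`, `discriminatory`.
#' @export
roc_analysis <- function(x, labels, class_pairs = NULL,
                         auc_hi = 0.7, auc_lo = 0.3) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  if (is.null(class_pairs)) {
    cls <- sort(unique(labels))
    if (length(cls) < 2) stop("need at least two classes for ROC analysis")
    class_pairs <- utils::combn(cls, 2, simplify = FALSE)
  }
  out <- NULL
  for (pr in class_pairs) {
    ia <- labels == pr[1]; ib <- labels == pr[2]
    if (!any(ia) || !any(ib))
      stop(sprintf("class pair (%s, %s) has an empty class", pr[1], pr[2]))
    for (f in seq_len(ncol(x))) {
      a <- rank_auc(x[ia, f], x[ib, f])
      out <- rbind(out, data.frame(
        feature = colnames(x)[f] %||% as.character(f),
        class_a = pr[1], class_b = pr[2], auc = a,
        n_pos = sum(ia), n_neg = sum(ib),
        discriminatory = a > auc_hi | a < auc_lo))
    }
  }
  class(out) <- c("roc_result", "data.frame")
  attr(out, "bounds") <- c(lo = auc_lo, hi = auc_hi)
  out
}

#' Count discriminatory features in a ROC result
#'
#' A feature counts once when flagged discriminatory in at least one class
#' pair; the per-pair breakdown is attached.
#'
#' @param roc a [roc_analysis()] result.
#' @return list with `n` (count of distinct discriminatory features),
#'   `features` (their names) and `per_pair` (data.frame of counts).
#' @export
count_discriminatory <- function(roc) {
  stopifnot(nrow(roc) > 0)
  disc <- unique(roc$feature[roc$discriminatory])
  per_pair <- stats::aggregate(discriminatory ~ class_a + class_b, roc, sum)
  list(n = length(disc), features = disc, per_pair = per_pair)
}

#' Mean silhouette width of labelled points in a score space
#'
#' @param scores numeric matrix (e.g. PCA scores).
#' @param labels class label per row.
#' @return mean silhouette width.
#' @export
mean_silhouette <- function(scores, labels) {
  if (!requireNamespace("cluster", quietly = TRUE))
    stop("the 'cluster' package is required for silhouette widths")
  f <- as.integer(factor(labels))
  if (length(unique(f)) < 2) stop("need at least two classes")
  s <- cluster::silhouette(f, stats::dist(scores))
  mean(s[, "sil_width"])
}
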