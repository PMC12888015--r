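test_that("rank_auc matches hand-computed values with and without ties", {
  expect_equal(rank_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(rank_auc(c(1, 2), c(3, 4)), 0)
  expect_equal(rank_auc(c(1, 3), c(2, 4)), 0.25)  # only the (3,2) pair wins
  expect_equal(rank_auc(c(2, 2), c(2, 2)), 0.5)   # all ties -> 1/2
  expect_equal(rank_auc(5, c(1, 9)), 0.5)
  expect_error(rank_auc(numeric(0), 1), "non-empty")
})

test_that("roc_analysis flags features outside the AUC bounds per pair", {
  set.seed(31)
  x <- cbind(up = c(rnorm(30, 5), rnorm(30, 0)),
             flat = rnorm(60))
  labels <- rep(c("a", "b"), each = 30)
  r <- roc_analysis(x, labels)
  expect_equal(nrow(r), 2)
  up <- r[r$feature == "up", ]
  expect_gt(up$auc, 0.7); expect_true(up$discriminatory)
  flat <- r[r$feature == "flat", ]
  expect_false(flat$discriminatory)
  cnt <- count_discriminatory(r)
  expect_equal(cnt$n, 1)
  expect_equal(cnt$features, "up")
})

test_that("roc_analysis errors for degenerate class structures", {
  x <- matrix(rnorm(10), 10, 1)
  expect_error(roc_analysis(x, rep("a", 10)), "two classes")
  expect_error(roc_analysis(x, rep(c("a", "b"), each = 5),
                            class_pairs = list(c("a", "zzz"))), "empty")
})

test_that("roi_pca returns orthonormal loadings and ordered variance", {
  set.seed(32)
  x <- matrix(rnorm(200 * 8), 200, 8) %*% diag(c(4, 3, 2, 1, 1, 1, 1, 1))
  colnames(x) <- paste0("f", 1:8)
  p <- roi_pca(x, 5)
  expect_equal(ncol(p$loadings), 5)
  expect_equal(t(p$loadings) %*% p$loadings, diag(5),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_true(all(p$explained_variance > 0 & p$explained_variance <= 1))
  # sign convention: dominant loading positive
  for (j in 1:5)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("roi_pca drops constant columns with a warning", {
  x <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_warning(p <- roi_pca(x), "zero-variance")
  expect_equal(p$kept_columns, "a")
})

test_that("score_interferents reports the PC percent change per other type", {
  mz <- interferent_panel()$hcca_mz[1:3]
  mk <- function(level) {
    m <- matrix(level, 10, 3)
    colnames(m) <- format(mz)
    m
  }
  res <- score_interferents(list(FC = mk(2), PAT = mk(4), PC = mk(1)),
                            interferent_panel())
  expect_equal(unname(res$percent_change["FC"]), -50)
  expect_equal(unname(res$percent_change["PAT"]), -75)
  expect_true(all(res$table$type == "hcca"))
  expect_equal(max(res$table$PAT), 1)   # scaled so the max type is 1
})

test_that("mean_silhouette separates well-separated clusters", {
  set.seed(33)
  s <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  expect_gt(mean_silhouette(s, rep(c("a", "b"), each = 20)), 0.7)
  expect_error(mean_silhouette(s, rep("a", 40)), "two classes")
})

test_that("interferent panel CSV round trip", {
  p <- interferent_panel()
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(mz = c(p$hcca_mz, p$trypsin_mz),
                       type = rep(c("hcca", "trypsin"),
                                  c(length(p$hcca_mz), length(p$trypsin_mz)))),
            path, row.names = FALSE)
  back <- read_interferent_panel(path)
  expect_equal(back$hcca_mz, p$hcca_mz)
  expect_equal(back$trypsin_mz, p$trypsin_mz)
})
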