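test_that("concordance index handles perfect, inverted and mixed rankings", {
  expect_equal(concordanceIndex(c(1, 2, 3), c(0.1, 0.2, 0.3)), 1)
  expect_equal(concordanceIndex(c(1, 2, 3), c(0.3, 0.2, 0.1)), 0)
  expect_equal(concordanceIndex(c(1, 2, 3), c(0.2, 0.1, 0.3)), 2 / 3)
  # predicted ties score one half
  expect_equal(concordanceIndex(c(1, 2), c(0.5, 0.5)), 0.5)
  expect_error(concordanceIndex(c(1, 1), c(0.1, 0.2)), "tied")
})

test_that("concordance index agrees with the pairwise oracle and is monotone-invariant", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    y <- round(rnorm(n), 2)
    yhat <- round(rnorm(n), 2)
    ci <- concordanceIndex(y, yhat)
    expect_equal(ci, oracleCI(y, yhat), tolerance = 1e-8)
    # strictly monotone transform of predictions leaves CI unchanged
    expect_equal(concordanceIndex(y, exp(2 * yhat) + 1), ci,
                 tolerance = 1e-8)
  }
})

test_that("rm2 is 1 for a perfect fit and matches the direct formula", {
  y <- c(1, 2, 3, 4)
  expect_equal(rm2Metric(y, y), 1)
  expect_error(rm2Metric(y, rep(2, 4)), "constant")

  yhat <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(rm2Metric(y, yhat), oracleRm2(y, yhat), tolerance = 1e-10)
  set.seed(17)
  for (rep in 1:10) {
    yy <- rnorm(12, 6, 1); pp <- yy + rnorm(12, 0, 0.7)
    r <- rm2Metric(yy, pp)
    expect_equal(r, oracleRm2(yy, pp), tolerance = 1e-10)
    expect_lte(r, cor(yy, pp)^2 + 1e-12)   # rm2 never exceeds r^2
  }
})

test_that("regression metrics match brute-force sums", {
  expect_equal(unname(regressionMetrics(c(1, 2), c(1, 2))),
               c(0, 1, 1))
  expect_equal(unname(regressionMetrics(c(0, 1), c(1, 0))["mse"]), 1)
  set.seed(23)
  y <- rnorm(15); p <- rnorm(15)
  m <- regressionMetrics(y, p)
  expect_equal(unname(m["mse"]), sum((y - p)^2) / 15, tolerance = 1e-10)
  rNum <- sum((y - mean(y)) * (p - mean(p)))
  rDen <- sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2))
  expect_equal(unname(m["pearson"]), rNum / rDen, tolerance = 1e-10)
  expect_equal(unname(m["spearman"]),
               cor(rank(y), rank(p)), tolerance = 1e-10)
})

test_that("classification metrics match the pair-counting AUC oracle", {
  # perfectly separated
  m <- classificationMetrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unname(m["auc"]), 1)
  # all predicted positive, half truly positive
  m2 <- classificationMetrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6),
                              threshold = 0.5)
  expect_equal(unname(m2["precision"]), 0.5)
  expect_equal(unname(m2["recall"]), 1)

  labels <- c(1, 0, 1, 1, 0, 0)
  probs <- c(0.9, 0.6, 0.6, 0.4, 0.2, 0.4)
  m3 <- classificationMetrics(labels, probs)
  expect_equal(unname(m3["auc"]), oracleAUC(labels, probs),
               tolerance = 1e-8)
  tp <- 2; fp <- 1; fn <- 1
  expect_equal(unname(m3["precision"]), tp / (tp + fp))
  expect_equal(unname(m3["recall"]), tp / (tp + fn))
  expect_equal(unname(m3["f1"]),
               2 * (2 / 3) * (2 / 3) / (2 / 3 + 2 / 3))
  expect_error(classificationMetrics(c(1, 1), c(0.5, 0.6)), "both classes")
})

test_that("AUC agrees with an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(41)
  labels <- rbinom(30, 1, 0.4)
  probs <- runif(30)
  got <- unname(classificationMetrics(labels, probs)["auc"])
  ref <- as.numeric(suppressMessages(pROC::auc(labels, probs,
                                               direction = "<")))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("clustering metrics behave on separated and degenerate geometry", {
  set.seed(51)
  blob1 <- matrix(rnorm(20, 0, 0.05), 10, 2)
  blob2 <- matrix(rnorm(20, 10, 0.05), 10, 2)
  m <- clusteringMetrics(rbind(blob1, blob2), rep(c(0, 1), each = 10))
  expect_gt(unname(m["sc"]), 0.95)
  expect_lt(unname(m["dbi"]), 0.05)
  expect_gt(unname(m["chi"]), 1000)

  same <- matrix(1, 4, 2)
  expect_error(clusteringMetrics(same, c(0, 0, 1, 1)), "degenerate")
})

test_that("silhouette matches the hand oracle and cluster::silhouette", {
  set.seed(53)
  X <- matrix(rnorm(20), 10, 2)
  labels <- rep(c(0, 1), 5)
  sc <- unname(clusteringMetrics(X, labels)["sc"])
  expect_equal(sc, oracleSilhouette(X, labels), tolerance = 1e-10)
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(labels + 1, dist(X))
  expect_equal(sc, mean(sil[, "sil_width"]), tolerance = 1e-10)
})

test_that("Calinski-Harabasz and Davies-Bouldin match direct two-cluster formulas", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5), c(5, 6))
  labels <- rep(c("a", "b"), each = 3)
  m <- clusteringMetrics(X, labels)
  c1 <- colMeans(X[1:3, ]); c2 <- colMeans(X[4:6, ]); g <- colMeans(X)
  bss <- 3 * sum((c1 - g)^2) + 3 * sum((c2 - g)^2)
  wss <- sum(t(t(X[1:3, ]) - c1)^2) + sum(t(t(X[4:6, ]) - c2)^2)
  expect_equal(unname(m["chi"]), (bss / 1) / (wss / 4), tolerance = 1e-10)
  s1 <- mean(sqrt(rowSums(t(t(X[1:3, ]) - c1)^2)))
  s2 <- mean(sqrt(rowSums(t(t(X[4:6, ]) - c2)^2)))
  expect_equal(unname(m["dbi"]),
               (s1 + s2) / sqrt(sum((c1 - c2)^2)), tolerance = 1e-10)
})
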