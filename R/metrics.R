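# Evaluation metric suite: regression (MSE, Pearson, Spearman, concordance
# index, rm2), binary classification (AUC, precision, recall, F1) and
# clustering quality (silhouette, Calinski-Harabasz, Davies-Bouldin).

#' Concordance index
#'
#' Over all pairs with distinct true affinities, the fraction whose
#' predicted ordering matches the true ordering; predicted ties count 0.5,
#' pairs with tied true values are excluded. Invariant under strictly
#' monotone transforms of the predictions.
#'
#' @param yTrue,yPred Equal-length numeric vectors (length >= 2).
#' @return Value in `[0, 1]`.
#' @examples
#' concordanceIndex(c(1, 2, 3), c(0.2, 0.1, 0.3))  # 2/3
#' @export
concordanceIndex <- function(yTrue, yPred) {
  .checkPaired(yTrue, yPred)
  n <- length(yTrue)
  num <- 0; den <- 0
  for (i in seq_len(n - 1L)) {
    dT <- yTrue[i] - yTrue[(i + 1L):n]
    dP <- yPred[i] - yPred[(i + 1L):n]
    keep <- dT != 0
    den <- den + sum(keep)
    num <- num + sum(ifelse(dP[keep] == 0, 0.5,
                            (sign(dP[keep]) == sign(dT[keep])) * 1))
  }
  if (den == 0)
    stop("concordance index undefined: all true values tied", call. = FALSE)
  num / den
}

#' rm2 metric
#'
#' The modified squared correlation used in the affinity-prediction
#' literature: `r^2 * (1 - sqrt(|r^2 - r0^2|))`, where `r^2` is the squared
#' Pearson correlation of predictions and truth (with intercept) and
#' `r0^2` the squared correlation constrained through the origin.
#'
#' @param yTrue,yPred Equal-length numeric vectors with non-zero variance.
#' @return Real value (1 for a perfect fit).
#' @export
rm2Metric <- function(yTrue, yPred) {
  .checkPaired(yTrue, yPred)
  if (sd(yPred) == 0 || sd(yTrue) == 0)
    stop("rm2 undefined for constant input", call. = FALSE)
  r2 <- cor(yTrue, yPred)^2
  # least-squares fit through the origin: y = k * yhat
  k <- sum(yTrue * yPred) / sum(yPred^2)
  ssRes0 <- sum((yTrue - k * yPred)^2)
  ssTot <- sum((yTrue - mean(yTrue))^2)
  r02 <- 1 - ssRes0 / ssTot
  r2 * (1 - sqrt(abs(r2 - r02)))
}

#' Regression metric slice
#'
#' @param yTrue,yPred Equal-length numeric vectors.
#' @return Named vector with `mse`, `pearson`, `spearman`.
#' @export
regressionMetrics <- function(yTrue, yPred) {
  .checkPaired(yTrue, yPred)
  c(mse = mean((yTrue - yPred)^2),
    pearson = cor(yTrue, yPred),
    spearman = cor(yTrue, yPred, method = "spearman"))
}

#' Classification metric slice
#'
#' AUC via the rank (Mann-Whitney) statistic with midranks for ties;
#' precision, recall and F1 at the probability threshold.
#'
#' @param labels 0/1 vector; both classes must be present for AUC.
#' @param probs Predicted probabilities or scores.
#' @param threshold Decision threshold for precision/recall/F1.
#' @return Named vector with `auc`, `precision`, `recall`, `f1`.
#' @export
classificationMetrics <- function(labels, probs, threshold = 0.5) {
  .checkPaired(labels, probs)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(probs)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.numeric(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  c(auc = auc, precision = precision, recall = recall, f1 = f1)
}

#' Clustering quality of an embedding space
#'
#' Evaluates how well binary labels (e.g. thresholded affinity) separate in
#' a learned embedding: mean silhouette coefficient (Euclidean),
#' Calinski-Harabasz index and Davies-Bouldin index.
#'
#' @param embeddings Numeric matrix, rows = samples.
#' @param labels Vector with exactly two distinct values, each appearing at
#'   least twice.
#' @return Named vector with `sc`, `chi`, `dbi`.
#' @export
clusteringMetrics <- function(embeddings, labels) {
  if (!is.matrix(embeddings) || nrow(embeddings) != length(labels))
    stop("embeddings rows must match labels", call. = FALSE)
  lev <- unique(labels)
  if (length(lev) != 2L || any(table(labels) < 2L))
    stop("need two clusters with >= 2 points each", call. = FALSE)
  X <- embeddings
  n <- nrow(X); k <- 2L

  centers <- rbind(colMeans(X[labels == lev[1], , drop = FALSE]),
                   colMeans(X[labels == lev[2], , drop = FALSE]))
  grand <- colMeans(X)
  sizes <- c(sum(labels == lev[1]), sum(labels == lev[2]))

  # silhouette
  D <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- mean(D[i, !own])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))

  # Calinski-Harabasz
  bss <- sum(sizes * rowSums((centers -
           matrix(grand, k, ncol(X), byrow = TRUE))^2))
  wss <- sum(vapply(1:2, function(g) {
    Xi <- X[labels == lev[g], , drop = FALSE]
    sum(sweep(Xi, 2, centers[g, ])^2)
  }, numeric(1)))
  if (wss == 0)
    stop("degenerate clustering: zero within-cluster dispersion",
         call. = FALSE)
  chi <- (bss / (k - 1)) / (wss / (n - k))

  # Davies-Bouldin
  sbar <- vapply(1:2, function(g) {
    Xi <- X[labels == lev[g], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2, centers[g, ])^2)))
  }, numeric(1))
  dCenters <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  if (dCenters == 0)
    stop("degenerate clustering: coincident cluster centers", call. = FALSE)
  dbi <- (sbar[1] + sbar[2]) / dCenters  # k = 2: both clusters share R_12

  c(sc = mean(s), chi = chi, dbi = dbi)
}

.checkPaired <- function(a, b) {
  if (length(a) != length(b))
    stop("input vectors must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("need at least two observations", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("inputs must be finite", call. = FALSE)
  invisible(TRUE)
}
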