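# Shared fixtures. Molecules are parsed once per test run (the parser
# memoises per session, but the named list here keeps the tests readable).

.fixtureEnv <- new.env(parent = emptyenv())

fixtureSmiles <- c(
  ethane = "CC",
  ethanol = "CCO",
  benzene = "c1ccccc1",
  toluene = "Cc1ccccc1",
  biphenyl = "c1ccccc1-c2ccccc2",
  naphthalene = "c1ccc2ccccc2c1",
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  pyridine = "c1ccncc1",
  alanine = "C[C@H](N)C(=O)O",
  sodium = "[Na+]"
)

fixtureMols <- function() {
  if (is.null(.fixtureEnv$mols)) {
    mols <- parseSmiles(unname(fixtureSmiles))
    names(mols) <- names(fixtureSmiles)
    .fixtureEnv$mols <- mols
  }
  .fixtureEnv$mols
}

# A pool of grammar molecules, parsed once and reused by several files.
syntheticMolPool <- function(n = 200L, seed = 77L) {
  key <- sprintf("pool_%d_%d", n, seed)
  if (is.null(.fixtureEnv[[key]])) {
    smiles <- generateSyntheticMolecules(n, synthConfig(), seed = seed)
    mols <- parseSmiles(unique(smiles))
    .fixtureEnv[[key]] <- list(smiles = smiles, mols = mols)
  }
  .fixtureEnv[[key]]
}

# Small random graph for encoder oracles: adjacency + features.
randomGraph <- function(n, f, seed, edgeProb = 0.5, weighted = FALSE) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[runif(length(up)) < edgeProb]
  A[on] <- if (weighted) runif(length(on), 0.51, 1) else 1
  A <- A + t(A)
  H <- matrix(rnorm(n * f), n, f)
  list(A = A, H = H)
}

# ---- independent brute-force oracles (kept free of package internals) -----

oracleGcn <- function(A, H, W) {
  n <- nrow(A)
  At <- A + diag(n)
  D <- diag(1 / sqrt(rowSums(At)))
  Z <- D %*% At %*% D %*% H %*% W
  pmax(Z, 0)
}

# exhaustive per-node softmax(LeakyReLU(a^T [Wh_i || Wh_j])) attention
oracleGatAttention <- function(A, H, W, a, slope = 0.2, bias = NULL) {
  n <- nrow(A)
  G <- H %*% W
  fp <- ncol(G)
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- sort(unique(c(i, which(A[i, ] != 0))))
    e <- sapply(nb, function(j) {
      v <- sum(a * c(G[i, ], G[j, ])) + if (is.null(bias)) 0 else bias[i, j]
      if (v > 0) v else slope * v
    })
    ex <- exp(e - max(e))
    alpha[i, nb] <- ex / sum(ex)
  }
  alpha
}

oracleGatLayer <- function(A, H, params, slope = 0.2) {
  outs <- lapply(params$heads, function(hp) {
    al <- oracleGatAttention(A, H, hp$W, hp$a, slope)
    pmax(al %*% (H %*% hp$W), 0)
  })
  do.call(cbind, outs)
}

oracleCI <- function(y, yhat) {
  num <- 0; den <- 0
  n <- length(y)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && y[i] != y[j]) {
      den <- den + 1
      hi <- if (y[i] > y[j]) c(i, j) else c(j, i)
      d <- yhat[hi[1]] - yhat[hi[2]]
      num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
    }
  }
  num / den
}

oracleRm2 <- function(y, yhat) {
  r <- sum((y - mean(y)) * (yhat - mean(yhat))) /
    sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
  r2 <- r^2
  k <- sum(y * yhat) / sum(yhat^2)
  r02 <- 1 - sum((y - k * yhat)^2) / sum((y - mean(y))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}

oracleAUC <- function(labels, probs) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracleSilhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  mean(sapply(seq_len(nrow(X)), function(i) {
    own <- which(labels == labels[i] & seq_len(nrow(X)) != i)
    oth <- which(labels != labels[i])
    a <- mean(D[i, own]); b <- mean(D[i, oth])
    (b - a) / max(a, b)
  }))
}

# Small synthetic benchmark + trained model shared by the heavier tests.
quickTrainedModel <- function() {
  if (is.null(.fixtureEnv$quickFit)) {
    ds <- generateSyntheticBenchmark(
      synthConfig(nDrugs = 60L, nProteins = 20L, seed = 11))
    cfg <- dtaConfig(hidden = 16L, heads = 2L, fusionDim = 32L,
                     seqDim = 64L, dropout = 0.1)
    sp <- makeKfoldSplit(ds, 6, seed = 2)[[1]]
    fit <- trainModel(dtaModel(cfg, seed = 1), ds, sp, seed = 3,
                      lr = 5e-3, epochs = 30L, batchSize = 4000L,
                      patience = 30L)
    .fixtureEnv$quickFit <- list(ds = ds, split = sp, fit = fit, cfg = cfg)
  }
  .fixtureEnv$quickFit
}
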