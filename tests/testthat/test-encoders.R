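test_that("graph convolution handles degenerate graphs exactly", {
  # single node: S = 1, so output is ReLU(h W)
  A1 <- matrix(0, 1, 1)
  out <- gcnLayer(A1, matrix(c(2, -3), 1), list(W = diag(2)))
  expect_equal(out, matrix(c(2, 0), 1))

  # two isolated nodes with equal features give equal outputs
  A2 <- matrix(0, 2, 2)
  H <- rbind(c(1, -1), c(1, -1))
  W <- matrix(rnorm(4), 2, 2)
  out2 <- gcnLayer(A2, H, list(W = W))
  expect_equal(out2[1, ], out2[2, ])
})

test_that("graph convolution matches the dense renormalized-product oracle", {
  for (seed in 1:20) {
    g <- randomGraph(n = 6, f = 4, seed = seed, weighted = (seed %% 2 == 0))
    W <- matrix(rnorm(4 * 3), 4, 3)
    expect_equal(gcnLayer(g$A, g$H, list(W = W)),
                 oracleGcn(g$A, g$H, W), tolerance = 1e-6)
  }
})

test_that("attention coefficients are a valid distribution over neighbourhoods", {
  set.seed(1)
  params <- dtafuse:::newGatParams(3, 4, heads = 2)
  # single neighbour: row still sums to one
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  al <- gatAttention(A, matrix(rnorm(6), 2, 3), params)
  expect_equal(rowSums(al), c(1, 1), tolerance = 1e-12)

  # identical node features: uniform attention over neighbourhood + self
  H <- matrix(1, 4, 3)
  Afull <- matrix(1, 4, 4) - diag(4)
  alU <- gatAttention(Afull, H, params)
  expect_equal(alU, matrix(0.25, 4, 4), tolerance = 1e-12)
})

test_that("attention and layer output match the exhaustive softmax oracle", {
  for (seed in 1:20) {
    g <- randomGraph(n = 5, f = 3, seed = 100 + seed)
    params <- dtafuse:::newGatParams(3, 4, heads = 2)
    al <- gatAttention(g$A, g$H, params, head = 1)
    hp <- params$heads[[1]]
    expect_equal(al, oracleGatAttention(g$A, g$H, hp$W, hp$a),
                 tolerance = 1e-6)
    expect_equal(rowSums(al), rep(1, 5), tolerance = 1e-6)

    out <- gatLayer(g$A, g$H, params)
    expect_equal(out, oracleGatLayer(g$A, g$H, params), tolerance = 1e-6)
    expect_equal(ncol(out), 2 * 4)   # K heads concatenated
  }
})

test_that("single-head attention layer reduces to the plain weighted sum", {
  g <- randomGraph(n = 6, f = 3, seed = 7)
  params <- dtafuse:::newGatParams(3, 5, heads = 1)
  out <- gatLayer(g$A, g$H, params)
  hp <- params$heads[[1]]
  al <- gatAttention(g$A, g$H, params)
  expect_equal(out, pmax(al %*% (g$H %*% hp$W), 0), tolerance = 1e-12)
  expect_equal(ncol(out), 5)
})

test_that("edge features bias the attention logits", {
  g <- randomGraph(n = 5, f = 3, seed = 3)
  ei <- which(g$A != 0, arr.ind = TRUE)
  edgeIndex <- t(ei)
  set.seed(4)
  edgeFeatures <- matrix(rnorm(nrow(ei) * 2), ncol = 2)
  params <- dtafuse:::newGatParams(3, 4, heads = 1, fEdge = 2)
  out <- gatLayer(g$A, g$H, params, edgeIndex, edgeFeatures)
  hp <- params$heads[[1]]
  bias <- matrix(0, 5, 5)
  bias[t(edgeIndex)] <- edgeFeatures %*% hp$b
  alOracle <- oracleGatAttention(g$A, g$H, hp$W, hp$a, bias = bias)
  expect_equal(out, pmax(alOracle %*% (g$H %*% hp$W), 0), tolerance = 1e-6)
  # and differs from the unbiased layer
  noB <- params; noB$heads[[1]]$b <- NULL
  expect_false(isTRUE(all.equal(out, gatLayer(g$A, g$H, noB))))
})

test_that("max-pool readout is the column maximum and permutation-invariant", {
  expect_equal(maxPoolReadout(matrix(c(1, 5), 1)), c(1, 5))
  expect_equal(maxPoolReadout(rbind(c(1, 5), c(3, 2))), c(3, 5))
  set.seed(11)
  H <- matrix(rnorm(8 * 6), 8, 6)
  for (k in 1:10)
    expect_equal(maxPoolReadout(H[sample(8), ]), maxPoolReadout(H))
})

test_that("MLP encoder respects identity weights, eval determinism and dropout", {
  idParams <- list(list(W = diag(3), b = numeric(3)))
  x <- c(0.5, 2, 0)
  expect_equal(mlpEncode(x, idParams), x)

  set.seed(2)
  params <- dtafuse:::newMlpParams(c(4, 6, 2))
  x4 <- rnorm(4)
  e1 <- mlpEncode(x4, params, dropout = 0.5, training = FALSE)
  e2 <- mlpEncode(x4, params, dropout = 0.5, training = FALSE)
  expect_identical(e1, e2)

  # dropout p = 1 zeroes every activation
  z <- mlpEncode(abs(x4), params, dropout = 1, training = TRUE)
  expect_equal(z, c(0, 0))
})
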