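# Graph neural network building blocks: spectral graph convolution with
# renormalized adjacency, multi-head graph attention with optional
# edge-feature logit bias, max-pool readout and MLP encoders.
#
# Each block has a public functional form (documented, used directly in
# tests and oracles) and an internal .xxxForward/.xxxBackward pair that
# carries the caches needed for analytic backpropagation; the public form
# delegates to the forward pass.

# Dense (possibly weighted) adjacency from a directed edge list.
denseAdjacency <- function(edgeIndex, n, weights = NULL) {
  A <- matrix(0, n, n)
  if (NCOL(edgeIndex) > 0) {
    w <- if (is.null(weights)) 1 else weights
    A[cbind(edgeIndex[1, ], edgeIndex[2, ])] <- w
  }
  A
}

# Symmetrically renormalized adjacency with self-loops:
# S = D^{-1/2} (A + I) D^{-1/2}. Edge weights (e.g. contact probabilities)
# enter as weighted entries of A.
normalizedAdjacency <- function(A) {
  if (nrow(A) != ncol(A)) stop("adjacency must be square", call. = FALSE)
  At <- A + diag(nrow(A))
  dInv <- 1 / sqrt(rowSums(At))
  At * outer(dInv, dInv)
}

#' Graph convolution layer
#'
#' One propagation step `sigma(D^-1/2 (A + I) D^-1/2 H W)` over a weighted
#' adjacency: self-loops are added, the degree-renormalized adjacency mixes
#' neighbour features, a learnable linear map projects them, and ReLU
#' activates the result.
#'
#' @param A N x N (weighted) adjacency matrix without self-loops.
#' @param H N x F_in node feature matrix.
#' @param params List with `W` (F_in x F_out weight matrix).
#' @param activation `"relu"` (default) or `"identity"`.
#' @return N x F_out matrix of updated node features.
#' @examples
#' A <- matrix(0, 1, 1)
#' gcnLayer(A, matrix(c(2, -3), 1), list(W = diag(2)))  # ReLU([2,-3])
#' @export
gcnLayer <- function(A, H, params, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  .gcnForward(A, H, params$W, activation)$out
}

.gcnForward <- function(A, H, W, activation = "relu") {
  if (nrow(H) != nrow(A)) stop("H rows must match adjacency", call. = FALSE)
  if (ncol(H) != nrow(W)) stop("W rows must match feature width", call. = FALSE)
  S <- normalizedAdjacency(A)
  Z <- S %*% H %*% W
  out <- if (activation == "relu") relu(Z) else Z
  list(out = out, cache = list(S = S, H = H, W = W, Z = Z,
                               activation = activation))
}

.gcnBackward <- function(cache, dOut) {
  dZ <- if (cache$activation == "relu") dOut * (cache$Z > 0) else dOut
  SH <- cache$S %*% cache$H
  list(dH = t(cache$S) %*% dZ %*% t(cache$W),
       grads = list(W = t(SH) %*% dZ))
}

# ---- Graph attention -------------------------------------------------------

# GAT parameter helper: per-head list(W = F_in x F', a = 2F' vector,
# b = edge-feature projection (Fe vector) or NULL); plus heads, leakySlope.
newGatParams <- function(fIn, fOut, heads, fEdge = 0L, leakySlope = 0.2) {
  perHead <- lapply(seq_len(heads), function(k) {
    list(W = glorot(fIn, fOut),
         a = runif(2 * fOut, -0.1, 0.1),
         b = if (fEdge > 0) runif(fEdge, -0.1, 0.1) else NULL)
  })
  list(heads = perHead, leakySlope = leakySlope)
}

# Dense per-head attention forward. adjacency: N x N 0/1 (or weighted) mask;
# neighbourhoods include the node itself. edgeBias: optional N x N additive
# logit term (precomputed from edge features, zero elsewhere).
.gatHeadForward <- function(A, H, W, a, leakySlope, edgeBias = NULL,
                            activation = "relu", mask = NULL) {
  n <- nrow(A)
  G <- H %*% W                                  # N x F'
  fp <- ncol(G)
  s1 <- drop(G %*% a[seq_len(fp)])              # a^T W h_i  (source term)
  s2 <- drop(G %*% a[fp + seq_len(fp)])         # a^T W h_j  (target term)
  E <- outer(s1, s2, `+`)
  if (!is.null(edgeBias)) E <- E + edgeBias
  pre <- E
  E <- leakyRelu(E, leakySlope)
  if (is.null(mask)) mask <- (A != 0) | diag(n) > 0  # self-attention included
  En <- E
  En[!mask] <- -Inf
  Emax <- En[cbind(seq_len(n), max.col(En, ties.method = "first"))]
  ex <- exp(En - Emax)
  ex[!mask] <- 0
  alpha <- ex / rowSums(ex)
  Z <- alpha %*% G
  out <- if (activation == "relu") relu(Z) else Z
  list(out = out, alpha = alpha,
       cache = list(G = G, H = H, W = W, a = a, s1 = s1, s2 = s2,
                    pre = pre, mask = mask, alpha = alpha, Z = Z,
                    leakySlope = leakySlope, activation = activation,
                    hasEdgeBias = !is.null(edgeBias)))
}

.gatHeadBackward <- function(cache, dOut) {
  G <- cache$G; alpha <- cache$alpha; mask <- cache$mask
  fp <- ncol(G)
  dZ <- if (cache$activation == "relu") dOut * (cache$Z > 0) else dOut
  dAlpha <- dZ %*% t(G)
  dG <- t(alpha) %*% dZ
  # softmax rows: dE_ij = alpha_ij * (dAlpha_ij - sum_k alpha_ik dAlpha_ik)
  rowDot <- rowSums(alpha * dAlpha)
  dE <- alpha * (dAlpha - rowDot)
  dE[!mask] <- 0
  slope <- cache$leakySlope
  dPre <- dE * (slope + (1 - slope) * (cache$pre > 0))
  ds1 <- rowSums(dPre)
  ds2 <- colSums(dPre)
  a1 <- cache$a[seq_len(fp)]; a2 <- cache$a[fp + seq_len(fp)]
  dG <- dG + outer(ds1, a1) + outer(ds2, a2)
  da <- c(drop(t(G) %*% ds1), drop(t(G) %*% ds2))
  dH <- dG %*% t(cache$W)
  dW <- t(cache$H) %*% dG
  list(dH = dH, dW = dW, da = da, dPre = dPre)
}

#' Graph attention coefficients for one head
#'
#' Computes the full attention coefficient matrix `alpha[i, j]` of a single
#' attention head: logits `e_ij = LeakyReLU(a^T [W h_i || W h_j])` are
#' softmax-normalized over each node's neighbourhood (self included), so
#' every row sums to one over the neighbours.
#'
#' @param A N x N adjacency (non-zero = neighbour); the node itself is
#'   always part of its neighbourhood.
#' @param H N x F_in node features.
#' @param params GAT parameter list (see [gatLayer()]).
#' @param head Head index (default 1).
#' @return N x N matrix of attention coefficients; zero outside
#'   neighbourhoods, rows summing to 1.
#' @export
gatAttention <- function(A, H, params, head = 1L) {
  hp <- params$heads[[head]]
  .gatHeadForward(A, H, hp$W, hp$a, params$leakySlope)$alpha
}

#' Multi-head graph attention layer
#'
#' Per head: `h'_i = sigma(sum_j alpha_ij W h_j)` with attention
#' coefficients from [gatAttention()]; the `K` head outputs are
#' concatenated (or averaged when `combine = "mean"`, the usual choice for
#' a final layer). Edge attributes, when supplied, are linearly projected
#' per head and added to the attention logits.
#'
#' @param A N x N adjacency.
#' @param H N x F_in node features.
#' @param params Parameter list: `heads` (list of per-head `W`, `a`,
#'   optional edge projection `b`) and `leakySlope` (LeakyReLU negative
#'   slope, default 0.2).
#' @param edgeIndex,edgeFeatures Optional directed edge list (2 x E) and
#'   E x Fe feature matrix; projected into the logits via each head's `b`.
#' @param combine `"concat"` (default) or `"mean"` over heads.
#' @param activation `"relu"` or `"identity"`, applied per head.
#' @return N x (K * F') matrix (`combine = "concat"`) or N x F'
#'   (`combine = "mean"`).
#' @export
gatLayer <- function(A, H, params, edgeIndex = NULL, edgeFeatures = NULL,
                     combine = c("concat", "mean"),
                     activation = c("relu", "identity")) {
  combine <- match.arg(combine)
  activation <- match.arg(activation)
  .gatForward(A, H, params, edgeIndex, edgeFeatures, combine,
              activation)$out
}

# Precompute the N x N additive logit bias of one head from edge features.
.edgeBiasMatrix <- function(n, edgeIndex, edgeFeatures, b) {
  if (is.null(edgeIndex) || is.null(b) || NCOL(edgeIndex) == 0) return(NULL)
  Bm <- matrix(0, n, n)
  Bm[cbind(edgeIndex[1, ], edgeIndex[2, ])] <- drop(edgeFeatures %*% b)
  Bm
}

.gatForward <- function(A, H, params, edgeIndex = NULL, edgeFeatures = NULL,
                        combine = "concat", activation = "relu") {
  n <- nrow(A)
  if (nrow(H) != n) stop("H rows must match adjacency", call. = FALSE)
  heads <- params$heads
  outs <- vector("list", length(heads))
  caches <- vector("list", length(heads))
  mask <- (A != 0) | diag(n) > 0
  for (k in seq_along(heads)) {
    hp <- heads[[k]]
    bias <- .edgeBiasMatrix(n, edgeIndex, edgeFeatures, hp$b)
    fw <- .gatHeadForward(A, H, hp$W, hp$a, params$leakySlope, bias,
                          activation, mask)
    outs[[k]] <- fw$out
    fw$cache$bLen <- length(hp$b)   # for zero grads on edge-less graphs
    caches[[k]] <- fw$cache
  }
  out <- if (combine == "concat") do.call(cbind, outs)
         else Reduce(`+`, outs) / length(outs)
  list(out = out,
       cache = list(headCaches = caches, combine = combine,
                    edgeIndex = edgeIndex, edgeFeatures = edgeFeatures,
                    nHeads = length(heads), fOut = ncol(outs[[1]])))
}

.gatBackward <- function(cache, dOut) {
  K <- cache$nHeads; fp <- cache$fOut
  dH <- NULL
  grads <- vector("list", K)
  for (k in seq_len(K)) {
    dOutK <- if (cache$combine == "concat")
      dOut[, (k - 1) * fp + seq_len(fp), drop = FALSE]
    else dOut / K
    bk <- .gatHeadBackward(cache$headCaches[[k]], dOutK)
    hc <- cache$headCaches[[k]]
    db <- if (is.null(hc$bLen) || hc$bLen == 0L) NULL
          else numeric(hc$bLen)
    if (hc$hasEdgeBias) {
      ei <- cache$edgeIndex
      dBiasEdges <- bk$dPre[cbind(ei[1, ], ei[2, ])]
      db <- drop(t(cache$edgeFeatures) %*% dBiasEdges)
    }
    grads[[k]] <- list(W = bk$dW, a = bk$da, b = db)
    dH <- if (is.null(dH)) bk$dH else dH + bk$dH
  }
  # leakySlope is a fixed hyperparameter carried in the parameter list for
  # the functional API; its zero gradient keeps the structures parallel.
  list(dH = dH, grads = list(heads = grads, leakySlope = 0))
}

# ---- Readout and MLP -------------------------------------------------------

#' Max-pool graph readout
#'
#' Column-wise maximum over node embeddings: a fixed-width graph-level
#' embedding that ignores node count and ordering.
#'
#' @param H N x F node embedding matrix.
#' @return Numeric vector of length F.
#' @examples
#' maxPoolReadout(rbind(c(1, 5), c(3, 2)))  # c(3, 5)
#' @export
maxPoolReadout <- function(H) {
  if (!is.matrix(H) || nrow(H) < 1L)
    stop("'H' must be a matrix with at least one row", call. = FALSE)
  apply(H, 2, max)
}

.maxPoolForward <- function(H) {
  which <- max.col(t(H), ties.method = "first")
  list(out = H[cbind(which, seq_len(ncol(H)))],
       cache = list(argmax = which, n = nrow(H), f = ncol(H)))
}

.maxPoolBackward <- function(cache, dOut) {
  dH <- matrix(0, cache$n, cache$f)
  dH[cbind(cache$argmax, seq_len(cache$f))] <- dOut
  dH
}

# ---- MLP -------------------------------------------------------------------

newMlpParams <- function(widths) {
  lapply(seq_len(length(widths) - 1L), function(l)
    list(W = glorot(widths[l], widths[l + 1L]),
         b = numeric(widths[l + 1L])))
}

#' Multilayer perceptron encoder
#'
#' A stack of linear/ReLU/dropout blocks. The final layer is linear when
#' `linearOut = TRUE` (prediction heads) and ReLU-activated otherwise.
#' Dropout is active only in training mode; in evaluation mode the function
#' is deterministic.
#'
#' @param x Numeric vector (one sample) or matrix (rows = samples).
#' @param params List of layers, each `list(W, b)`; see `newMlpParams`.
#' @param dropout Dropout probability in `[0, 1]`.
#' @param training Logical; enables dropout.
#' @param linearOut Logical; skip the activation on the last layer.
#' @return Encoded vector/matrix.
#' @export
mlpEncode <- function(x, params, dropout = 0, training = FALSE,
                      linearOut = FALSE) {
  .mlpForward(x, params, dropout, training, linearOut)$out
}

.mlpForward <- function(x, params, dropout = 0, training = FALSE,
                        linearOut = FALSE) {
  vecIn <- is.null(dim(x))
  X <- if (vecIn) matrix(x, nrow = 1) else x
  L <- length(params)
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    W <- params[[l]]$W; b <- params[[l]]$b
    if (ncol(X) != nrow(W))
      stop("MLP input width mismatch", call. = FALSE)
    Z <- X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
    last <- (l == L)
    Aout <- if (last && linearOut) Z else relu(Z)
    mask <- NULL
    if (training && dropout > 0 && !(last && linearOut)) {
      mask <- matrix(runif(length(Aout)) >= dropout, nrow(Aout), ncol(Aout))
      Aout <- Aout * mask / max(1 - dropout, .Machine$double.eps)
    }
    caches[[l]] <- list(X = X, Z = Z, mask = mask, last = last)
    X <- Aout
  }
  out <- if (vecIn) drop(X) else X
  list(out = out, cache = list(layers = caches, dropout = dropout,
                               linearOut = linearOut, vecIn = vecIn))
}

.mlpBackward <- function(params, cache, dOut) {
  dX <- if (cache$vecIn) matrix(dOut, nrow = 1) else dOut
  L <- length(params)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    cc <- cache$layers[[l]]
    if (!is.null(cc$mask))
      dX <- dX * cc$mask / max(1 - cache$dropout, .Machine$double.eps)
    dZ <- if (cc$last && cache$linearOut) dX else dX * (cc$Z > 0)
    grads[[l]] <- list(W = t(cc$X) %*% dZ, b = colSums(dZ))
    dX <- dZ %*% t(params[[l]]$W)
  }
  list(dX = if (cache$vecIn) drop(dX) else dX, grads = grads)
}
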