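# Context-aware gated fusion of the compound and protein embeddings, and
# the affinity / interaction prediction heads.

newFusionParams <- function(width, hidden = width) {
  list(W1 = glorot(width, hidden), b1 = numeric(hidden),
       W2 = glorot(hidden, width), b2 = numeric(width))
}

#' Context-aware fusion gate
#'
#' Computes the per-coordinate mixing weight between the compound and
#' protein embeddings: a two-layer attention net
#' `attention(x) = W2 ReLU(W1 x + b1) + b2` is applied to the sum
#' `x = D_com + P_com` and squashed with a sigmoid, so every gate entry
#' lies strictly inside (0, 1).
#'
#' @param Dcom,Pcom Numeric vectors (or matrices, rows = samples) of equal
#'   width: the concatenated compound and protein view embeddings after
#'   projection to the common fusion width.
#' @param params Fusion parameters `list(W1, b1, W2, b2)`.
#' @return Gate vector/matrix with entries in (0, 1).
#' @examples
#' p <- list(W1 = matrix(0, 2, 2), b1 = c(0, 0),
#'           W2 = matrix(0, 2, 2), b2 = c(0, 0))
#' fusionGate(c(1, 2), c(3, 4), p)  # 0.5 everywhere
#' @export
fusionGate <- function(Dcom, Pcom, params) {
  .fusionGateForward(Dcom, Pcom, params)$out
}

.fusionGateForward <- function(Dcom, Pcom, params) {
  vecIn <- is.null(dim(Dcom))
  D <- if (vecIn) matrix(Dcom, nrow = 1) else Dcom
  P <- if (vecIn) matrix(Pcom, nrow = 1) else Pcom
  if (!all(dim(D) == dim(P)))
    stop("Dcom and Pcom must have equal width", call. = FALSE)
  x <- D + P
  Z1 <- x %*% params$W1 + matrix(params$b1, nrow(x), length(params$b1),
                                 byrow = TRUE)
  A1 <- relu(Z1)
  att <- A1 %*% params$W2 + matrix(params$b2, nrow(x), length(params$b2),
                                   byrow = TRUE)
  w <- sigmoid(att)
  list(out = if (vecIn) drop(w) else w,
       cache = list(x = x, Z1 = Z1, A1 = A1, w = w, vecIn = vecIn))
}

# dOut is gradient w.r.t. the gate; returns gradient w.r.t. x (= dD = dP).
.fusionGateBackward <- function(params, cache, dOut) {
  dW <- if (cache$vecIn) matrix(dOut, nrow = 1) else dOut
  dAtt <- dW * cache$w * (1 - cache$w)
  dA1 <- dAtt %*% t(params$W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  grads <- list(W1 = t(cache$x) %*% dZ1, b1 = colSums(dZ1),
                W2 = t(cache$A1) %*% dAtt, b2 = colSums(dAtt))
  dx <- dZ1 %*% t(params$W1)
  list(dx = if (cache$vecIn) drop(dx) else dx, grads = grads)
}

#' Fuse compound and protein embeddings
#'
#' Per-coordinate convex combination
#' `embedding = D_com * weight + P_com * (1 - weight)`: the gate decides,
#' coordinate by coordinate, how much of the compound versus the protein
#' context enters the fused representation.
#'
#' @param Dcom,Pcom Equal-width vectors or matrices.
#' @param weight Gate from [fusionGate()], entries in (0, 1).
#' @return Fused embedding of the same width.
#' @examples
#' fuseViews(c(0, 4), c(2, 0), c(0.5, 0.5))  # c(1, 2)
#' @export
fuseViews <- function(Dcom, Pcom, weight) {
  if (length(Dcom) != length(Pcom) || length(Dcom) != length(weight))
    stop("Dcom, Pcom and weight must have equal width", call. = FALSE)
  Dcom * weight + Pcom * (1 - weight)
}

#' Affinity prediction head
#'
#' Multilayer perceptron with ReLU activations and dropout on the fused
#' embedding; the output layer is linear (unbounded real affinity).
#'
#' @param embedding Fused embedding vector or matrix (rows = samples).
#' @param params MLP head parameters (list of `list(W, b)` layers).
#' @param dropout Dropout probability, active only when `training = TRUE`.
#' @param training Logical.
#' @return Predicted affinity (scalar or vector).
#' @export
predictAffinity <- function(embedding, params, dropout = 0,
                            training = FALSE) {
  out <- mlpEncode(embedding, params, dropout, training, linearOut = TRUE)
  if (is.null(dim(out))) unname(out) else drop(out)
}

#' Interaction probability head
#'
#' Same head as [predictAffinity()] with a terminal sigmoid, for binary
#' drug-protein interaction: the logit equals the affinity head's
#' pre-activation under shared weights.
#'
#' @inheritParams predictAffinity
#' @return Probability in (0, 1).
#' @export
predictInteraction <- function(embedding, params, dropout = 0,
                               training = FALSE) {
  sigmoid(predictAffinity(embedding, params, dropout, training))
}
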