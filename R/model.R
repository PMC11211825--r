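# The multi-view affinity model: two compound graph views (atom-bond,
# pharmacophore) encoded by multi-head GAT stacks, a contact-graph protein
# view encoded by GCN->GCN->GAT (contact probabilities weight the GCN
# adjacency and bias the GAT logits), an MLP branch on the pooled sequence
# embedding, linear projections to a common fusion width, sigmoid-gated
# fusion and an MLP prediction head.

#' Model configuration
#'
#' Architecture, ablation and training settings with documented defaults.
#' The three ablation switches reproduce the standard configuration ladder:
#' `usePharm = FALSE, useProviders = FALSE, fusion = "concat"` is the plain
#' atom-bond + contact-graph baseline; enabling `usePharm`, then
#' `useProviders`, then `fusion = "gated"` adds the pharmacophore view, the
#' pre-trained-embedding pathway and the context-aware fusion in turn.
#'
#' @param task `"dta"` (real-valued affinity, squared-error loss) or
#'   `"dpi"` (binary interaction, cross-entropy loss).
#' @param hidden Node-embedding width of every graph encoder (after head
#'   concatenation); must be divisible by `heads`. Default 256.
#' @param heads Attention heads per GAT layer; hidden layers concatenate
#'   heads, the final layer concatenates too unless
#'   `finalCombine = "mean"`. Default 4.
#' @param nLayersCompound GAT depth of each compound view. Default 3.
#' @param nLayersProteinGcn Number of GCN layers before the protein GAT
#'   layer. Default 2.
#' @param fusionDim Common width both concatenated embeddings are projected
#'   to before fusion. Default 256.
#' @param dropout Dropout probability in the MLP branches and head.
#' @param leakySlope LeakyReLU negative slope in attention logits.
#' @param usePharm Include the pharmacophore view.
#' @param useProviders Use embedding providers (atom embeddings as node
#'   features and the pooled-sequence MLP branch); otherwise handcrafted
#'   atom descriptors are used and the sequence branch is dropped.
#' @param fusion `"gated"` (context-aware gate) or `"concat"` (plain
#'   concatenation baseline).
#' @param finalCombine Head combination on the last GAT layer: `"concat"`
#'   or `"mean"`.
#' @param drugOnly Ignore the protein side entirely (diagnostic ablation).
#' @param atomDim,pharmDim,residueDim,seqDim Input feature widths; filled
#'   in automatically from the featurizers/providers in use.
#' @param lr,epochs,batchSize,patience,valFrac Training defaults:
#'   learning rate 5e-4, at most 500 epochs, batch 128, early-stopping
#'   patience 50, 1/6 of the training records carved out for validation.
#' @return Named list of settings.
#' @export
dtaConfig <- function(task = c("dta", "dpi"),
                      hidden = 256L, heads = 4L,
                      nLayersCompound = 3L, nLayersProteinGcn = 2L,
                      fusionDim = 256L, dropout = 0.2, leakySlope = 0.2,
                      usePharm = TRUE, useProviders = TRUE,
                      fusion = c("gated", "concat"),
                      finalCombine = c("concat", "mean"),
                      drugOnly = FALSE,
                      atomDim = NULL, pharmDim = NULL,
                      residueDim = NULL, seqDim = 1280L,
                      lr = 5e-4, epochs = 500L, batchSize = 128L,
                      patience = 50L, valFrac = 1 / 6) {
  task <- match.arg(task)
  fusion <- match.arg(fusion)
  finalCombine <- match.arg(finalCombine)
  if (hidden %% heads != 0)
    stop("'hidden' must be divisible by 'heads'", call. = FALSE)
  list(task = task, hidden = as.integer(hidden), heads = as.integer(heads),
       nLayersCompound = as.integer(nLayersCompound),
       nLayersProteinGcn = as.integer(nLayersProteinGcn),
       fusionDim = as.integer(fusionDim), dropout = dropout,
       leakySlope = leakySlope, usePharm = usePharm,
       useProviders = useProviders, fusion = fusion,
       finalCombine = finalCombine, drugOnly = drugOnly,
       atomDim = atomDim, pharmDim = pharmDim, residueDim = residueDim,
       seqDim = as.integer(seqDim),
       lr = lr, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), patience = as.integer(patience),
       valFrac = valFrac)
}

.pharmFeatureWidth <- function() {
  mol <- .dummyMolecule()
  length(featurizePharmNode(decomposePharmUnits(mol)[[1]], mol))
}

.edgeFeatureWidth <- function()
  length(.BOND_TYPES) + length(.BOND_STEREO) + 1L

# One GAT stack: depth layers, hidden width (concat over heads), final
# layer combined per finalCombine.
.newGatStack <- function(fIn, cfg, depth, fEdge = 0L) {
  perHead <- cfg$hidden %/% cfg$heads
  lapply(seq_len(depth), function(l) {
    inW <- if (l == 1) fIn else cfg$hidden
    outW <- if (l == depth && cfg$finalCombine == "mean") cfg$hidden
            else perHead
    newGatParams(inW, outW, cfg$heads, fEdge, cfg$leakySlope)
  })
}

#' Create an affinity model
#'
#' Initializes all weights (Glorot-uniform) for the configuration; the
#' returned model predicts immediately (untrained) and is trained with
#' [trainModel()].
#'
#' @param config Configuration from [dtaConfig()].
#' @param seed Integer seed for weight initialization.
#' @return A [DTAModel-class].
#' @export
dtaModel <- function(config = dtaConfig(), seed = 1L) {
  cfg <- config
  if (is.null(cfg$atomDim))
    cfg$atomDim <- if (cfg$useProviders) 32L
                   else descriptorAtomProvider()$dim
  if (is.null(cfg$pharmDim)) cfg$pharmDim <- .pharmFeatureWidth()
  if (is.null(cfg$residueDim))
    cfg$residueDim <- ncol(residueDescriptor("A"))

  params <- withSeed(seed, {
    p <- list()
    p$drugStruct <- .newGatStack(cfg$atomDim, cfg, cfg$nLayersCompound,
                                 fEdge = .edgeFeatureWidth())
    if (cfg$usePharm)
      p$drugPharm <- .newGatStack(cfg$pharmDim, cfg, cfg$nLayersCompound)
    p$protGcn <- lapply(seq_len(cfg$nLayersProteinGcn), function(l) {
      inW <- if (l == 1) cfg$residueDim else cfg$hidden
      list(W = glorot(inW, cfg$hidden))
    })
    p$protGat <- .newGatStack(cfg$hidden, cfg, 1L, fEdge = 1L)
    if (cfg$useProviders && !cfg$drugOnly)
      p$seqMlp <- newMlpParams(c(cfg$seqDim, cfg$hidden, cfg$hidden))
    dcomW <- cfg$hidden * (1L + cfg$usePharm)
    pcomW <- cfg$hidden * (1L + (cfg$useProviders && !cfg$drugOnly))
    p$projD <- list(W = glorot(dcomW, cfg$fusionDim),
                    b = numeric(cfg$fusionDim))
    if (!cfg$drugOnly)
      p$projP <- list(W = glorot(pcomW, cfg$fusionDim),
                      b = numeric(cfg$fusionDim))
    if (cfg$fusion == "gated" && !cfg$drugOnly)
      p$gate <- newFusionParams(cfg$fusionDim)
    headIn <- if (cfg$drugOnly) cfg$fusionDim
              else if (cfg$fusion == "gated") cfg$fusionDim
              else 2L * cfg$fusionDim
    p$head <- newMlpParams(c(headIn, cfg$fusionDim,
                             max(cfg$fusionDim %/% 2L, 4L), 1L))
    p
  })
  new("DTAModel", config = cfg, params = params)
}

# ---- featurization ---------------------------------------------------------

#' Featurize compounds for a model
#'
#' Parses SMILES and builds both graph views with node features matching
#' the model's configuration (provider embeddings or handcrafted
#' descriptors).
#'
#' @param smiles Character vector of SMILES.
#' @param config Model configuration (decides the atom feature source).
#' @param atomProvider Provider used when `config$useProviders`; default
#'   the deterministic fallback.
#' @return List of [MolGraphPair-class], one per compound.
#' @export
featurizeDrugs <- function(smiles, config = dtaConfig(),
                           atomProvider = NULL) {
  mols <- parseSmiles(smiles)
  provider <- if (config$useProviders) {
    if (is.null(atomProvider)) fallbackAtomProvider(config$atomDim %||% 32L)
    else atomProvider
  } else NULL
  lapply(mols, buildMolGraphPair, provider = provider)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Featurize proteins for a model
#'
#' Builds the weighted residue contact graph of every sequence and, when
#' the provider pathway is enabled, the pooled sequence-level embedding.
#' Contact probabilities come from the protein provider (deterministic
#' fallback by default) or can be supplied directly.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param config Model configuration.
#' @param proteinProvider Provider producing residue embeddings and contact
#'   probabilities; default the deterministic fallback sized to
#'   `config$seqDim`.
#' @param contacts Optional list of precomputed L x L contact matrices
#'   (overrides the provider's).
#' @return `list(graphs = list of ResidueContactGraph, seqEmb = matrix or
#'   NULL)`.
#' @export
featurizeProteins <- function(sequences, config = dtaConfig(),
                              proteinProvider = NULL, contacts = NULL) {
  useSeq <- config$useProviders && !config$drugOnly
  if (is.null(proteinProvider))
    proteinProvider <- fallbackProteinProvider(config$seqDim)
  graphs <- vector("list", length(sequences))
  seqEmb <- if (useSeq) matrix(0, length(sequences), proteinProvider$dim)
            else NULL
  for (i in seq_along(sequences)) {
    if (!is.null(contacts) && is.null(seqEmb)) {
      cm <- contacts[[i]]
    } else {
      pe <- proteinProvider$embed(sequences[i])
      cm <- if (!is.null(contacts)) contacts[[i]] else pe$contacts
      if (useSeq) seqEmb[i, ] <- poolSequenceEmbedding(pe$embeddings)
    }
    graphs[[i]] <- buildContactGraph(sequences[i], cm)
  }
  list(graphs = graphs, seqEmb = seqEmb)
}

# ---- entity encoders -------------------------------------------------------

.gatStackForward <- function(stack, A, H, cfg, edgeIndex = NULL,
                             edgeFeatures = NULL) {
  depth <- length(stack)
  caches <- vector("list", depth)
  for (l in seq_len(depth)) {
    combine <- if (l == depth) cfg$finalCombine else "concat"
    fw <- .gatForward(A, H, stack[[l]], edgeIndex, edgeFeatures, combine)
    caches[[l]] <- fw$cache
    H <- fw$out
  }
  pool <- .maxPoolForward(H)
  list(emb = pool$out, nodeAct = H,
       cache = list(layers = caches, pool = pool$cache))
}

.gatStackBackward <- function(stack, cache, dEmb, dNodeAct = NULL) {
  dH <- .maxPoolBackward(cache$pool, dEmb)
  if (!is.null(dNodeAct)) dH <- dH + dNodeAct
  grads <- vector("list", length(stack))
  for (l in rev(seq_along(stack))) {
    bk <- .gatBackward(cache$layers[[l]], dH)
    grads[[l]] <- bk$grads
    dH <- bk$dH
  }
  list(grads = grads, dH = dH)
}

.encodeDrugForward <- function(params, cfg, pair) {
  ab <- pair@atomBond
  nA <- nrow(ab@nodeFeatures)
  Aab <- denseAdjacency(ab@edgeIndex, nA)
  fwS <- .gatStackForward(params$drugStruct, Aab, ab@nodeFeatures, cfg,
                          ab@edgeIndex, ab@edgeFeatures)
  out <- list(Dstruct = fwS$emb, structCache = fwS$cache,
              structNodeAct = fwS$nodeAct)
  if (cfg$usePharm) {
    ph <- pair@pharm
    Aph <- denseAdjacency(ph@edgeIndex, nrow(ph@nodeFeatures))
    fwP <- .gatStackForward(params$drugPharm, Aph, ph@nodeFeatures, cfg)
    out$Dpharma <- fwP$emb
    out$pharmCache <- fwP$cache
  }
  out
}

.encodeDrugBackward <- function(params, cfg, cache, dDstruct, dDpharma,
                                dStructNodeAct = NULL) {
  gS <- .gatStackBackward(params$drugStruct, cache$structCache, dDstruct,
                          dStructNodeAct)
  grads <- list(drugStruct = gS$grads)
  if (cfg$usePharm) {
    gP <- .gatStackBackward(params$drugPharm, cache$pharmCache, dDpharma)
    grads$drugPharm <- gP$grads
  }
  grads
}

.encodeProtForward <- function(params, cfg, graph) {
  L <- nrow(graph@nodeFeatures)
  A <- denseAdjacency(graph@edgeIndex, L, graph@edgeWeights)
  H <- graph@nodeFeatures
  gcnCaches <- vector("list", length(params$protGcn))
  for (l in seq_along(params$protGcn)) {
    fw <- .gcnForward(A, H, params$protGcn[[l]]$W)
    gcnCaches[[l]] <- fw$cache
    H <- fw$out
  }
  ew <- if (length(graph@edgeWeights))
    matrix(graph@edgeWeights, ncol = 1) else NULL
  fwG <- .gatStackForward(params$protGat, A, H, cfg, graph@edgeIndex, ew)
  list(Pstruct = fwG$emb,
       cache = list(gcn = gcnCaches, gat = fwG$cache))
}

.encodeProtBackward <- function(params, cfg, cache, dPstruct) {
  gG <- .gatStackBackward(params$protGat, cache$gat, dPstruct)
  dH <- gG$dH
  gcnGrads <- vector("list", length(params$protGcn))
  for (l in rev(seq_along(params$protGcn))) {
    bk <- .gcnBackward(cache$gcn[[l]], dH)
    gcnGrads[[l]] <- list(W = bk$grads$W)
    dH <- bk$dH
  }
  list(protGcn = gcnGrads, protGat = gG$grads)
}

# ---- batched pair forward / backward --------------------------------------

# drugFeats: list of MolGraphPair; protFeats: list(graphs, seqEmb);
# pairs: data.frame(drugIdx, protIdx). Entities are encoded once, then the
# fusion/head runs vectorized over the pair rows.
.modelForward <- function(params, cfg, drugFeats, protFeats, pairs,
                          training = FALSE, needCache = FALSE) {
  nD <- length(drugFeats)
  drugCaches <- if (needCache) vector("list", nD)
  Dcom <- matrix(0, nD, cfg$hidden * (1L + cfg$usePharm))
  for (d in seq_len(nD)) {
    fw <- .encodeDrugForward(params, cfg, drugFeats[[d]])
    Dcom[d, ] <- c(fw$Dstruct, if (cfg$usePharm) fw$Dpharma)
    if (needCache) drugCaches[[d]] <- fw
  }
  Dp <- Dcom %*% params$projD$W +
    matrix(params$projD$b, nD, cfg$fusionDim, byrow = TRUE)

  protSide <- !cfg$drugOnly
  if (protSide) {
    nP <- length(protFeats$graphs)
    protCaches <- if (needCache) vector("list", nP)
    useSeq <- cfg$useProviders
    Pcom <- matrix(0, nP, cfg$hidden * (1L + useSeq))
    seqCache <- NULL
    if (useSeq) {
      fwSeq <- .mlpForward(protFeats$seqEmb, params$seqMlp, cfg$dropout,
                           training)
      seqOut <- fwSeq$out
      seqCache <- fwSeq$cache
    }
    for (p in seq_len(nP)) {
      fw <- .encodeProtForward(params, cfg, protFeats$graphs[[p]])
      Pcom[p, ] <- c(fw$Pstruct, if (useSeq) seqOut[p, ])
      if (needCache) protCaches[[p]] <- fw
    }
    Pp <- Pcom %*% params$projP$W +
      matrix(params$projP$b, nP, cfg$fusionDim, byrow = TRUE)
  }

  di <- pairs$drugIdx; pi <- pairs$protIdx
  Dr <- Dp[di, , drop = FALSE]
  if (protSide) Pr <- Pp[pi, , drop = FALSE]

  gateCache <- NULL
  if (cfg$drugOnly) {
    emb <- Dr
  } else if (cfg$fusion == "gated") {
    gw <- .fusionGateForward(Dr, Pr, params$gate)
    gateCache <- gw$cache
    W <- gw$out
    emb <- Dr * W + Pr * (1 - W)
  } else {
    emb <- cbind(Dr, Pr)
  }
  headFw <- .mlpForward(emb, params$head, cfg$dropout, training,
                        linearOut = TRUE)
  yhat <- drop(headFw$out)
  list(yhat = yhat, embedding = emb,
       cache = if (needCache) list(
         Dcom = Dcom, Dp = Dp, drugCaches = drugCaches,
         Pcom = if (protSide) Pcom, Pp = if (protSide) Pp,
         protCaches = if (protSide) protCaches,
         seqCache = if (protSide) seqCache,
         gateCache = gateCache, gateW = if (!is.null(gateCache)) W,
         Dr = Dr, Pr = if (protSide) Pr,
         headCache = headFw$cache, pairs = pairs,
         nD = nD, nP = if (protSide) nP))
}

# dYhat: gradient of the loss w.r.t. yhat (length = pair count).
# Returns grads structured like params. keepNodeGrads: also return
# d(output)/d(final atom-bond node activations) per drug (for Grad-AAM).
.modelBackward <- function(params, cfg, fwCache, dYhat) {
  cc <- fwCache
  headBk <- .mlpBackward(params$head, cc$headCache,
                         matrix(dYhat, ncol = 1))
  dEmb <- headBk$dX
  grads <- list(head = headBk$grads)

  protSide <- !cfg$drugOnly
  if (cfg$drugOnly) {
    dDr <- dEmb
  } else if (cfg$fusion == "gated") {
    W <- cc$gateW
    dDr <- dEmb * W
    dPr <- dEmb * (1 - W)
    dGate <- dEmb * (cc$Dr - cc$Pr)
    gateBk <- .fusionGateBackward(params$gate, cc$gateCache, dGate)
    grads$gate <- gateBk$grads
    dDr <- dDr + gateBk$dx
    dPr <- dPr + gateBk$dx
  } else {
    f <- cfg$fusionDim
    dDr <- dEmb[, seq_len(f), drop = FALSE]
    dPr <- dEmb[, f + seq_len(f), drop = FALSE]
  }

  di <- cc$pairs$drugIdx
  dDp <- rowsum(dDr, di)
  dDpFull <- matrix(0, cc$nD, cfg$fusionDim)
  dDpFull[as.integer(rownames(dDp)), ] <- dDp
  grads$projD <- list(W = t(cc$Dcom) %*% dDpFull, b = colSums(dDpFull))
  dDcom <- dDpFull %*% t(params$projD$W)

  h <- cfg$hidden
  drugGrads <- NULL
  for (d in seq_len(cc$nD)) {
    dDstruct <- dDcom[d, seq_len(h)]
    dDpharma <- if (cfg$usePharm) dDcom[d, h + seq_len(h)]
    g <- .encodeDrugBackward(params, cfg, cc$drugCaches[[d]],
                             dDstruct, dDpharma)
    drugGrads <- if (is.null(drugGrads)) g
                 else .mapLeaves(`+`, drugGrads, g)
  }
  grads$drugStruct <- drugGrads$drugStruct
  if (cfg$usePharm) grads$drugPharm <- drugGrads$drugPharm

  if (protSide) {
    pi <- cc$pairs$protIdx
    dPp <- rowsum(dPr, pi)
    dPpFull <- matrix(0, cc$nP, cfg$fusionDim)
    dPpFull[as.integer(rownames(dPp)), ] <- dPp
    grads$projP <- list(W = t(cc$Pcom) %*% dPpFull, b = colSums(dPpFull))
    dPcom <- dPpFull %*% t(params$projP$W)

    protGrads <- NULL
    for (p in seq_len(cc$nP)) {
      g <- .encodeProtBackward(params, cfg, cc$protCaches[[p]]$cache,
                               dPcom[p, seq_len(h)])
      protGrads <- if (is.null(protGrads)) g
                   else .mapLeaves(`+`, protGrads, g)
    }
    grads$protGcn <- protGrads$protGcn
    grads$protGat <- protGrads$protGat

    if (cfg$useProviders) {
      dSeqOut <- dPcom[, h + seq_len(h), drop = FALSE]
      seqBk <- .mlpBackward(params$seqMlp, cc$seqCache, dSeqOut)
      grads$seqMlp <- seqBk$grads
    }
  }
  grads[names(params)]  # same leaf order as the parameter structure
}

# ---- prediction API --------------------------------------------------------

#' Predict affinities or interaction probabilities for pairs
#'
#' Runs the full forward pass in evaluation mode (dropout off,
#' deterministic).
#'
#' @param model A [DTAModel-class].
#' @param drugFeats List of [MolGraphPair-class] from [featurizeDrugs()].
#' @param protFeats Protein features from [featurizeProteins()].
#' @param pairs `data.frame` with columns `drugIdx`, `protIdx` (1-based
#'   indices into the feature lists). Default: all-vs-all.
#' @param returnEmbedding Also return the fused (penultimate-layer input)
#'   embeddings.
#' @return Numeric vector of predictions (affinity for a `"dta"` model,
#'   interaction probability for `"dpi"`); or a list with `pred` and
#'   `embedding` when `returnEmbedding = TRUE`.
#' @export
predictPairs <- function(model, drugFeats, protFeats, pairs = NULL,
                         returnEmbedding = FALSE) {
  cfg <- model@config
  if (is.null(pairs)) {
    nP <- if (cfg$drugOnly) 1L else length(protFeats$graphs)
    pairs <- expand.grid(drugIdx = seq_along(drugFeats),
                         protIdx = seq_len(nP))
  }
  fw <- .modelForward(model@params, cfg, drugFeats, protFeats, pairs,
                      training = FALSE, needCache = FALSE)
  pred <- if (cfg$task == "dpi") sigmoid(fw$yhat) else fw$yhat
  if (returnEmbedding) list(pred = pred, embedding = fw$embedding)
  else pred
}

#' Gradient-weighted atom attribution map
#'
#' Attributes one prediction to the atoms of the compound: the gradient of
#' the model output with respect to the final atom-bond GAT node
#' activations is channel-averaged into weights, the weighted activations
#' are summed per atom, ReLU-clipped and max-normalized to `[0, 1]`.
#'
#' @param model A [DTAModel-class].
#' @param drugFeat A single [MolGraphPair-class].
#' @param protFeats Protein features from [featurizeProteins()] holding the
#'   one target of interest.
#' @param protIdx Index of the target within `protFeats`.
#' @param view Attribution view; only `"atom_bond"` carries per-atom
#'   gradients.
#' @return Numeric vector of per-atom scores in `[0, 1]` (maximum exactly 1
#'   unless all scores degenerate to 0).
#' @export
gradAAM <- function(model, drugFeat, protFeats, protIdx = 1L,
                    view = "atom_bond") {
  if (!identical(view, "atom_bond"))
    stop("attribution is only supported for the 'atom_bond' view ",
         "(other inputs carry no per-atom gradients)", call. = FALSE)
  cfg <- model@config
  pairs <- data.frame(drugIdx = 1L, protIdx = as.integer(protIdx))
  fw <- .modelForward(model@params, cfg, list(drugFeat), protFeats, pairs,
                      training = FALSE, needCache = TRUE)
  dNode <- .nodeGradAtomBond(model@params, cfg, fw$cache)
  Hlast <- fw$cache$drugCaches[[1]]$structNodeAct
  w <- colMeans(dNode)
  scores <- relu(drop(Hlast %*% w))
  m <- max(scores)
  if (m > 0) scores <- scores / m
  unname(scores)
}

# Gradient of the scalar output w.r.t. the final atom-bond GAT node
# activations of drug 1 in the cached forward pass.
.nodeGradAtomBond <- function(params, cfg, cc) {
  headBk <- .mlpBackward(params$head, cc$headCache, matrix(1, 1, 1))
  dEmb <- headBk$dX
  if (cfg$drugOnly) {
    dDr <- dEmb
  } else if (cfg$fusion == "gated") {
    W <- cc$gateW
    dGate <- dEmb * (cc$Dr - cc$Pr)
    gateBk <- .fusionGateBackward(params$gate, cc$gateCache, dGate)
    dDr <- dEmb * W + gateBk$dx
  } else {
    dDr <- dEmb[, seq_len(cfg$fusionDim), drop = FALSE]
  }
  dDcom <- dDr %*% t(params$projD$W)
  dDstruct <- dDcom[1, seq_len(cfg$hidden)]
  .maxPoolBackward(cc$drugCaches[[1]]$structCache$pool, dDstruct)
}

#' Screen a compound library against one target
#'
#' Featurizes a SMILES library, predicts the affinity of every compound for
#' the given protein and returns the library ranked by descending predicted
#' affinity.
#'
#' @param model A trained [DTAModel-class].
#' @param smiles Character vector: the screening library.
#' @param sequence Target amino-acid sequence.
#' @param atomProvider,proteinProvider Optional providers (defaults as in
#'   the featurizers).
#' @return `data.frame` with columns `rank`, `smiles`, `score`, sorted by
#'   decreasing score.
#' @export
screenLibrary <- function(model, smiles, sequence, atomProvider = NULL,
                          proteinProvider = NULL) {
  cfg <- model@config
  drugs <- featurizeDrugs(smiles, cfg, atomProvider)
  prot <- featurizeProteins(sequence, cfg, proteinProvider)
  pred <- predictPairs(model, drugs, prot,
                       data.frame(drugIdx = seq_along(drugs), protIdx = 1L))
  ord <- order(pred, decreasing = TRUE)
  data.frame(rank = seq_along(smiles), smiles = smiles[ord],
             score = pred[ord], row.names = NULL)
}

# ---- parameter-structure helpers ------------------------------------------

# Apply f leaf-wise over parallel nested lists of numerics.
.mapLeaves <- function(f, ...) {
  args <- list(...)
  a <- args[[1]]
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a))   # out[i] <- list(...) keeps NULL leaves in place
      out[i] <- list(do.call(.mapLeaves, c(list(f), lapply(args, `[[`, i))))
    out
  } else if (is.null(a) || length(a) == 0L) {
    a
  } else {
    do.call(f, args)
  }
}

.flattenParams <- function(p) unlist(p, use.names = FALSE)

.unflattenParams <- function(template, flat) {
  i <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    if (is.null(x) || length(x) == 0L) return(x)
    vals <- flat[i + seq_along(x)]
    i <<- i + length(x)
    if (is.matrix(x)) matrix(vals, nrow(x), ncol(x)) else vals
  }
  rec(template)
}
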