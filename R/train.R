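# Training loop: minibatch Adam on squared-error (DTA) or cross-entropy
# (DPI) loss, with optional validation-based early stopping. Entities are
# encoded once per batch they appear in; the fusion and head run vectorized
# over the batch rows.

.adamInit <- function(params)
  list(m = .mapLeaves(function(x) x * 0, params),
       v = .mapLeaves(function(x) x * 0, params),
       t = 0L)

.adamStep <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .mapLeaves(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .mapLeaves(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- .mapLeaves(function(p, m, v)
    p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

# Loss and its gradient w.r.t. the raw head output.
.lossAndGrad <- function(task, yhat, y) {
  n <- length(y)
  if (task == "dta") {
    r <- yhat - y
    list(loss = mean(r^2), dYhat = 2 * r / n)
  } else {
    # numerically stable binary cross-entropy on logits
    z <- yhat
    loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
    list(loss = loss, dYhat = (sigmoid(z) - y) / n)
  }
}

# Map dataset records to entity indices for the featurized lists.
.recordPairs <- function(dataset, idx) {
  r <- dataset@records[idx, , drop = FALSE]
  data.frame(drugIdx = match(r$drug_id, names(dataset@ligands)),
             protIdx = match(r$target_id, names(dataset@proteins)),
             y = r$affinity)
}

.evalLoss <- function(params, cfg, drugFeats, protFeats, pairs) {
  fw <- .modelForward(params, cfg, drugFeats, protFeats, pairs,
                      training = FALSE, needCache = FALSE)
  .lossAndGrad(cfg$task, fw$yhat, pairs$y)$loss
}

#' Train an affinity model
#'
#' Minibatch Adam on squared-error (DTA) or binary cross-entropy (DPI)
#' loss. When the split provides (or `valFrac` carves out) a validation
#' set, the best-on-validation parameters are returned and training stops
#' early after `patience` epochs without improvement. Fully seeded runs
#' are reproducible on one machine.
#'
#' @param model A [DTAModel-class] from [dtaModel()].
#' @param dataset A [DTADataset-class]. For DPI, affinities are the 0/1
#'   labels.
#' @param split A [SplitSpec-class]; its training records are used for
#'   optimization.
#' @param seed Integer seed for shuffling, validation carving and dropout.
#' @param atomProvider,proteinProvider Optional embedding providers.
#' @param quiet Suppress per-epoch log lines.
#' @param ... Overrides of training settings in the model config
#'   (`lr`, `epochs`, `batchSize`, `patience`, `valFrac`).
#' @return `list(model, history)`: the trained model and a `data.frame`
#'   with per-epoch `epoch`, `trainLoss`, `valLoss`.
#' @export
trainModel <- function(model, dataset, split, seed = 1L,
                       atomProvider = NULL, proteinProvider = NULL,
                       quiet = TRUE, ...) {
  cfg <- model@config
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  stopifnot(is(dataset, "DTADataset"), is(split, "SplitSpec"))
  if (length(split@train) == 0L)
    stop("empty training split", call. = FALSE)

  drugFeats <- featurizeDrugs(unname(dataset@ligands), cfg, atomProvider)
  protFeats <- featurizeProteins(unname(dataset@proteins), cfg,
                                 proteinProvider)

  trainIdx <- split@train
  valIdx <- split@val
  withSeed(seed, {
    if (length(valIdx) == 0L && cfg$valFrac > 0 &&
        length(trainIdx) >= 12L) {
      nVal <- max(1L, floor(cfg$valFrac * length(trainIdx)))
      vi <- sample(seq_along(trainIdx), nVal)
      valIdx <- trainIdx[vi]
      trainIdx <- trainIdx[-vi]
    }
    trainPairs <- .recordPairs(dataset, trainIdx)
    valPairs <- if (length(valIdx)) .recordPairs(dataset, valIdx)

    params <- model@params
    opt <- .adamInit(params)
    best <- list(params = params, valLoss = Inf, epoch = 0L)
    history <- data.frame(epoch = integer(), trainLoss = numeric(),
                          valLoss = numeric())
    nTr <- nrow(trainPairs)
    bs <- min(cfg$batchSize, nTr)

    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(nTr)
      epochLoss <- 0
      nBatches <- ceiling(nTr / bs)
      for (b in seq_len(nBatches)) {
        rows <- perm[((b - 1L) * bs + 1L):min(b * bs, nTr)]
        batch <- trainPairs[rows, , drop = FALSE]
        fw <- .modelForward(params, cfg, drugFeats, protFeats, batch,
                            training = TRUE, needCache = TRUE)
        lg <- .lossAndGrad(cfg$task, fw$yhat, batch$y)
        if (!is.finite(lg$loss))
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d (batch %d)",
            epoch, b), call. = FALSE)
        grads <- .modelBackward(params, cfg, fw$cache, lg$dYhat)
        step <- .adamStep(params, grads, opt, cfg$lr)
        params <- step$params
        opt <- step$state
        epochLoss <- epochLoss + lg$loss * length(rows)
      }
      trainLoss <- epochLoss / nTr
      valLoss <- if (!is.null(valPairs))
        .evalLoss(params, cfg, drugFeats, protFeats, valPairs) else NA_real_
      history <- rbind(history, data.frame(
        epoch = epoch, trainLoss = trainLoss, valLoss = valLoss))
      if (!quiet)
        message(sprintf("epoch %3d  train %.4f  val %s", epoch, trainLoss,
                        ifelse(is.na(valLoss), "-", sprintf("%.4f", valLoss))))
      if (!is.na(valLoss) && valLoss < best$valLoss) {
        best <- list(params = params, valLoss = valLoss, epoch = epoch)
      }
      if (!is.na(valLoss) && epoch - best$epoch >= cfg$patience) break
    }
    finalParams <- if (is.finite(best$valLoss)) best$params else params
    list(model = new("DTAModel", config = cfg, params = finalParams),
         history = history,
         features = list(drugs = drugFeats, proteins = protFeats))
  })
}

#' Evaluate a trained model on a record subset
#'
#' Predicts every record in the index set and computes the task's metric
#' suite (regression metrics including concordance index and rm2 for DTA,
#' threshold/AUC metrics for DPI).
#'
#' @param model A trained [DTAModel-class].
#' @param dataset The [DTADataset-class].
#' @param idx Record indices (e.g. `testIdx(split)`).
#' @param features Optional precomputed `list(drugs, proteins)` features
#'   (as returned by [trainModel()]); featurized on the fly otherwise.
#' @param ... Providers forwarded to the featurizers.
#' @return `list(metrics, pred, truth)`.
#' @export
evaluateModel <- function(model, dataset, idx, features = NULL, ...) {
  cfg <- model@config
  if (is.null(features)) {
    features <- list(
      drugs = featurizeDrugs(unname(dataset@ligands), cfg, ...),
      proteins = featurizeProteins(unname(dataset@proteins), cfg))
  }
  pairs <- .recordPairs(dataset, idx)
  pred <- predictPairs(model, features$drugs, features$proteins, pairs)
  metrics <- if (cfg$task == "dta") {
    c(regressionMetrics(pairs$y, pred),
      ci = concordanceIndex(pairs$y, pred),
      rm2 = rm2Metric(pairs$y, pred))
  } else {
    classificationMetrics(pairs$y, pred)
  }
  list(metrics = metrics, pred = pred, truth = pairs$y)
}
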