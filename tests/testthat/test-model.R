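smallCfg <- function(...) {
  dtaConfig(hidden = 8L, heads = 2L, fusionDim = 6L, seqDim = 10L,
            nLayersCompound = 2L, dropout = 0, ...)
}

smallFeatures <- function(cfg) {
  drugs <- featurizeDrugs(c("CCO", "c1ccncc1C"), cfg,
                          fallbackAtomProvider(32, 5))
  prots <- featurizeProteins(c("ACDKWMK", "MKLVHAA"), cfg,
                             fallbackProteinProvider(10, 5))
  list(drugs = drugs, prots = prots)
}

test_that("the end-to-end forward pass is finite and deterministic in eval mode", {
  cfg <- smallCfg()
  model <- dtaModel(cfg, seed = 3)
  ft <- smallFeatures(cfg)
  pairs <- data.frame(drugIdx = c(1, 2), protIdx = c(1, 2))
  p1 <- predictPairs(model, ft$drugs, ft$prots, pairs)
  p2 <- predictPairs(model, ft$drugs, ft$prots, pairs)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  expect_length(p1, 2)
})

test_that("analytic gradients match central differences on a 5-atom molecule", {
  cfg <- smallCfg()
  model <- dtaModel(cfg, seed = 3)
  drugs <- featurizeDrugs("CC(=O)CO", cfg, fallbackAtomProvider(32, 5))
  prots <- featurizeProteins("ACDKW", cfg, fallbackProteinProvider(10, 5))
  pairs <- data.frame(drugIdx = 1, protIdx = 1, y = 5.5)

  lossFn <- function(params) {
    fw <- dtafuse:::.modelForward(params, cfg, drugs, prots, pairs,
                                  FALSE, FALSE)
    dtafuse:::.lossAndGrad("dta", fw$yhat, pairs$y)$loss
  }
  fw <- dtafuse:::.modelForward(model@params, cfg, drugs, prots, pairs,
                                FALSE, TRUE)
  lg <- dtafuse:::.lossAndGrad("dta", fw$yhat, pairs$y)
  grads <- dtafuse:::.modelBackward(model@params, cfg, fw$cache, lg$dYhat)

  flat <- dtafuse:::.flattenParams(model@params)
  gflat <- dtafuse:::.flattenParams(grads)
  expect_length(gflat, length(flat))
  set.seed(99)
  idx <- sort(sample(length(flat), 60))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    (lossFn(dtafuse:::.unflattenParams(model@params, up)) -
     lossFn(dtafuse:::.unflattenParams(model@params, dn))) / (2 * eps)
  }, numeric(1))
  expect_equal(gflat[idx], num, tolerance = 1e-4)
})

test_that("the ablation ladder changes the architecture as configured", {
  # baseline: single compound view, handcrafted atoms, no sequence branch,
  # plain concatenation
  m1 <- dtaModel(dtaConfig(hidden = 8L, heads = 2L, fusionDim = 6L,
                           usePharm = FALSE, useProviders = FALSE,
                           fusion = "concat"), seed = 1)
  expect_null(m1@params$drugPharm)
  expect_null(m1@params$seqMlp)
  expect_null(m1@params$gate)
  expect_equal(nrow(m1@params$projD$W), 8)            # D_com = D_struct
  expect_equal(nrow(m1@params$projP$W), 8)            # P_com = P_struct
  expect_equal(nrow(m1@params$head[[1]]$W), 12)       # [D || P]
  expect_equal(nrow(m1@params$drugStruct[[1]]$heads[[1]]$W),
               descriptorAtomProvider()$dim)

  # + pharmacophore view
  m2 <- dtaModel(dtaConfig(hidden = 8L, heads = 2L, fusionDim = 6L,
                           usePharm = TRUE, useProviders = FALSE,
                           fusion = "concat"), seed = 1)
  expect_false(is.null(m2@params$drugPharm))
  expect_equal(nrow(m2@params$projD$W), 16)           # D_struct || D_pharma

  # + providers (atom embeddings + pooled-sequence branch)
  m3 <- dtaModel(dtaConfig(hidden = 8L, heads = 2L, fusionDim = 6L,
                           seqDim = 10L, fusion = "concat"), seed = 1)
  expect_false(is.null(m3@params$seqMlp))
  expect_equal(nrow(m3@params$drugStruct[[1]]$heads[[1]]$W), 32)
  expect_equal(nrow(m3@params$projP$W), 16)           # P_struct || P_seq

  # + gated fusion (the full model)
  m4 <- dtaModel(smallCfg(), seed = 1)
  expect_false(is.null(m4@params$gate))
  expect_equal(nrow(m4@params$head[[1]]$W), 6)        # fused width

  # every rung runs a forward pass end to end
  for (m in list(m1, m2, m3, m4)) {
    cfg <- m@config
    drugs <- featurizeDrugs("c1ccncc1C", cfg,
                            if (cfg$useProviders) fallbackAtomProvider(32, 5))
    prots <- featurizeProteins("ACDKWMK", cfg, fallbackProteinProvider(10, 5))
    p <- predictPairs(m, drugs, prots,
                      data.frame(drugIdx = 1, protIdx = 1))
    expect_true(is.finite(p))
  }
})

test_that("one epoch on eight synthetic pairs returns finite losses", {
  ds <- generateSyntheticBenchmark(
    synthConfig(nDrugs = 4L, nProteins = 2L, seed = 5))
  cfg <- smallCfg()
  sp <- new("SplitSpec", regime = "kfold6", train = 1:6, val = integer(),
            test = 7:8, seed = 1L)
  fit <- trainModel(dtaModel(cfg, 1), ds, sp, seed = 1, epochs = 1L,
                    batchSize = 8L, valFrac = 0)
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$trainLoss))
})

test_that("the model memorizes a four-pair training set", {
  ds <- generateSyntheticBenchmark(
    synthConfig(nDrugs = 2L, nProteins = 2L, noiseSd = 0, seed = 8))
  cfg <- smallCfg()
  sp <- new("SplitSpec", regime = "kfold6", train = 1:4, val = integer(),
            test = integer(), seed = 1L)
  fit <- trainModel(dtaModel(cfg, 2), ds, sp, seed = 2, epochs = 300L,
                    lr = 1e-2, batchSize = 4L, valFrac = 0)
  expect_lt(tail(fit$history$trainLoss, 1), 0.05)
})

test_that("training aborts with a diagnostic when the loss diverges", {
  ds <- generateSyntheticBenchmark(
    synthConfig(nDrugs = 4L, nProteins = 2L, seed = 5))
  cfg <- smallCfg()
  sp <- new("SplitSpec", regime = "kfold6", train = 1:8, val = integer(),
            test = integer(), seed = 1L)
  expect_error(
    trainModel(dtaModel(cfg, 1), ds, sp, seed = 1, epochs = 50L,
               lr = 1e150, batchSize = 8L, valFrac = 0),
    "diverged")
})

test_that("DPI task trains on binary labels and predicts probabilities", {
  path <- system.file("extdata", "toy_dpi.tsv", package = "dtafuse")
  ds <- dpiToDataset(loadDPIPairs(path))
  cfg <- smallCfg(task = "dpi")
  sp <- new("SplitSpec", regime = "split811", train = 1:5, val = integer(),
            test = 6L, seed = 1L)
  fit <- trainModel(dtaModel(cfg, 1), ds, sp, seed = 1, epochs = 3L,
                    batchSize = 6L, valFrac = 0)
  ev <- evaluateModel(fit$model, ds, 1:6, fit$features)
  expect_true(all(ev$pred > 0 & ev$pred < 1))
})

test_that("attribution scores are per-atom, normalized, and view-checked", {
  cfg <- smallCfg()
  model <- dtaModel(cfg, seed = 7)
  drugs <- featurizeDrugs("CC(=O)Oc1ccccc1C(=O)O", cfg,
                          fallbackAtomProvider(32, 5))
  prots <- featurizeProteins("ACDKWMK", cfg, fallbackProteinProvider(10, 5))
  s <- gradAAM(model, drugs[[1]], prots)
  expect_length(s, 13)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(max(s), 1)
  expect_error(gradAAM(model, drugs[[1]], prots, view = "pharm"),
               "atom_bond")
})

test_that("screening returns the library ranked by descending score", {
  qf <- quickTrainedModel()
  lib <- c("CCO", "c1ccncc1", "Cc1ccncc1", "CCCC", "c1ccccc1")
  ranked <- screenLibrary(qf$fit$model, lib, proteins(qf$ds)[[1]])
  expect_setequal(ranked$smiles, lib)
  expect_true(all(diff(ranked$score) <= 0))
  expect_equal(ranked$rank, 1:5)
})
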