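# Dataset splitting: rotating k-fold over records, 8:1:1 random split, and
# entity-level cold-start splits (unseen drugs, unseen proteins, or both).

.newSplit <- function(regime, train, val, test, seed) {
  new("SplitSpec", regime = regime,
      train = as.integer(sort(train)), val = as.integer(sort(val)),
      test = as.integer(sort(test)), seed = as.integer(seed))
}

#' k-fold record split
#'
#' Shuffles the records once and deals them into `k` folds whose sizes
#' differ by at most one; fold `f` of the returned list uses fold `f` as
#' the test set and the remaining `k - 1` folds as training records.
#'
#' @param dataset A [DTADataset-class] (or anything with records; an
#'   integer record count is also accepted).
#' @param k Number of folds; default 6.
#' @param seed Integer seed; the same seed always gives the same folds.
#' @return List of `k` [SplitSpec-class] objects.
#' @export
makeKfoldSplit <- function(dataset, k = 6L, seed = 1L) {
  n <- if (is(dataset, "DTADataset")) nrow(dataset@records)
       else as.integer(dataset)
  if (n < k) stop("need at least k records", call. = FALSE)
  folds <- withSeed(seed, {
    perm <- sample.int(n)
    split(perm, rep(seq_len(k), length.out = n))
  })
  lapply(seq_len(k), function(f)
    .newSplit("kfold6", train = unlist(folds[-f]), val = integer(),
              test = folds[[f]], seed = seed))
}

#' Random 8:1:1 split
#'
#' The train/validation/test split used for interaction (DPI)
#' classification.
#'
#' @inheritParams makeKfoldSplit
#' @return A [SplitSpec-class].
#' @export
makeRandomSplit <- function(dataset, seed = 1L) {
  n <- if (is(dataset, "DTADataset")) nrow(dataset@records)
       else as.integer(dataset)
  if (n < 10L) stop("need at least 10 records for an 8:1:1 split",
                    call. = FALSE)
  withSeed(seed, {
    perm <- sample.int(n)
    nTest <- max(1L, round(0.1 * n))
    nVal <- max(1L, round(0.1 * n))
    .newSplit("split811",
              train = perm[seq_len(n - nVal - nTest)],
              val = perm[(n - nVal - nTest + 1L):(n - nTest)],
              test = perm[(n - nTest + 1L):n], seed = seed)
  })
}

#' Cold-start split
#'
#' Entity-level holdout measuring generalization to unseen compounds
#' and/or targets:
#' * `cold_drug` — a fraction of the drugs is held out; every record of a
#'   held-out drug is a test record, so no test-set drug occurs in
#'   training.
#' * `cold_protein` — the same with proteins.
#' * `cold_pair` — drugs *and* proteins are held out; test records are the
#'   pairs where both entities are unseen, training records the pairs
#'   where both are seen, and mixed pairs are discarded.
#'
#' @param dataset A [DTADataset-class].
#' @param mode One of `"cold_drug"`, `"cold_protein"`, `"cold_pair"`.
#' @param fracTest Fraction of entities (per entity type) to hold out.
#' @param seed Integer seed.
#' @return A [SplitSpec-class]; overlap invariants are asserted before it
#'   is returned.
#' @export
makeColdSplit <- function(dataset, mode = c("cold_drug", "cold_protein",
                                            "cold_pair"),
                          fracTest = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(dataset, "DTADataset"))
  recs <- dataset@records
  drugs <- names(dataset@ligands)
  prots <- names(dataset@proteins)

  holdout <- function(ids, frac) {
    nH <- floor(frac * length(ids))
    if (nH < 1L || nH >= length(ids))
      stop(sprintf(
        "infeasible holdout fraction %.3f for %d entities", frac,
        length(ids)), call. = FALSE)
    sample(ids, nH)
  }

  withSeed(seed, {
    if (mode == "cold_drug") {
      hd <- holdout(drugs, fracTest)
      test <- which(recs$drug_id %in% hd)
      train <- which(!(recs$drug_id %in% hd))
    } else if (mode == "cold_protein") {
      hp <- holdout(prots, fracTest)
      test <- which(recs$target_id %in% hp)
      train <- which(!(recs$target_id %in% hp))
    } else {
      hd <- holdout(drugs, fracTest)
      hp <- holdout(prots, fracTest)
      coldD <- recs$drug_id %in% hd
      coldP <- recs$target_id %in% hp
      test <- which(coldD & coldP)
      train <- which(!coldD & !coldP)  # one-cold pairs are discarded
    }
    sp <- .newSplit(mode, train = train, val = integer(), test = test,
                    seed = seed)
    .assertCold(sp, recs, mode)
    sp
  })
}

.assertCold <- function(split, recs, mode) {
  trD <- unique(recs$drug_id[split@train])
  teD <- unique(recs$drug_id[split@test])
  trP <- unique(recs$target_id[split@train])
  teP <- unique(recs$target_id[split@test])
  if (mode %in% c("cold_drug", "cold_pair") &&
      length(intersect(trD, teD)))
    stop("cold split violated: shared drugs", call. = FALSE)
  if (mode %in% c("cold_protein", "cold_pair") &&
      length(intersect(trP, teP)))
    stop("cold split violated: shared proteins", call. = FALSE)
  invisible(TRUE)
}
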