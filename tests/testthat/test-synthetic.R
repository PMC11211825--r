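test_that("every grammar molecule parses and the pool is structurally mixed", {
  pool <- syntheticMolPool(200)     # parseSmiles() errors on any failure
  expect_length(pool$smiles, 200)
  mols <- parseSmiles(pool$smiles)
  ringy <- vapply(mols, function(m) any(atoms(m)$inRing), logical(1))
  expect_gt(sum(ringy), 0)
  expect_gt(sum(!ringy), 0)
})

test_that("generation is deterministic under a fixed seed", {
  s1 <- generateSyntheticMolecules(50, synthConfig(), seed = 123)
  s2 <- generateSyntheticMolecules(50, synthConfig(), seed = 123)
  expect_identical(s1, s2)
  expect_false(identical(
    s1, generateSyntheticMolecules(50, synthConfig(), seed = 124)))

  p1 <- generateSyntheticProteins(20, synthConfig(), seed = 9)
  p2 <- generateSyntheticProteins(20, synthConfig(), seed = 9)
  expect_identical(p1, p2)

  d1 <- generateSyntheticBenchmark(synthConfig(nDrugs = 10L,
                                               nProteins = 5L, seed = 4))
  d2 <- generateSyntheticBenchmark(synthConfig(nDrugs = 10L,
                                               nProteins = 5L, seed = 4))
  expect_identical(affinityMatrix(d1), affinityMatrix(d2))
})

test_that("ring-bearing fraction tracks the grammar rate within 3 sigma", {
  cfg <- synthConfig(ringProb = 0.6)
  n <- 400L
  smiles <- generateSyntheticMolecules(n, cfg, seed = 31)
  mols <- parseSmiles(smiles)
  ringy <- vapply(mols, function(m) any(atoms(m)$inRing), logical(1))
  expect_lt(abs(mean(ringy) - cfg$ringProb),
            3 * sqrt(cfg$ringProb * (1 - cfg$ringProb) / n))
})

test_that("protein sequences are alphabet-valid with planted motifs", {
  cfg <- synthConfig(motifRate = 0.5)
  seqs <- generateSyntheticProteins(60, cfg, seed = 21)
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)))
  lens <- nchar(seqs)
  expect_true(all(lens >= cfg$seqLenRange[1]))
  counts <- dtafuse:::countMotif(seqs, cfg$motif)
  expect_gt(sum(counts > 0), 0)
  expect_gt(sum(counts == 0), 0)
})

test_that("with zero noise the affinities equal the generative formula", {
  cfg <- synthConfig(nDrugs = 15L, nProteins = 8L, noiseSd = 0, seed = 6)
  ds <- generateSyntheticBenchmark(cfg)
  md <- ds@metadata
  frag <- dtafuse:::countAromaticN(parseSmiles(unname(ligands(ds))))
  motif <- dtafuse:::countMotif(unname(proteins(ds)), cfg$motif)
  expected <- cfg$base + outer(cfg$alpha * frag, cfg$beta * motif, `+`) +
    cfg$gamma * outer(frag > 0, motif > 0, `&`)
  expect_equal(unname(affinityMatrix(ds)), unname(expected),
               tolerance = 1e-12)
  expect_equal(md$fragCounts, unname(frag))
})

test_that("the interaction term is pair-specific: shuffling pairings kills it", {
  cfg <- synthConfig(nDrugs = 40L, nProteins = 25L, noiseSd = 0.3,
                     seed = 14)
  ds <- generateSyntheticBenchmark(cfg)
  recs <- affinityRecords(ds)
  md <- ds@metadata
  frag <- md$fragCounts[match(recs$drug_id, names(ligands(ds)))]
  motif <- md$motifCounts[match(recs$target_id, names(proteins(ds)))]
  inter <- as.numeric(frag > 0 & motif > 0)

  # the true pairing recovers the planted interaction coefficient ...
  rssMain <- sum(resid(lm(recs$affinity ~ frag + motif))^2)
  fitFull <- lm(recs$affinity ~ frag + motif + inter)
  expect_equal(unname(coef(fitFull)["inter"]), cfg$gamma, tolerance = 0.3)
  expect_lt(sum(resid(fitFull)^2), 0.9 * rssMain)

  # ... but a pairing-shuffled interaction indicator explains ~nothing
  set.seed(99)
  interShuf <- sample(inter)
  fitShuf <- lm(recs$affinity ~ frag + motif + interShuf)
  expect_lt(abs(unname(coef(fitShuf)["interShuf"])), 0.2)
  expect_gt(sum(resid(fitShuf)^2), 0.95 * rssMain)
})

test_that("missing-fraction masking drops records but never all of them", {
  cfg <- synthConfig(nDrugs = 10L, nProteins = 6L, missingFrac = 0.3,
                     seed = 2)
  ds <- generateSyntheticBenchmark(cfg)
  n <- nrow(affinityRecords(ds))
  expect_lt(n, 60)
  expect_gt(n, 0)
  expect_equal(n, sum(!is.na(affinityMatrix(ds))))
})
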