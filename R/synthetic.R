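# Synthetic fixture generator. Emits valid drug-like SMILES from a small
# fragment grammar, protein-like sequences with an optionally planted
# motif, and a benchmark whose affinities carry a plantable
# structure -> affinity signal:
#
#   affinity = base + alpha * (# aromatic nitrogens in the drug)
#                   + beta  * (# motif copies in the protein)
#                   + gamma * 1[both present]  + Gaussian noise
#
# The interaction term makes the signal recoverable only by a model that
# uses both entities, mimicking the pair-level structure a DTA model must
# learn. All draws are seeded and reproducible.

.RING_TEMPLATES <- c(
  benzene = "c1ccccc1",
  pyridine = "c1ccncc1",
  cyclohexane = "C1CCCCC1",
  piperidine = "C1CCNCC1",
  tetrahydrofuran = "C1CCOC1",
  furan = "c1ccoc1",
  thiophene = "c1ccsc1"
)

# Linker fragments may be extended on their right (last atom keeps a free
# valence); terminal fragments may only end a chain (halogen-terminated).
.CHAIN_FRAGMENTS <- c("C", "CC", "CO", "CN", "C(C)C", "C(=O)O",
                      "C(=O)N", "CCO")
.TERMINAL_FRAGMENTS <- c("CCl", "CF", "C", "CC", "CO")

#' Synthetic configuration
#'
#' Study conditions of the synthetic benchmark; the defaults are the fixed
#' conditions all learnability checks run under.
#'
#' @param nDrugs,nProteins Library sizes (default 200 x 50).
#' @param ringProb Probability a generated molecule carries a ring
#'   scaffold.
#' @param pyridineProb Probability a ring scaffold is the aromatic-N
#'   template (the planted drug fragment).
#' @param maxSubstituents Maximum chain substituents on a ring scaffold.
#' @param maxChainFrags Maximum fragments of a purely acyclic molecule.
#' @param seqLenRange Protein length range (residues).
#' @param motif Planted protein motif.
#' @param motifRate Per-slot insertion rate; each protein receives
#'   `Binomial(2, motifRate)` motif copies.
#' @param base,alpha,beta,gamma Affinity model coefficients (see package
#'   docs): intercept, per-aromatic-nitrogen, per-motif-copy, and the
#'   both-present interaction bump.
#' @param noiseSd Gaussian observation noise (affinity units).
#' @param missingFrac Fraction of affinity cells masked as unmeasured.
#' @param seed Integer seed.
#' @return Named list of settings.
#' @export
synthConfig <- function(nDrugs = 200L, nProteins = 50L,
                        ringProb = 0.6, pyridineProb = 0.35,
                        maxSubstituents = 2L, maxChainFrags = 4L,
                        seqLenRange = c(50L, 120L),
                        motif = "CWNQH", motifRate = 0.35,
                        base = 5, alpha = 0.5, beta = 0.4, gamma = 1,
                        noiseSd = 0.3, missingFrac = 0, seed = 1L) {
  stopifnotScalarCount(nDrugs, "nDrugs")
  stopifnotScalarCount(nProteins, "nProteins")
  if (noiseSd < 0) stop("'noiseSd' must be >= 0", call. = FALSE)
  as.list(environment())
}

.randomMoleculeSmiles <- function(config) {
  if (runif(1) < config$ringProb) {
    ring <- if (runif(1) < config$pyridineProb) .RING_TEMPLATES[["pyridine"]]
            else sample(.RING_TEMPLATES[names(.RING_TEMPLATES) != "pyridine"], 1)
    nSub <- sample(0:config$maxSubstituents, 1)
    pre <- if (nSub >= 1) sample(.CHAIN_FRAGMENTS, 1) else ""
    post <- if (nSub >= 2) sample(.TERMINAL_FRAGMENTS, 1) else ""
    paste0(pre, ring, post)
  } else {
    n <- sample(seq_len(config$maxChainFrags), 1)
    body <- if (n > 1) sample(.CHAIN_FRAGMENTS, n - 1, replace = TRUE)
            else character()
    paste(c(body, sample(.TERMINAL_FRAGMENTS, 1)), collapse = "")
  }
}

#' Generate synthetic drug-like SMILES
#'
#' Draws molecules from the fragment grammar: ring scaffolds (aromatic and
#' saturated, with up to two chain substituents) and purely acyclic
#' chains. Every emitted string is valid SMILES by construction; the
#' population contains both ring-bearing and acyclic molecules.
#'
#' @param n Number of molecules.
#' @param config A [synthConfig()].
#' @param seed Overrides `config$seed`.
#' @return Character vector of `n` SMILES strings.
#' @export
generateSyntheticMolecules <- function(n, config = synthConfig(),
                                       seed = config$seed) {
  withSeed(seed, vapply(seq_len(n),
                        function(i) .randomMoleculeSmiles(config),
                        character(1)))
}

#' Generate synthetic protein sequences
#'
#' Uniform draws over the 20-letter alphabet with `Binomial(2, motifRate)`
#' copies of the planted motif inserted at random positions.
#'
#' @param n Number of sequences.
#' @param config A [synthConfig()].
#' @param seed Overrides `config$seed`.
#' @return Character vector of sequences.
#' @export
generateSyntheticProteins <- function(n, config = synthConfig(),
                                      seed = config$seed) {
  aa <- .AA_TABLE$aa
  withSeed(seed, vapply(seq_len(n), function(i) {
    L <- sample(config$seqLenRange[1]:config$seqLenRange[2], 1)
    s <- paste(sample(aa, L, replace = TRUE), collapse = "")
    nCopies <- rbinom(1, 2, config$motifRate)
    for (k in seq_len(nCopies)) {
      pos <- sample(nchar(s) - 1L, 1)
      s <- paste0(substr(s, 1, pos), config$motif,
                  substr(s, pos + 1L, nchar(s)))
    }
    s
  }, character(1)))
}

# Planted drug signal: number of aromatic nitrogen atoms.
countAromaticN <- function(mols) {
  vapply(mols, function(m) {
    at <- atoms(m)
    sum(at$element == "N" & at$aromatic)
  }, numeric(1))
}

countMotif <- function(sequences, motif) {
  vapply(sequences, function(s) {
    hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
    if (hits[1] == -1) 0 else length(hits)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate the planted-signal synthetic benchmark
#'
#' Builds a complete [DTADataset-class] from the grammar: drug fragment
#' counts and protein motif counts are combined by the additive +
#' interaction affinity model described in [synthConfig()], plus Gaussian
#' noise. The generative truth (fragment counts, motif counts, noiseless
#' affinities) is stored in the dataset metadata.
#'
#' @param config A [synthConfig()].
#' @return A [DTADataset-class].
#' @export
generateSyntheticBenchmark <- function(config = synthConfig()) {
  smiles <- generateSyntheticMolecules(config$nDrugs, config,
                                       seed = config$seed)
  seqs <- generateSyntheticProteins(config$nProteins, config,
                                    seed = config$seed + 1L)
  frag <- countAromaticN(parseSmiles(smiles))
  motif <- countMotif(seqs, config$motif)

  signal <- config$base +
    outer(config$alpha * frag, config$beta * motif, `+`) +
    config$gamma * outer(frag > 0, motif > 0, `&`)

  aff <- withSeed(config$seed + 2L, {
    a <- signal + matrix(rnorm(length(signal), sd = config$noiseSd),
                         nrow(signal))
    if (config$missingFrac > 0) {
      drop1 <- runif(length(a)) < config$missingFrac
      if (all(drop1)) drop1[1] <- FALSE
      a[drop1] <- NA_real_
    }
    a
  })

  ligands <- stats::setNames(smiles, sprintf("D%04d", seq_along(smiles)))
  proteins <- stats::setNames(seqs, sprintf("T%04d", seq_along(seqs)))
  dimnames(aff) <- list(names(ligands), names(proteins))
  .newDTADataset(ligands, proteins, aff, metadata = list(
    config = config, fragCounts = unname(frag),
    motifCounts = unname(motif), signal = unname(signal)))
}
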