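# Embedding providers: a uniform contract for pre-trained molecule/protein
# embedders plus deterministic offline fallbacks.
#
# A provider is a plain list:
#   atom provider:    list(name, dim, embed = function(mol) N x dim matrix)
#   protein provider: list(name, dim,
#                          embed = function(sequence)
#                                  list(embeddings = L x dim,
#                                       contacts = L x L))
# The model-level code never knows which provider it received; real adapters
# for pre-trained models can be dropped in behind the same contract.

#' Deterministic fallback atom embeddings
#'
#' Offline stand-in for a pre-trained molecular embedder. Row i is a
#' deterministic function of atom i's local descriptor (element, degree,
#' aromaticity, formal charge) and the seed, so chemically equivalent atoms
#' in identical local environments receive identical rows and the same
#' molecule always embeds identically.
#'
#' @param mol A [Molecule-class].
#' @param dim Embedding width; default 32, matching the width produced by
#'   pre-trained molecular embedders this package is designed around.
#' @param seed Integer seed.
#' @return N x `dim` numeric matrix, N = atom count.
#' @export
fallbackAtomEmbeddings <- function(mol, dim = 32L, seed = 1L) {
  stopifnotScalarCount(dim, "dim")
  at <- atoms(mol)
  key <- paste(at$element, at$degree, at$aromatic, at$charge, seed,
               sep = "|")
  hashes <- fnvHash(key)
  rows <- lapply(hashes, function(h) withSeed(h, rnorm(dim)))
  do.call(rbind, rows)
}

#' Deterministic fallback protein embeddings and contact probabilities
#'
#' Offline stand-in for a pre-trained protein language model. Residue
#' embedding rows are a deterministic function of (residue identity,
#' position, seed). The synthetic contact-probability matrix is symmetric,
#' lies in `[0, 1]`, has elevated probabilities on a near-diagonal band
#' (backbone-neighbour contacts) and sparse planted long-range contacts at
#' the configured rate.
#'
#' @param sequence Amino-acid string.
#' @param dim Residue embedding width; default 1280, matching pre-trained
#'   protein language models.
#' @param seed Integer seed.
#' @param contactRate Bernoulli rate of long-range (|i-j| > `bandWidth`)
#'   contacts; default 0.02.
#' @param bandWidth Half-width of the elevated near-diagonal band.
#' @param maxLen Sequences longer than this are truncated with a warning
#'   (pre-trained protein models have a comparable input cap).
#' @return `list(embeddings = L x dim matrix, contacts = L x L matrix,
#'   truncated = logical)`.
#' @export
fallbackProteinEmbeddings <- function(sequence, dim = 1280L, seed = 1L,
                                      contactRate = 0.02, bandWidth = 3L,
                                      maxLen = 1022L) {
  letters1 <- .checkSequence(sequence)
  if (length(letters1) > maxLen) {
    warning(sprintf("sequence truncated from %d to %d residues",
                    length(letters1), maxLen))
    letters1 <- letters1[seq_len(maxLen)]
  }
  L <- length(letters1)
  stopifnotScalarCount(dim, "dim")

  keys <- paste(letters1, seq_len(L), seed, sep = "|")
  emb <- do.call(rbind, lapply(fnvHash(keys),
                               function(h) withSeed(h, rnorm(dim))))

  seqSeed <- fnvHash(paste(paste(letters1, collapse = ""), seed, sep = "|"))
  contacts <- withSeed(seqSeed, {
    p <- matrix(0, L, L)
    ut <- which(upper.tri(p), arr.ind = TRUE)   # column-major order
    d <- ut[, 2] - ut[, 1]
    vals <- numeric(nrow(ut))
    band <- d <= bandWidth
    vals[band] <- runif(sum(band), 0.6, 0.95)
    long <- which(!band)
    hit <- runif(length(long)) < contactRate
    vals[long[hit]] <- runif(sum(hit), 0.55, 0.95)
    vals[long[!hit]] <- runif(sum(!hit), 0, 0.45)
    p[upper.tri(p)] <- vals
    p <- p + t(p)
    diag(p) <- 1
    p
  })
  list(embeddings = emb, contacts = contacts, truncated = L < nchar(sequence))
}

#' Fallback provider constructors
#'
#' Wrap the deterministic fallback embedders in the provider contract used
#' by [buildAtomBondGraph()] and [featurizeProteins()].
#'
#' @param dim Embedding width (32 for atoms, 1280 for proteins by default).
#' @param seed Integer seed baked into the provider.
#' @param ... Passed through to [fallbackProteinEmbeddings()].
#' @return A provider list with elements `name`, `dim`, `embed`.
#' @export
fallbackAtomProvider <- function(dim = 32L, seed = 1L) {
  list(name = sprintf("fallback-atom-%d", seed), dim = as.integer(dim),
       embed = function(mol) fallbackAtomEmbeddings(mol, dim, seed))
}

#' @rdname fallbackAtomProvider
#' @export
fallbackProteinProvider <- function(dim = 1280L, seed = 1L, ...) {
  list(name = sprintf("fallback-protein-%d", seed), dim = as.integer(dim),
       embed = function(sequence)
         fallbackProteinEmbeddings(sequence, dim, seed, ...))
}

#' Handcrafted-descriptor atom provider
#'
#' The non-pre-trained baseline: atom node features are the versioned
#' handcrafted descriptor set rather than learned embeddings.
#'
#' @return A provider list.
#' @export
descriptorAtomProvider <- function() {
  width <- ncol(atomDescriptors(.dummyMolecule()))
  list(name = "descriptor-atom", dim = width,
       embed = function(mol) unname(atomDescriptors(mol)))
}

.dummyMolecule <- function() {
  new("Molecule", smiles = "C", canonical = "C",
      atoms = data.frame(element = "C", degree = 0L, aromatic = FALSE,
                         charge = 0L, chirality = "none", inRing = FALSE,
                         stringsAsFactors = FALSE),
      bonds = data.frame(i = integer(), j = integer(), type = character(),
                         stereo = character(), inRing = logical()),
      ringAtoms = list(), ringBonds = list())
}
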