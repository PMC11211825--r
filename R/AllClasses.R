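#' Molecule: a parsed small molecule
#'
#' Atom and bond tables produced by the RDKit-backed SMILES parser, plus the
#' smallest set of smallest rings (SSSR). Atom and bond indices are 1-based
#' and contiguous.
#'
#' @slot smiles Input SMILES string.
#' @slot canonical Canonical SMILES as emitted by the parser.
#' @slot atoms `data.frame` with columns `element`, `degree`, `aromatic`,
#'   `charge`, `chirality`, `inRing`; one row per heavy atom (hydrogens are
#'   implicit).
#' @slot bonds `data.frame` with columns `i`, `j` (1-based atom indices),
#'   `type`, `stereo`, `inRing`; one row per chemical bond.
#' @slot ringAtoms List of integer vectors: atom indices of each SSSR ring.
#' @slot ringBonds List of integer vectors: bond indices of each SSSR ring.
#' @export
setClass("Molecule", representation(
  smiles = "character",
  canonical = "character",
  atoms = "data.frame",
  bonds = "data.frame",
  ringAtoms = "list",
  ringBonds = "list"
))

setValidity("Molecule", function(object) {
  n <- nrow(object@atoms)
  b <- object@bonds
  msg <- character()
  if (nrow(b) > 0) {
    if (any(b$i == b$j))
      msg <- c(msg, "bond endpoints must be distinct atoms")
    if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n))
      msg <- c(msg, "bond references a non-existent atom")
  }
  for (r in object@ringAtoms)
    if (any(r < 1 | r > n)) msg <- c(msg, "ring atom index out of range")
  if (length(msg)) msg else TRUE
})

#' AtomBondGraph: the fine-grained molecular view
#'
#' Atoms as nodes, chemical bonds as attributed directed edges (each bond
#' contributes both directions with identical features). Node features come
#' from an atom-embedding provider or the handcrafted descriptor fallback.
#'
#' @slot smiles Canonical SMILES of the underlying molecule.
#' @slot nodeFeatures N x F numeric matrix, rows aligned with atom indices.
#' @slot edgeIndex 2 x E integer matrix of directed edges (1-based).
#' @slot edgeFeatures E x Fe numeric matrix of bond-type/stereo encodings.
#' @export
setClass("AtomBondGraph", representation(
  smiles = "character",
  nodeFeatures = "matrix",
  edgeIndex = "matrix",
  edgeFeatures = "matrix"
))

setValidity("AtomBondGraph", function(object) {
  e <- object@edgeIndex
  msg <- character()
  if (ncol(e) > 0) {
    if (any(e[1, ] == e[2, ])) msg <- c(msg, "self-loops are not stored")
    key <- paste(e[1, ], e[2, ])
    rkey <- paste(e[2, ], e[1, ])
    if (!setequal(key, rkey)) msg <- c(msg, "edge set must be symmetric")
    if (ncol(e) != nrow(object@edgeFeatures))
      msg <- c(msg, "edgeFeatures rows must match edge count")
  }
  if (length(msg)) msg else TRUE
})

#' PharmacophoreGraph: the coarse functional-unit view
#'
#' Rings (SSSR) and acyclic bonds become nodes; two units are adjacent iff
#' they share at least one atom. Node features aggregate member-atom and
#' member-bond descriptors permutation-invariantly.
#'
#' @slot smiles Canonical SMILES of the underlying molecule.
#' @slot units List of unit records: `list(kind, atoms, bonds)` with
#'   `kind` one of `"ring"`, `"acyclic_bond"`.
#' @slot nodeFeatures U x Fp numeric matrix, one row per unit.
#' @slot edgeIndex 2 x E integer matrix of directed edges between units.
#' @export
setClass("PharmacophoreGraph", representation(
  smiles = "character",
  units = "list",
  nodeFeatures = "matrix",
  edgeIndex = "matrix"
))

#' MolGraphPair: both molecular views of one compound
#'
#' @slot atomBond [AtomBondGraph-class] view.
#' @slot pharm [PharmacophoreGraph-class] view (shares the atom index space).
#' @export
setClass("MolGraphPair", representation(
  atomBond = "AtomBondGraph",
  pharm = "PharmacophoreGraph"
))

#' ResidueContactGraph: weighted protein contact graph
#'
#' Residues as nodes; an undirected edge wherever the (max-symmetrized)
#' contact probability strictly exceeds the threshold, weighted by that
#' probability.
#'
#' @slot sequence Amino-acid sequence (20-letter alphabet plus `X`).
#' @slot nodeFeatures L x Fr residue descriptor matrix.
#' @slot edgeIndex 2 x E integer matrix of directed edges.
#' @slot edgeWeights Numeric vector of contact probabilities per directed
#'   edge, each in (threshold, 1].
#' @slot threshold Contact probability cut-off (default 0.5, strict).
#' @export
setClass("ResidueContactGraph", representation(
  sequence = "character",
  nodeFeatures = "matrix",
  edgeIndex = "matrix",
  edgeWeights = "numeric",
  threshold = "numeric"
))

setValidity("ResidueContactGraph", function(object) {
  msg <- character()
  if (length(object@edgeWeights) != ncol(object@edgeIndex))
    msg <- c(msg, "one weight per directed edge required")
  if (length(object@edgeWeights) &&
      any(object@edgeWeights <= object@threshold | object@edgeWeights > 1))
    msg <- c(msg, "edge weights must lie in (threshold, 1]")
  if (ncol(object@edgeIndex) && any(object@edgeIndex[1, ] == object@edgeIndex[2, ]))
    msg <- c(msg, "no self-contacts")
  if (length(msg)) msg else TRUE
})

#' DTADataset: a benchmark-style affinity dataset
#'
#' Ligand and protein lookup tables plus a dense affinity matrix in which
#' `NA` marks unmeasured pairs; `records` is the flattened list of measured
#' (drug, target, affinity) triples.
#'
#' @slot ligands Named character vector: compound ID -> SMILES.
#' @slot proteins Named character vector: target ID -> sequence.
#' @slot affinity Numeric matrix, rows = compounds, cols = targets, `NA` =
#'   missing.
#' @slot records `data.frame` with columns `drug_id`, `target_id`,
#'   `affinity`.
#' @slot metadata List of free-form provenance (e.g. the generative truth of
#'   a synthetic benchmark).
#' @export
setClass("DTADataset", representation(
  ligands = "character",
  proteins = "character",
  affinity = "matrix",
  records = "data.frame",
  metadata = "list"
))

setValidity("DTADataset", function(object) {
  msg <- character()
  r <- object@records
  if (!all(c("drug_id", "target_id", "affinity") %in% names(r)))
    return("records needs drug_id, target_id, affinity columns")
  if (!all(r$drug_id %in% names(object@ligands)))
    msg <- c(msg, "record drug_id not found in ligand table")
  if (!all(r$target_id %in% names(object@proteins)))
    msg <- c(msg, "record target_id not found in protein table")
  if (nrow(r) != sum(!is.na(object@affinity)))
    msg <- c(msg, "record count must equal non-missing affinity cells")
  if (any(!is.finite(r$affinity)))
    msg <- c(msg, "record affinities must be finite")
  if (length(msg)) msg else TRUE
})

#' SplitSpec: one train/validation/test assignment
#'
#' @slot regime One of `"kfold6"`, `"split811"`, `"cold_drug"`,
#'   `"cold_protein"`, `"cold_pair"`.
#' @slot train,val,test Integer record indices; disjoint. Under a cold
#'   regime, records involving held-out entities but not matching the test
#'   definition (e.g. one-seen pairs under `cold_pair`) are dropped from all
#'   three sets.
#' @slot seed Integer seed the split was generated from.
#' @export
setClass("SplitSpec", representation(
  regime = "character",
  train = "integer",
  val = "integer",
  test = "integer",
  seed = "integer"
))

setValidity("SplitSpec", function(object) {
  idx <- c(object@train, object@val, object@test)
  if (anyDuplicated(idx)) "train/val/test must be disjoint" else TRUE
})

#' DTAModel: the multi-view affinity model
#'
#' Parameters and configuration of the two-view compound / two-view protein
#' encoder stack with gated fusion. Created by [dtaModel()]; train with
#' [trainModel()].
#'
#' @slot config Named list of architecture and ablation settings (see
#'   [dtaConfig()]).
#' @slot params Nested list of numeric weight matrices.
#' @export
setClass("DTAModel", representation(
  config = "list",
  params = "list"
))
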