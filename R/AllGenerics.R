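#' @name dtafuse-accessors
#' @title Accessors for dtafuse objects
#' @description Slot accessors for the S4 containers: atom/bond tables of a
#'   [Molecule-class], node/edge matrices of the graph views, the ligand,
#'   protein and record tables of a [DTADataset-class], and split index sets
#'   of a [SplitSpec-class].
#' @param x An object.
#' @return The requested component.
NULL

#' @rdname dtafuse-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("edgeIndex", function(x) standardGeneric("edgeIndex"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("edgeFeatures", function(x) standardGeneric("edgeFeatures"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("pharmUnits", function(x) standardGeneric("pharmUnits"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("affinityMatrix", function(x) standardGeneric("affinityMatrix"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("affinityRecords", function(x) standardGeneric("affinityRecords"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("trainIdx", function(x) standardGeneric("trainIdx"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("valIdx", function(x) standardGeneric("valIdx"))
#' @rdname dtafuse-accessors
#' @export
setGeneric("testIdx", function(x) standardGeneric("testIdx"))

#' @rdname dtafuse-accessors
#' @export
setMethod("atoms", "Molecule", function(x) x@atoms)
#' @rdname dtafuse-accessors
#' @export
setMethod("bonds", "Molecule", function(x) x@bonds)
#' @rdname dtafuse-accessors
#' @export
setMethod("canonicalSmiles", "Molecule", function(x) x@canonical)

#' @rdname dtafuse-accessors
#' @export
setMethod("nodeFeatures", "AtomBondGraph", function(x) x@nodeFeatures)
#' @rdname dtafuse-accessors
#' @export
setMethod("edgeIndex", "AtomBondGraph", function(x) x@edgeIndex)
#' @rdname dtafuse-accessors
#' @export
setMethod("edgeFeatures", "AtomBondGraph", function(x) x@edgeFeatures)

#' @rdname dtafuse-accessors
#' @export
setMethod("nodeFeatures", "PharmacophoreGraph", function(x) x@nodeFeatures)
#' @rdname dtafuse-accessors
#' @export
setMethod("edgeIndex", "PharmacophoreGraph", function(x) x@edgeIndex)
#' @rdname dtafuse-accessors
#' @export
setMethod("pharmUnits", "PharmacophoreGraph", function(x) x@units)

#' @rdname dtafuse-accessors
#' @export
setMethod("nodeFeatures", "ResidueContactGraph", function(x) x@nodeFeatures)
#' @rdname dtafuse-accessors
#' @export
setMethod("edgeIndex", "ResidueContactGraph", function(x) x@edgeIndex)
#' @rdname dtafuse-accessors
#' @export
setMethod("edgeWeights", "ResidueContactGraph", function(x) x@edgeWeights)

#' @rdname dtafuse-accessors
#' @export
setMethod("ligands", "DTADataset", function(x) x@ligands)
#' @rdname dtafuse-accessors
#' @export
setMethod("proteins", "DTADataset", function(x) x@proteins)
#' @rdname dtafuse-accessors
#' @export
setMethod("affinityMatrix", "DTADataset", function(x) x@affinity)
#' @rdname dtafuse-accessors
#' @export
setMethod("affinityRecords", "DTADataset", function(x) x@records)

#' @rdname dtafuse-accessors
#' @export
setMethod("trainIdx", "SplitSpec", function(x) x@train)
#' @rdname dtafuse-accessors
#' @export
setMethod("valIdx", "SplitSpec", function(x) x@val)
#' @rdname dtafuse-accessors
#' @export
setMethod("testIdx", "SplitSpec", function(x) x@test)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %s (%d atoms, %d bonds, %d rings)\n",
              object@canonical, nrow(object@atoms), nrow(object@bonds),
              length(object@ringAtoms)))
})

setMethod("show", "AtomBondGraph", function(object) {
  cat(sprintf("AtomBondGraph: %s\n  %d nodes x %d features, %d directed edges\n",
              object@smiles, nrow(object@nodeFeatures),
              ncol(object@nodeFeatures), ncol(object@edgeIndex)))
})

setMethod("show", "PharmacophoreGraph", function(object) {
  kinds <- vapply(object@units, `[[`, character(1), "kind")
  cat(sprintf(
    "PharmacophoreGraph: %s\n  %d units (%d ring, %d acyclic), %d directed edges\n",
    object@smiles, length(object@units), sum(kinds == "ring"),
    sum(kinds == "acyclic_bond"), ncol(object@edgeIndex)))
})

setMethod("show", "MolGraphPair", function(object) {
  cat("MolGraphPair\n")
  show(object@atomBond)
  show(object@pharm)
})

setMethod("show", "ResidueContactGraph", function(object) {
  cat(sprintf(
    "ResidueContactGraph: %d residues, %d contacts (p > %.2f)\n",
    nchar(object@sequence), ncol(object@edgeIndex) / 2, object@threshold))
})

setMethod("show", "DTADataset", function(object) {
  cat(sprintf(
    "DTADataset: %d compounds x %d targets, %d measured affinities\n",
    length(object@ligands), length(object@proteins), nrow(object@records)))
})

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec [%s]: %d train / %d val / %d test (seed %d)\n",
              object@regime, length(object@train), length(object@val),
              length(object@test), object@seed))
})

setMethod("show", "DTAModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    paste0("DTAModel (%s task)\n",
           "  views: atom-bond%s + contact graph%s\n",
           "  fusion: %s | hidden %d | heads %d | fusion width %d\n"),
    cfg$task,
    if (cfg$usePharm) " + pharmacophore" else "",
    if (cfg$useProviders) " + sequence embedding" else "",
    cfg$fusion, cfg$hidden, cfg$heads, cfg$fusionDim))
})
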