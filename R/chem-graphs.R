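# The two molecular views: atom-bond graph (atoms as nodes, bonds as
# attributed edges) and the coarse pharmacophore graph (SSSR rings and
# acyclic bonds as nodes, shared-atom adjacency).

#' Build the atom-bond graph of a molecule
#'
#' Atoms become nodes and every chemical bond contributes two directed edges
#' carrying identical bond-type/stereo features. Node features come from the
#' supplied atom-embedding provider, or from the handcrafted descriptor set
#' when `provider` is `NULL`.
#'
#' @param mol A [Molecule-class].
#' @param provider An atom-embedding provider (see [fallbackAtomProvider()])
#'   or `NULL` for handcrafted descriptors.
#' @return An [AtomBondGraph-class].
#' @examples
#' \dontrun{
#' g <- buildAtomBondGraph(parseSmiles("c1ccccc1")[[1]])
#' dim(nodeFeatures(g))  # 6 x descriptor width
#' }
#' @export
buildAtomBondGraph <- function(mol, provider = NULL) {
  stopifnot(is(mol, "Molecule"))
  n <- nrow(mol@atoms)
  if (is.null(provider)) {
    feats <- atomDescriptors(mol)
  } else {
    feats <- provider$embed(mol)
    if (!is.matrix(feats) || nrow(feats) != n)
      stop(sprintf(
        "provider '%s' returned %d rows for a molecule with %d atoms",
        provider$name, NROW(feats), n), call. = FALSE)
    if (ncol(feats) != provider$dim)
      stop("provider returned wrong embedding width", call. = FALSE)
  }
  bd <- mol@bonds
  bondFeats <- bondDescriptors(mol)
  if (nrow(bd)) {
    edgeIndex <- rbind(c(rbind(bd$i, bd$j)), c(rbind(bd$j, bd$i)))
    edgeFeats <- bondFeats[rep(seq_len(nrow(bd)), each = 2L), , drop = FALSE]
  } else {
    edgeIndex <- matrix(integer(), 2, 0)
    edgeFeats <- matrix(0, 0, ncol(bondFeats))
  }
  new("AtomBondGraph", smiles = mol@canonical,
      nodeFeatures = unname(feats),
      edgeIndex = edgeIndex, edgeFeatures = unname(edgeFeats))
}

#' Decompose a molecule into pharmacophore units
#'
#' Every SSSR ring becomes one `ring` unit; every bond not belonging to any
#' ring becomes one `acyclic_bond` unit together with its two atoms. In
#' fused ring systems a bond shared between two SSSR rings is assigned to
#' exactly one unit (the first ring in deterministic order), so the unit
#' bond sets always partition the molecule's bonds. An isolated bond-less
#' atom yields one degenerate unit holding just that atom.
#'
#' Units are ordered deterministically: ring units by their lowest atom
#' index, then acyclic units by bond index.
#'
#' @param mol A [Molecule-class].
#' @return A list of unit records `list(kind, atoms, bonds)` with sorted
#'   1-based index vectors.
#' @examples
#' \dontrun{
#' decomposePharmUnits(parseSmiles("Cc1ccccc1")[[1]])  # 1 ring + 1 acyclic
#' }
#' @export
decomposePharmUnits <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  nb <- nrow(mol@bonds)
  rings <- mol@ringAtoms
  ringBonds <- mol@ringBonds
  if (length(rings)) {
    ord <- order(vapply(rings, min, numeric(1)),
                 vapply(rings, function(r) paste(sort(r), collapse = ","),
                        character(1)))
    rings <- rings[ord]
    ringBonds <- ringBonds[ord]
  }
  units <- list()
  claimed <- logical(nb)
  for (k in seq_along(rings)) {
    bids <- sort(ringBonds[[k]])
    own <- bids[!claimed[bids]]   # fused bonds stay with the first ring
    claimed[bids] <- TRUE
    units[[length(units) + 1L]] <- list(kind = "ring",
                                        atoms = sort(rings[[k]]),
                                        bonds = own)
  }
  acyclic <- which(!claimed)
  for (b in acyclic) {
    units[[length(units) + 1L]] <- list(
      kind = "acyclic_bond",
      atoms = sort(c(mol@bonds$i[b], mol@bonds$j[b])),
      bonds = b)
  }
  covered <- unique(unlist(lapply(units, `[[`, "atoms")))
  lonely <- setdiff(seq_len(nrow(mol@atoms)), covered)
  for (a in lonely) {  # degenerate unit: isolated atom, no bonds
    units[[length(units) + 1L]] <- list(kind = "acyclic_bond",
                                        atoms = a, bonds = integer())
  }
  units
}

#' Featurize one pharmacophore unit
#'
#' Permutation-invariant aggregate of the unit's member atoms and bonds:
#' unit kind and size, aromatic fraction, mean degree, total formal charge,
#' sums and means of member-atom element one-hots, and counts of each bond
#' type. Invariant under any reordering of the molecule's atoms.
#'
#' @param unit A unit record from [decomposePharmUnits()].
#' @param mol The [Molecule-class] the unit belongs to.
#' @return A fixed-width numeric vector.
#' @export
featurizePharmNode <- function(unit, mol) {
  at <- mol@atoms[unit$atoms, , drop = FALSE]
  bd <- mol@bonds[unit$bonds, , drop = FALSE]
  elem <- .oneHot(at$element, .ATOM_VOCAB)
  btype <- if (nrow(bd)) colSums(.oneHot(bd$type, .BOND_TYPES))
           else numeric(length(.BOND_TYPES))
  c(atom_count = nrow(at),
    bond_count = nrow(bd),
    ring_flag = as.numeric(unit$kind == "ring"),
    aromatic_fraction = mean(as.numeric(at$aromatic)),
    mean_degree = mean(at$degree),
    total_charge = sum(at$charge),
    stats::setNames(colSums(elem), paste0("sum_", .ATOM_VOCAB)),
    stats::setNames(colMeans(elem), paste0("mean_", .ATOM_VOCAB)),
    stats::setNames(btype, paste0("bond_", .BOND_TYPES)))
}

#' Build the pharmacophore graph of a molecule
#'
#' Nodes are the units of [decomposePharmUnits()]; two units are adjacent
#' iff they share at least one atom. Node features come from
#' [featurizePharmNode()].
#'
#' @param mol A [Molecule-class].
#' @return A [PharmacophoreGraph-class].
#' @examples
#' \dontrun{
#' g <- buildPharmacophoreGraph(parseSmiles("c1ccccc1-c2ccccc2")[[1]])
#' length(pharmUnits(g))  # 3: two rings + the bridging bond
#' }
#' @export
buildPharmacophoreGraph <- function(mol) {
  units <- decomposePharmUnits(mol)
  u <- length(units)
  feats <- t(vapply(units, featurizePharmNode, mol = mol,
                    FUN.VALUE = featurizePharmNode(units[[1]], mol)))
  pairs <- matrix(integer(), 2, 0)
  if (u > 1) {
    for (a in seq_len(u - 1)) {
      for (b in seq((a + 1), u)) {
        if (length(intersect(units[[a]]$atoms, units[[b]]$atoms)))
          pairs <- cbind(pairs, c(a, b), c(b, a))
      }
    }
  }
  new("PharmacophoreGraph", smiles = mol@canonical, units = units,
      nodeFeatures = unname(feats), edgeIndex = pairs)
}

#' Featurize a compound into both graph views
#'
#' @param mol A [Molecule-class] (or a SMILES string, parsed on the fly).
#' @param provider Optional atom-embedding provider for the atom-bond view.
#' @return A [MolGraphPair-class].
#' @export
buildMolGraphPair <- function(mol, provider = NULL) {
  if (is.character(mol)) mol <- parseSmiles(mol)[[1]]
  new("MolGraphPair",
      atomBond = buildAtomBondGraph(mol, provider),
      pharm = buildPharmacophoreGraph(mol))
}

#' Serialize a graph view to JSON
#'
#' Debug/golden-file export of nodes, edges and features of either molecular
#' view or a residue contact graph. Indices are 1-based.
#'
#' @param graph An [AtomBondGraph-class], [PharmacophoreGraph-class] or
#'   [ResidueContactGraph-class].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
graphToJSON <- function(graph, path = NULL) {
  payload <- list(
    class = class(graph)[1],
    node_features = unname(nodeFeatures(graph)),
    edge_index = unname(edgeIndex(graph)))
  if (is(graph, "AtomBondGraph"))
    payload$edge_features <- unname(edgeFeatures(graph))
  if (is(graph, "ResidueContactGraph"))
    payload$edge_weights <- edgeWeights(graph)
  if (is(graph, "PharmacophoreGraph"))
    payload$units <- graph@units
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Mask atoms in the atom-bond view
#'
#' Zeroes the node feature rows of the given atoms in the atom-bond graph
#' (the pharmacophore view is left untouched). Used to probe how much a
#' prediction depends on particular atoms, e.g. when validating
#' attribution maps.
#'
#' @param pair A [MolGraphPair-class].
#' @param atomIdx Integer vector of 1-based atom indices to mask.
#' @return A modified [MolGraphPair-class].
#' @export
maskAtomFeatures <- function(pair, atomIdx) {
  stopifnot(is(pair, "MolGraphPair"))
  nf <- pair@atomBond@nodeFeatures
  atomIdx <- as.integer(atomIdx)
  if (any(atomIdx < 1L | atomIdx > nrow(nf)))
    stop("atom index out of range", call. = FALSE)
  nf[atomIdx, ] <- 0
  pair@atomBond@nodeFeatures <- nf
  pair
}
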