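# Handcrafted descriptor vocabularies, version 1.
#
# These are the offline fallback features used when no pre-trained embedding
# provider is attached: a fixed, versioned element vocabulary for atoms, a
# bond-type/stereo encoding for edges, and a residue table combining a
# 21-letter one-hot with four physicochemical scalars (Kyte-Doolittle
# hydropathy, net side-chain charge at pH 7, polarity flag, molecular weight).

.ATOM_VOCAB <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B",
                 "Si", "Se", "Na", "K", "other")
.CHIRALITY_LEVELS <- c("none", "cw", "ccw", "other")
.BOND_TYPES <- c("single", "double", "triple", "aromatic", "other")
.BOND_STEREO <- c("none", "z", "e", "cis", "trans", "other")

.oneHot <- function(x, levels) {
  x <- ifelse(x %in% levels, x, "other")
  m <- matrix(0, length(x), length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(x), match(x, levels))] <- 1
  m
}

# Amino-acid scalars: hydropathy (Kyte & Doolittle), charge at pH 7,
# polar side chain flag, residue molecular weight (Da).
.AA_TABLE <- local({
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  hydro <- c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
             3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2)
  charge <- c(0, 1, 0, -1, 0, 0, -1, 0, 0.5, 0,
              0, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  polar <- c(0, 1, 1, 1, 1, 1, 1, 0, 1, 0,
             0, 1, 0, 0, 0, 1, 1, 0, 1, 0)
  mw <- c(89.1, 174.2, 132.1, 133.1, 121.2, 146.2, 147.1, 75.1, 155.2,
          131.2, 131.2, 146.2, 149.2, 165.2, 115.1, 105.1, 119.1,
          204.2, 181.2, 117.1)
  data.frame(aa = aa, hydro = hydro, charge = charge, polar = polar,
             mw = mw, stringsAsFactors = FALSE)
})

.AA_ALPHABET <- c(.AA_TABLE$aa, "X")

# Per-atom fallback descriptor rows for a parsed molecule.
atomDescriptors <- function(mol) {
  at <- atoms(mol)
  cbind(
    .oneHot(at$element, .ATOM_VOCAB),
    degree = at$degree / 4,
    aromatic = as.numeric(at$aromatic),
    charge = at$charge,
    .oneHot(at$chirality, .CHIRALITY_LEVELS),
    in_ring = as.numeric(at$inRing)
  )
}

# Per-bond edge feature rows (one per chemical bond; duplicated per direction
# when the directed edge list is built).
bondDescriptors <- function(mol) {
  bd <- bonds(mol)
  if (nrow(bd) == 0L)
    return(matrix(0, 0L, length(.BOND_TYPES) + length(.BOND_STEREO) + 1L))
  cbind(
    .oneHot(bd$type, .BOND_TYPES),
    .oneHot(bd$stereo, .BOND_STEREO),
    in_ring = as.numeric(bd$inRing)
  )
}

#' Residue descriptor vector
#'
#' Fixed-width descriptor for one amino acid: a 21-way one-hot (20 standard
#' residues plus `X` for unknown) concatenated with hydropathy, charge,
#' polarity and molecular-weight scalars. Unknown residues get an `X` one-hot
#' and alphabet-average physicochemical values.
#'
#' @param aa Character vector of one-letter residue codes.
#' @return A numeric matrix with one row per input code; identical codes give
#'   identical rows.
#' @examples
#' residueDescriptor(c("A", "W", "X"))
#' @export
residueDescriptor <- function(aa) {
  if (!all(nchar(aa) == 1L))
    stop("residue codes must be single letters", call. = FALSE)
  aa <- toupper(aa)
  bad <- setdiff(unique(aa), .AA_ALPHABET)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  oneHot <- .oneHot(aa, .AA_ALPHABET)
  idx <- match(aa, .AA_TABLE$aa)
  defaults <- colMeans(.AA_TABLE[, c("hydro", "charge", "polar", "mw")])
  scal <- t(vapply(idx, function(i) {
    if (is.na(i)) defaults
    else unlist(.AA_TABLE[i, c("hydro", "charge", "polar", "mw")])
  }, numeric(4)))
  scal[, "mw"] <- scal[, "mw"] / 150  # keep scalars on comparable scale
  cbind(oneHot, scal)
}
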