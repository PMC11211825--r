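# Weighted residue contact graph and sequence-level pooling.

.checkSequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(letters1), .AA_ALPHABET)
  if (length(bad))
    stop("sequence contains non-amino-acid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  letters1
}

#' Build a weighted residue contact graph
#'
#' Each residue is a node; an undirected edge is created wherever the
#' contact probability strictly exceeds `threshold` (0.5 by default — a
#' probability of exactly 0.5 is *not* a contact), and the probability
#' itself becomes the edge weight. Provider matrices that are not exactly
#' symmetric are symmetrized by the elementwise maximum before
#' thresholding, so the graph is invariant under transposition of the
#' input. The diagonal is ignored (no self-contacts).
#'
#' @param sequence Amino-acid string over the 20-letter alphabet plus `X`.
#' @param contactProbs L x L numeric matrix of contact probabilities in
#'   `[0, 1]`, L = sequence length.
#' @param threshold Strict probability cut-off; default 0.5.
#' @return A [ResidueContactGraph-class] with residue-descriptor node
#'   features.
#' @examples
#' p <- matrix(0.1, 3, 3); p[1, 3] <- p[3, 1] <- 0.9
#' g <- buildContactGraph("ACD", p)
#' edgeIndex(g)    # one undirected contact: residues 1-3
#' edgeWeights(g)  # 0.9, 0.9
#' @export
buildContactGraph <- function(sequence, contactProbs, threshold = 0.5) {
  letters1 <- .checkSequence(sequence)
  L <- length(letters1)
  if (!is.matrix(contactProbs) || nrow(contactProbs) != ncol(contactProbs))
    stop("'contactProbs' must be a square matrix", call. = FALSE)
  if (nrow(contactProbs) != L)
    stop(sprintf("contact matrix is %d x %d but the sequence has %d residues",
                 nrow(contactProbs), ncol(contactProbs), L), call. = FALSE)
  if (any(!is.finite(contactProbs)) ||
      any(contactProbs < 0 | contactProbs > 1))
    stop("contact probabilities must be finite and in [0, 1]", call. = FALSE)

  p <- pmax(contactProbs, t(contactProbs))
  hits <- which(upper.tri(p) & p > threshold, arr.ind = TRUE)
  if (nrow(hits)) {
    w <- p[hits]
    edgeIndex <- rbind(c(rbind(hits[, 1], hits[, 2])),
                       c(rbind(hits[, 2], hits[, 1])))
    weights <- rep(w, each = 2L)
  } else {
    edgeIndex <- matrix(integer(), 2, 0)
    weights <- numeric()
  }
  new("ResidueContactGraph",
      sequence = paste(letters1, collapse = ""),
      nodeFeatures = unname(residueDescriptor(letters1)),
      edgeIndex = edgeIndex, edgeWeights = weights, threshold = threshold)
}

#' Pool residue embeddings into a sequence-level embedding
#'
#' Column-wise mean over residue positions, yielding one fixed-width vector
#' per protein regardless of length.
#'
#' @param residueEmbs L x E numeric matrix of residue-level embeddings.
#' @return Numeric vector of length E.
#' @examples
#' poolSequenceEmbedding(rbind(c(1, 2), c(3, 4)))  # c(2, 3)
#' @export
poolSequenceEmbedding <- function(residueEmbs) {
  if (!is.matrix(residueEmbs) || nrow(residueEmbs) < 1L)
    stop("'residueEmbs' must be a matrix with at least one row",
         call. = FALSE)
  if (any(!is.finite(residueEmbs)))
    stop("residue embeddings must be finite", call. = FALSE)
  colMeans(residueEmbs)
}

#' Read protein sequences from a FASTA file
#'
#' Minimal reader for plain (uncompressed) FASTA; returns a named character
#' vector keyed by the first token of each header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
readFasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  headers <- grepl("^>", lines)
  if (!any(headers) || !headers[1])
    stop("not a FASTA file: ", path, call. = FALSE)
  id <- sub("^>\\s*(\\S+).*$", "\\1", lines[headers])
  grp <- cumsum(headers)
  seqs <- vapply(split(lines[!headers], grp[!headers]),
                 paste, character(1), collapse = "")
  stats::setNames(toupper(unname(seqs)), id)
}
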