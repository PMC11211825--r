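# Benchmark-layout readers and writers. The on-disk layout follows the
# common affinity-benchmark convention: a JSON ligand map (compound ID ->
# SMILES), a JSON protein map (target ID -> sequence) and a dense affinity
# matrix (rows = compounds, columns = targets) with empty cells for
# unmeasured pairs. All files are plain text.

.newDTADataset <- function(ligands, proteins, affinity, metadata = list()) {
  keep <- which(!is.na(affinity), arr.ind = TRUE)
  records <- data.frame(
    drug_id = names(ligands)[keep[, 1]],
    target_id = names(proteins)[keep[, 2]],
    affinity = affinity[keep],
    stringsAsFactors = FALSE)
  new("DTADataset", ligands = ligands, proteins = proteins,
      affinity = affinity, records = records, metadata = metadata)
}

#' Construct a DTADataset
#'
#' @param ligands Named character vector, compound ID -> SMILES.
#' @param proteins Named character vector, target ID -> sequence.
#' @param affinity Numeric matrix (compounds x targets); `NA` marks an
#'   unmeasured pair. Records are flattened from the non-missing cells.
#' @param metadata Optional provenance list.
#' @return A [DTADataset-class].
#' @export
DTADataset <- function(ligands, proteins, affinity, metadata = list()) {
  if (is.null(names(ligands)) || is.null(names(proteins)))
    stop("ligand and protein tables must be named", call. = FALSE)
  affinity <- as.matrix(affinity)
  if (!all(dim(affinity) == c(length(ligands), length(proteins))))
    stop("affinity matrix must be compounds x targets", call. = FALSE)
  dimnames(affinity) <- list(names(ligands), names(proteins))
  .newDTADataset(ligands, proteins, affinity, metadata)
}

#' Load a benchmark affinity dataset from disk
#'
#' Expects `ligands.json`, `proteins.json` and `affinity.csv` in
#' `directory`. The CSV holds the dense matrix with compound IDs as row
#' names and target IDs as column names; empty cells / `NA` mark missing
#' measurements. For `name = "davis"` (or `transform = "pkd"`) raw Kd
#' values in nM are converted to `pKd = -log10(Kd / 1e9)`, the transformed
#' scale the affinity-regression literature trains on.
#'
#' @param directory Dataset directory.
#' @param name Dataset name; `"davis"` switches on the pKd transform.
#' @param transform `"auto"` (from `name`), `"pkd"` or `"none"`.
#' @return A [DTADataset-class].
#' @export
loadDTADataset <- function(directory, name = "dataset",
                           transform = c("auto", "pkd", "none")) {
  transform <- match.arg(transform)
  need <- file.path(directory, c("ligands.json", "proteins.json",
                                 "affinity.csv"))
  missing1 <- need[!file.exists(need)]
  if (length(missing1))
    stop("missing dataset file(s): ", paste(basename(missing1),
                                            collapse = ", "), call. = FALSE)
  ligands <- unlist(jsonlite::fromJSON(need[1]))
  proteins <- unlist(jsonlite::fromJSON(need[2]))
  aff <- as.matrix(read.csv(need[3], row.names = 1, check.names = FALSE))
  if (!setequal(rownames(aff), names(ligands)) ||
      !setequal(colnames(aff), names(proteins)))
    stop("affinity matrix IDs do not resolve in the ligand/protein tables",
         call. = FALSE)
  aff <- aff[names(ligands), names(proteins), drop = FALSE]
  doPkd <- transform == "pkd" ||
    (transform == "auto" && identical(tolower(name), "davis"))
  if (doPkd) aff <- -log10(aff / 1e9)
  ds <- .newDTADataset(ligands, proteins, aff,
                       metadata = list(name = name, pkdTransform = doPkd))
  message(sprintf("loaded '%s': %d compounds, %d targets, %d records",
                  name, length(ligands), length(proteins),
                  nrow(ds@records)))
  ds
}

#' Write a dataset in the benchmark layout
#'
#' Inverse of [loadDTADataset()] (no affinity transform is applied);
#' writing and re-loading with `transform = "none"` reproduces the record
#' set exactly.
#'
#' @param dataset A [DTADataset-class].
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
writeDTADataset <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(as.list(dataset@ligands),
                       file.path(directory, "ligands.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(as.list(dataset@proteins),
                       file.path(directory, "proteins.json"),
                       auto_unbox = TRUE)
  write.csv(dataset@affinity, file.path(directory, "affinity.csv"))
  invisible(directory)
}

#' Load drug-protein interaction pairs
#'
#' Reads a delimited file with columns `smiles`, `sequence`, `label`
#' (0/1). When `negRatio` is given, negatives are down-sampled (seeded) to
#' the requested positive:negative ratio, e.g. `negRatio = 3` keeps three
#' negatives per positive; an exact subsample must be possible.
#'
#' @param path Path to a tab- or comma-separated file with a header.
#' @param negRatio Optional negatives-per-positive ratio.
#' @param seed Seed for the subsample.
#' @return `data.frame` with columns `smiles`, `sequence`, `label`.
#' @export
loadDPIPairs <- function(path, negRatio = NULL, seed = 1L) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE)
  need <- c("smiles", "sequence", "label")
  if (!all(need %in% names(df)))
    stop("DPI file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$label %in% c(0, 1)))
    stop("DPI labels must be 0/1", call. = FALSE)
  if (!is.null(negRatio)) {
    pos <- which(df$label == 1)
    neg <- which(df$label == 0)
    wanted <- length(pos) * negRatio
    if (wanted > length(neg))
      stop(sprintf(
        "cannot reach 1:%g ratio: %d positives but only %d negatives",
        negRatio, length(pos), length(neg)), call. = FALSE)
    keepNeg <- if (wanted == length(neg)) neg
               else withSeed(seed, sample(neg, wanted))
    df <- df[sort(c(pos, keepNeg)), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Convert DPI pairs to a dataset
#'
#' Assigns IDs to the unique compounds and proteins of a pair list and
#' packs the 0/1 labels into the affinity matrix (unobserved combinations
#' stay missing), so the same training machinery drives both tasks.
#'
#' @param pairs `data.frame` from [loadDPIPairs()].
#' @return A [DTADataset-class] whose records carry the binary labels.
#' @export
dpiToDataset <- function(pairs) {
  smiles <- unique(pairs$smiles)
  seqs <- unique(pairs$sequence)
  ligands <- stats::setNames(smiles, sprintf("D%04d", seq_along(smiles)))
  proteins <- stats::setNames(seqs, sprintf("T%04d", seq_along(seqs)))
  aff <- matrix(NA_real_, length(ligands), length(proteins),
                dimnames = list(names(ligands), names(proteins)))
  di <- match(pairs$smiles, smiles)
  pj <- match(pairs$sequence, seqs)
  # duplicated (drug, protein) pairs keep the last label seen
  aff[cbind(di, pj)] <- pairs$label
  .newDTADataset(ligands, proteins, aff, metadata = list(task = "dpi"))
}
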