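# SMILES parsing through the bundled RDKit helper script. Parsing is done in
# batches (one interpreter start per call) and memoised per session, so test
# suites and screening runs pay the interpreter cost once per unique SMILES
# set, not per molecule.

.parseCache <- new.env(parent = emptyenv())

pythonBin <- function() {
  bin <- getOption("dtafuse.python", "")
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin))
    stop("no python interpreter found; set options(dtafuse.python=...)",
         call. = FALSE)
  bin
}

molToolsScript <- function() {
  p <- system.file("python", "mol_tools.py", package = "dtafuse")
  if (!nzchar(p))
    stop("mol_tools.py helper not found in the installed package",
         call. = FALSE)
  p
}

runMolTools <- function(command, lines) {
  infile <- tempfile(fileext = ".txt")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)))
  writeLines(lines, infile)
  status <- system2(pythonBin(), c(molToolsScript(), command, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(outfile))
    stop("RDKit helper failed (command: ", command, ")", call. = FALSE)
  jsonlite::fromJSON(readLines(outfile, warn = FALSE), simplifyVector = FALSE)
}

.moleculeFromRecord <- function(rec) {
  atoms <- do.call(rbind, lapply(rec$atoms, function(a) {
    data.frame(element = a$element, degree = a$degree,
               aromatic = a$aromatic, charge = a$charge,
               chirality = a$chirality, inRing = a$in_ring,
               stringsAsFactors = FALSE)
  }))
  if (is.null(atoms))
    atoms <- data.frame(element = character(), degree = integer(),
                        aromatic = logical(), charge = integer(),
                        chirality = character(), inRing = logical())
  bonds <- do.call(rbind, lapply(rec$bonds, function(b) {
    data.frame(i = b$i + 1L, j = b$j + 1L, type = b$type,
               stereo = b$stereo, inRing = b$in_ring,
               stringsAsFactors = FALSE)
  }))
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), type = character(),
                        stereo = character(), inRing = logical())
  new("Molecule",
      smiles = rec$smiles,
      canonical = rec$canonical,
      atoms = atoms,
      bonds = bonds,
      ringAtoms = lapply(rec$ring_atoms, function(r) unlist(r) + 1L),
      ringBonds = lapply(rec$ring_bonds, function(r) unlist(r) + 1L))
}

#' Parse SMILES strings into Molecule objects
#'
#' Delegates parsing, aromaticity/chirality perception and SSSR ring
#' detection to RDKit (via the bundled helper script). Hydrogens stay
#' implicit; they are never graph nodes. Results are memoised for the
#' session, so repeated calls with the same strings are free.
#'
#' @param smiles Character vector of SMILES strings (non-empty).
#' @return A list of [Molecule-class] objects, one per input, in input order.
#' @examples
#' \dontrun{
#' mols <- parseSmiles(c("CC", "c1ccccc1"))
#' atoms(mols[[2]])
#' }
#' @export
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0L)
    stop("'smiles' must be a non-empty character vector", call. = FALSE)
  if (any(is.na(smiles) | !nzchar(smiles)))
    stop("empty SMILES string supplied", call. = FALSE)
  if (any(grepl("[\n\r]", smiles)))
    stop("SMILES strings must not contain newlines", call. = FALSE)

  todo <- unique(smiles[!vapply(smiles, exists, logical(1),
                                envir = .parseCache)])
  if (length(todo)) {
    recs <- runMolTools("parse", todo)
    for (k in seq_along(todo)) {
      rec <- recs[[k]]
      if (!is.null(rec$error))
        stop(sprintf("cannot parse SMILES '%s': %s", rec$smiles, rec$error),
             call. = FALSE)
      assign(todo[k], .moleculeFromRecord(rec), envir = .parseCache)
    }
  }
  lapply(smiles, get, envir = .parseCache)
}

#' Tanimoto similarity between compounds
#'
#' Morgan (ECFP4, radius 2, 2048 bits) fingerprint Tanimoto similarity,
#' computed with RDKit. Used by the screening workflow to check that
#' top-ranked hits are not mere structural duplicates.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Symmetric numeric matrix of pairwise similarities in `[0, 1]`
#'   with unit diagonal.
#' @export
tanimotoSimilarity <- function(smiles) {
  if (!is.character(smiles) || length(smiles) < 2L)
    stop("need at least two SMILES strings", call. = FALSE)
  out <- runMolTools("tanimoto", smiles)
  if (!is.null(out$error)) stop(out$error, call. = FALSE)
  m <- do.call(rbind, lapply(out$similarity, unlist))
  dimnames(m) <- list(smiles, smiles)
  m
}
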