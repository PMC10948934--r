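#' Read a penalty matrix from its TSV representation
#'
#' The on-disk dialect is a plain tab-separated file: a header row with a
#' leading `residue` column followed by the 19 position labels
#' `U1..U6,C1..C7,D1..D6`, then 20 data rows keyed by the one-letter
#' amino-acid code. Decimal point, no thousands separators — the format is
#' diff-able and opens in any spreadsheet.
#'
#' All structural problems (wrong dimension, duplicate residue rows, missing
#' cells, negative penalties, positions without a zero residue) are collected
#' and reported together, naming the offending row/column.
#'
#' @param path Path to the TSV file.
#' @param motifClass Motif class of the stored matrix.
#' @param name Matrix identifier; defaults to the file base name.
#' @param unknownPolicy Unknown-residue policy to attach (not stored on disk).
#' @return A validated [PenaltyMatrix-class].
#' @seealso [writePenaltyMatrix()], [ffatMatrixFile()]
#' @export
readPenaltyMatrix <- function(path, motifClass = c("conventional", "phospho"),
                              name = NULL,
                              unknownPolicy = c("max_penalty", "skip_window")) {
  motifClass <- match.arg(motifClass)
  unknownPolicy <- match.arg(unknownPolicy)
  if (!file.exists(path))
    stop("penalty matrix file not found: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("matrix file '", path, "' has no position columns")
  key <- names(df)[1L]
  residues <- as.character(df[[key]])
  if (anyDuplicated(residues))
    stop("duplicate residue row(s) in '", path, "': ",
         paste(unique(residues[duplicated(residues)]), collapse = ", "))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- residues
  missing_pos <- setdiff(FFAT_POSITIONS, colnames(mat))
  extra_pos <- setdiff(colnames(mat), FFAT_POSITIONS)
  missing_res <- setdiff(AA_ALPHABET20, residues)
  extra_res <- setdiff(residues, AA_ALPHABET20)
  errs <- character(0)
  if (length(missing_pos))
    errs <- c(errs, sprintf("missing position column(s): %s",
                            paste(missing_pos, collapse = ", ")))
  if (length(extra_pos))
    errs <- c(errs, sprintf("unexpected position column(s): %s",
                            paste(extra_pos, collapse = ", ")))
  if (length(missing_res))
    errs <- c(errs, sprintf("missing residue row(s): %s",
                            paste(missing_res, collapse = ", ")))
  if (length(extra_res))
    errs <- c(errs, sprintf("unexpected residue row(s): %s",
                            paste(extra_res, collapse = ", ")))
  if (length(errs))
    stop("invalid penalty matrix '", path, "':\n  ",
         paste(errs, collapse = "\n  "))
  # cell-level invariants are enforced by the class validity method, which
  # also enumerates every violation
  PenaltyMatrix(mat, motifClass = motifClass, name = name,
                unknownPolicy = unknownPolicy)
}

#' Write a penalty matrix in the TSV dialect
#'
#' Inverse of [readPenaltyMatrix()]: `readPenaltyMatrix(writePenaltyMatrix(m))`
#' reproduces the matrix cell for cell.
#'
#' @param m A [PenaltyMatrix-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePenaltyMatrix <- function(m, path) {
  stopifnot(is(m, "PenaltyMatrix"))
  p <- penalties(m)
  df <- data.frame(residue = rownames(p), p, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Paths to the matrices shipped with the package
#'
#' The package ships a default Phospho-FFAT penalty matrix and its derived
#' conventional counterpart. The shipped matrix is a synthetic construction
#' from the FFAT consensus (an acidic flanking tract around an
#' F-F/Y-rich core with a phospho-acceptor at core position 4), not a
#' transcription of any experimentally fitted matrix; its file name carries
#' the `synthetic` label. It satisfies the full scoring contract: the
#' phospho matrix gives S and T penalty 0 at C4, and [makeConventional()]
#' turns it into the conventional-class matrix (C4: S,T -> 4; D,E -> 0).
#'
#' @param class `"phospho"` or `"conventional"`.
#' @return File path to the requested matrix TSV.
#' @examples
#' m <- readPenaltyMatrix(ffatMatrixFile("phospho"), motifClass = "phospho")
#' penalties(m)[c("S", "T"), "C4"]
#' @export
ffatMatrixFile <- function(class = c("phospho", "conventional")) {
  class <- match.arg(class)
  fn <- switch(class,
    phospho = "ffat_phospho_synthetic.tsv",
    conventional = "ffat_conventional_synthetic.tsv")
  path <- system.file("extdata", fn, package = "vapTriage", mustWork = TRUE)
  path
}

#' Load the shipped matrix pair
#'
#' Convenience wrapper returning both default matrices, keyed by motif class,
#' in the form expected by [scanProteome()].
#'
#' @return A named list with elements `conventional` and `phospho`.
#' @export
defaultMatrixPair <- function() {
  list(
    conventional = readPenaltyMatrix(ffatMatrixFile("conventional"),
                                     motifClass = "conventional"),
    phospho = readPenaltyMatrix(ffatMatrixFile("phospho"),
                                motifClass = "phospho")
  )
}
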