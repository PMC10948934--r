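#' @import methods
NULL

#' Canonical amino-acid alphabet and window architecture
#'
#' The scoring model works on 19-residue windows: six upstream flank
#' positions (U1-U6), a seven-residue core (C1-C7) and six downstream flank
#' positions (D1-D6). `AA_ALPHABET20` is the canonical 20-letter amino-acid
#' alphabet, alphabetically ordered; `FFAT_POSITIONS` the ordered window
#' position labels.
#'
#' @format Character vectors of length 20 and 19.
#' @name ffat-constants
#' @aliases AA_ALPHABET20 FFAT_POSITIONS
#' @export AA_ALPHABET20 FFAT_POSITIONS
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

FFAT_POSITIONS <- c(paste0("U", 1:6), paste0("C", 1:7), paste0("D", 1:6))

.MOTIF_CLASSES <- c("conventional", "phospho")
.UNKNOWN_POLICIES <- c("max_penalty", "skip_window")

#' PenaltyMatrix: a penalty-based position weight matrix for FFAT scoring
#'
#' A `PenaltyMatrix` holds, for one motif class (conventional FFAT or
#' Phospho-FFAT), a non-negative penalty for each of the 19 window positions
#' x 20 canonical residues. A window's score is the sum of the 19 per-position
#' penalties of its residues; lower is better and an ideal sequence scores
#' exactly zero, which the class guarantees by requiring at least one
#' zero-penalty residue at every position.
#'
#' @slot name Identifier string for the matrix.
#' @slot motifClass Either `"conventional"` or `"phospho"`.
#' @slot penalties Numeric 20 x 19 matrix; rows named by the canonical
#'   amino-acid one-letter codes (alphabetical), columns by the window
#'   position labels `U1..U6, C1..C7, D1..D6`.
#' @slot unknownPolicy How non-canonical residues (X, B, Z, U, O) are scored:
#'   `"max_penalty"` charges the position's column maximum (conservative; the
#'   default), `"skip_window"` drops any window containing one.
#'
#' @seealso [readPenaltyMatrix()], [makeConventional()], [idealSequence()]
#' @export
setClass("PenaltyMatrix",
  representation(
    name = "character",
    motifClass = "character",
    penalties = "matrix",
    unknownPolicy = "character"
  )
)

.validPenaltyMatrix <- function(object) {
  errs <- character(0)
  p <- object@penalties
  if (length(object@name) != 1L || is.na(object@name))
    errs <- c(errs, "'name' must be a single string")
  if (length(object@motifClass) != 1L ||
      !object@motifClass %in% .MOTIF_CLASSES)
    errs <- c(errs, sprintf("'motifClass' must be one of: %s",
                            paste(.MOTIF_CLASSES, collapse = ", ")))
  if (length(object@unknownPolicy) != 1L ||
      !object@unknownPolicy %in% .UNKNOWN_POLICIES)
    errs <- c(errs, sprintf("'unknownPolicy' must be one of: %s",
                            paste(.UNKNOWN_POLICIES, collapse = ", ")))
  if (!is.numeric(p)) {
    errs <- c(errs, "'penalties' must be a numeric matrix")
    return(errs)
  }
  if (!identical(dim(p), c(20L, 19L))) {
    errs <- c(errs, sprintf(
      "'penalties' must be 20 residues x 19 positions, got %d x %d",
      nrow(p), ncol(p)))
  }
  rn <- rownames(p)
  cn <- colnames(p)
  if (is.null(rn) || anyDuplicated(rn))
    errs <- c(errs, "duplicate or missing residue row names")
  missing_res <- setdiff(AA_ALPHABET20, rn)
  if (length(missing_res))
    errs <- c(errs, sprintf("missing residue row(s): %s",
                            paste(missing_res, collapse = ", ")))
  extra_res <- setdiff(rn, AA_ALPHABET20)
  if (length(extra_res))
    errs <- c(errs, sprintf("unexpected residue row(s): %s",
                            paste(extra_res, collapse = ", ")))
  missing_pos <- setdiff(FFAT_POSITIONS, cn)
  if (length(missing_pos))
    errs <- c(errs, sprintf("missing position column(s): %s",
                            paste(missing_pos, collapse = ", ")))
  extra_pos <- setdiff(cn, FFAT_POSITIONS)
  if (length(extra_pos))
    errs <- c(errs, sprintf("unexpected position column(s): %s",
                            paste(extra_pos, collapse = ", ")))
  if (!length(errs)) {
    na_cells <- which(is.na(p), arr.ind = TRUE)
    if (nrow(na_cells)) {
      errs <- c(errs, sprintf(
        "missing cell(s): %s",
        paste(sprintf("(%s,%s)", rownames(p)[na_cells[, 1]],
                      colnames(p)[na_cells[, 2]]), collapse = ", ")))
    } else {
      neg <- which(p < 0, arr.ind = TRUE)
      if (nrow(neg))
        errs <- c(errs, sprintf(
          "negative penalty at: %s",
          paste(sprintf("(%s,%s)", rownames(p)[neg[, 1]],
                        colnames(p)[neg[, 2]]), collapse = ", ")))
      no_zero <- colnames(p)[apply(p, 2, function(col) all(col > 0))]
      if (length(no_zero))
        errs <- c(errs, sprintf(
          "position(s) without a zero-penalty residue (ideal sequence could not score 0): %s",
          paste(no_zero, collapse = ", ")))
    }
  }
  if (length(errs)) errs else TRUE
}

setValidity("PenaltyMatrix", .validPenaltyMatrix)

#' Construct a PenaltyMatrix
#'
#' @param penalties Numeric 20 x 19 matrix with residue row names and window
#'   position column names (any row/column order; stored in canonical order).
#' @param motifClass `"conventional"` or `"phospho"`.
#' @param name Identifier string.
#' @param unknownPolicy `"max_penalty"` (default) or `"skip_window"`.
#' @return A validated [PenaltyMatrix-class] object.
#' @examples
#' p <- matrix(0, 20, 19, dimnames = list(AA_ALPHABET20, FFAT_POSITIONS))
#' m <- PenaltyMatrix(p, "conventional", "all_zero")
#' idealSequence(m)
#' @export
PenaltyMatrix <- function(penalties, motifClass = c("conventional", "phospho"),
                          name = "unnamed",
                          unknownPolicy = c("max_penalty", "skip_window")) {
  motifClass <- match.arg(motifClass)
  unknownPolicy <- match.arg(unknownPolicy)
  if (!is.matrix(penalties))
    stop("'penalties' must be a matrix")
  rn <- rownames(penalties)
  cn <- colnames(penalties)
  # reorder to canonical order when all labels are present
  if (!is.null(rn) && !is.null(cn) &&
      setequal(rn, AA_ALPHABET20) && setequal(cn, FFAT_POSITIONS) &&
      !anyDuplicated(rn) && !anyDuplicated(cn)) {
    penalties <- penalties[AA_ALPHABET20, FFAT_POSITIONS, drop = FALSE]
  }
  storage.mode(penalties) <- "double"
  new("PenaltyMatrix", name = name, motifClass = motifClass,
      penalties = penalties, unknownPolicy = unknownPolicy)
}

#' @describeIn PenaltyMatrix-class The 20 x 19 penalty matrix.
#' @param x,object A `PenaltyMatrix`.
#' @export
setGeneric("penalties", function(x) standardGeneric("penalties"))

#' @rdname PenaltyMatrix-class
#' @export
setMethod("penalties", "PenaltyMatrix", function(x) x@penalties)

#' @describeIn PenaltyMatrix-class The motif class of the matrix.
#' @export
setGeneric("motifClass", function(x) standardGeneric("motifClass"))

#' @rdname PenaltyMatrix-class
#' @export
setMethod("motifClass", "PenaltyMatrix", function(x) x@motifClass)

#' @describeIn PenaltyMatrix-class The matrix identifier.
#' @export
setGeneric("matrixName", function(x) standardGeneric("matrixName"))

#' @rdname PenaltyMatrix-class
#' @export
setMethod("matrixName", "PenaltyMatrix", function(x) x@name)

#' @describeIn PenaltyMatrix-class The unknown-residue scoring policy.
#' @export
setGeneric("unknownPolicy", function(x) standardGeneric("unknownPolicy"))

#' @rdname PenaltyMatrix-class
#' @export
setMethod("unknownPolicy", "PenaltyMatrix", function(x) x@unknownPolicy)

setMethod("show", "PenaltyMatrix", function(object) {
  cat(sprintf("PenaltyMatrix '%s' (%s class)\n",
              object@name, object@motifClass))
  cat("  19 positions (U1-U6 | C1-C7 | D1-D6) x 20 residues\n")
  cat(sprintf("  penalty range: [%g, %g]; unknown-residue policy: %s\n",
              min(object@penalties), max(object@penalties),
              object@unknownPolicy))
  cat(sprintf("  ideal sequence: %s\n", idealSequence(object)))
})

#' Derive the ideal (zero-scoring) 19-mer of a matrix
#'
#' At each window position the residue with penalty zero is chosen; when
#' several residues tie at zero the alphabetically first one-letter code
#' wins, so the result is deterministic. By construction the returned
#' 19-mer scores exactly 0 under [scoreWindow()].
#'
#' @param m A [PenaltyMatrix-class].
#' @return A 19-character string.
#' @export
setGeneric("idealSequence", function(m) standardGeneric("idealSequence"))

#' @rdname idealSequence
#' @export
setMethod("idealSequence", "PenaltyMatrix", function(m) {
  p <- m@penalties
  res <- vapply(seq_len(ncol(p)), function(j) {
    zeros <- rownames(p)[p[, j] == 0]
    sort(zeros)[1L]  # rows are already alphabetical; sort() guards reorder
  }, character(1))
  paste(res, collapse = "")
})

#' Transform a Phospho-FFAT matrix into a conventional-FFAT matrix
#'
#' The two motif classes differ only at the fourth core position (C4, window
#' position 10): the phospho class accepts the phosphorylatable residues S/T
#' there, while the conventional class wants an acidic residue. The transform
#' copies the phospho matrix and modifies C4 to assign penalty 4 to S and T
#' and penalty 0 to D and E; every other cell is untouched.
#'
#' @param m A [PenaltyMatrix-class] of class `"phospho"`.
#' @param name Name for the derived matrix; defaults to the input name with
#'   a `_conventional` suffix.
#' @return A valid `PenaltyMatrix` with `motifClass` `"conventional"`.
#' @examples
#' ph <- readPenaltyMatrix(ffatMatrixFile("phospho"), motifClass = "phospho")
#' cv <- makeConventional(ph)
#' penalties(cv)[c("S", "T", "D", "E"), "C4"]
#' @export
makeConventional <- function(m, name = NULL) {
  stopifnot(is(m, "PenaltyMatrix"))
  if (motifClass(m) != "phospho")
    stop("makeConventional() expects a phospho-class matrix, got '",
         motifClass(m), "'")
  p <- m@penalties
  p[c("S", "T"), "C4"] <- 4
  p[c("D", "E"), "C4"] <- 0
  if (is.null(name)) name <- paste0(m@name, "_conventional")
  PenaltyMatrix(p, motifClass = "conventional", name = name,
                unknownPolicy = m@unknownPolicy)
}
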