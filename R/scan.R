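#' Score one 19-residue window under a penalty matrix
#'
#' The score is the exact sum of the 19 per-position penalties looked up for
#' the window's residues — no rounding, no normalisation. Zero is ideal;
#' larger is worse. Residues outside the canonical 20 are handled according
#' to the matrix's unknown-residue policy: `"max_penalty"` charges the
#' position's column maximum, `"skip_window"` makes the whole window score
#' `NA` (such windows are dropped by [scanSequence()]).
#'
#' @param window A 19-character string of amino-acid letters (upper-cased
#'   internally).
#' @param m A [PenaltyMatrix-class].
#' @return A single non-negative number (or `NA` under `skip_window` when an
#'   unknown residue is present).
#' @examples
#' m <- readPenaltyMatrix(ffatMatrixFile("conventional"))
#' scoreWindow(idealSequence(m), m)  # 0
#' @export
scoreWindow <- function(window, m) {
  stopifnot(is(m, "PenaltyMatrix"))
  if (!is.character(window) || length(window) != 1L)
    stop("'window' must be a single string")
  window <- toupper(window)
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  if (length(chars) != 19L)
    stop("window must be exactly 19 residues, got ", length(chars))
  if (!all(grepl("^[A-Z]$", chars)))
    stop("window contains non-letter characters: ",
         paste(unique(chars[!grepl("^[A-Z]$", chars)]), collapse = ", "))
  p <- penalties(m)
  idx <- match(chars, AA_ALPHABET20)
  if (anyNA(idx)) {
    if (unknownPolicy(m) == "skip_window") return(NA_real_)
    colmax <- apply(p, 2, max)
    known <- !is.na(idx)
    s <- sum(p[cbind(idx[known], which(known))]) + sum(colmax[!known])
    return(s)
  }
  sum(p[cbind(idx, seq_len(19L))])
}

#' Scan a protein sequence: score every 19-residue window
#'
#' Enumerates all fully contained windows (no terminal padding: a protein of
#' length L has L - 18 windows; motifs within six residues of a terminus are
#' therefore undetectable — a documented limitation of the 19-residue model).
#' Returns one row per admissible window start, in ascending start order.
#' Coordinates are 1-based and refer to the protein; `core_start` is the
#' position of the first core residue (C1, i.e. `start + 6`).
#'
#' @param seq A single protein sequence (character string or
#'   [Biostrings::AAString]). `*` stop characters are stripped with a
#'   warning; lower case is accepted.
#' @param m A [PenaltyMatrix-class].
#' @param protein_id Identifier copied into the output rows.
#' @return A `data.frame` of motif hits with columns `protein_id`,
#'   `motif_class`, `start`, `core_start`, `window_seq`, `score`. A sequence
#'   shorter than 19 residues yields an empty frame with a warning, not an
#'   error.
#' @export
scanSequence <- function(seq, m, protein_id = "protein") {
  stopifnot(is(m, "PenaltyMatrix"))
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L) stop("'seq' must be a single sequence")
  if (grepl("*", seq, fixed = TRUE)) {
    warning("stripping '*' stop character(s) from ", protein_id)
    seq <- gsub("*", "", seq, fixed = TRUE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  empty <- data.frame(protein_id = character(0), motif_class = character(0),
                      start = integer(0), core_start = integer(0),
                      window_seq = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 19L) {
    warning("sequence '", protein_id, "' is shorter than 19 residues (",
            n, "); no windows scored")
    return(empty)
  }
  if (!all(grepl("^[A-Z]$", chars)))
    stop("sequence '", protein_id, "' contains non-letter characters")
  p <- penalties(m)
  idx <- match(chars, AA_ALPHABET20)
  unknown <- is.na(idx)
  skip <- unknownPolicy(m) == "skip_window"
  if (any(unknown) && !skip) {
    # augment with a virtual 21st residue row holding each column's maximum
    p <- rbind(p, apply(p, 2, max))
    idx[unknown] <- 21L
  }
  nwin <- n - 18L
  scores <- numeric(nwin)
  for (pos in 1:19) {
    scores <- scores + p[cbind(idx[pos:(pos + nwin - 1L)], pos)]
  }
  starts <- seq_len(nwin)
  if (any(unknown) && skip) {
    # a window is skipped when it covers any unknown residue
    bad <- unique(unlist(lapply(which(unknown), function(i)
      max(1L, i - 18L):min(nwin, i))))
    keep <- setdiff(starts, bad)
    starts <- keep
    scores <- scores[keep]
  }
  data.frame(
    protein_id = protein_id,
    motif_class = motifClass(m),
    start = as.integer(starts),
    core_start = as.integer(starts + 6L),
    window_seq = substring(seq, starts, starts + 18L),
    score = unname(scores),
    stringsAsFactors = FALSE
  )
}

#' Select the k best core-disjoint hits of one protein and motif class
#'
#' Hits are ranked by score (ascending), ties broken by smaller start
#' (N-terminal first). Hits are then accepted greedily, skipping any whose
#' seven-residue core interval (C1..C7, protein positions `core_start` to
#' `core_start + 6`) overlaps the core of an already accepted hit — without
#' this rule the shifted windows of a single strong motif would occupy every
#' slot. The result is sorted by score then start.
#'
#' @param hits A hit `data.frame` from [scanSequence()] (one protein, one
#'   motif class).
#' @param k Maximum number of hits to return (default 2, matching the
#'   "two best sequences per class" reporting convention).
#' @return Up to `k` rows of `hits`, with a `rank` column added.
#' @export
bestHits <- function(hits, k = 2L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("'k' must be a single integer >= 1")
  k <- as.integer(k)
  if (nrow(hits) == 0L) {
    out <- hits
    out$rank <- integer(0)
    return(out)
  }
  if (length(unique(hits$protein_id)) > 1L ||
      length(unique(hits$motif_class)) > 1L)
    stop("bestHits() expects hits from a single protein and motif class")
  ord <- order(hits$score, hits$start)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) >= k) break
    core_i <- hits$core_start[i] + 0:6
    overlaps <- any(vapply(chosen, function(j)
      abs(hits$core_start[i] - hits$core_start[j]) < 7L, logical(1)))
    if (!overlaps) chosen <- c(chosen, i)
  }
  out <- hits[chosen, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Is a motif score significant?
#'
#' The significance band is closed at both ends: scores in `[0, threshold]`
#' count, with the default threshold 2.5. Zero — the ideal-sequence score —
#' is always significant.
#'
#' @param score Non-negative score(s).
#' @param threshold Upper edge of the significance band (default 2.5).
#' @return Logical vector.
#' @export
classifySignificant <- function(score, threshold = 2.5) {
  if (any(is.na(score)))
    stop("NA score(s) cannot be classified")
  if (any(score < 0))
    stop("negative score(s): the penalty model cannot produce them")
  score >= 0 & score <= threshold
}

#' Scan a whole proteome for conventional and Phospho-FFAT motifs
#'
#' Scores every protein under both matrices and reports, per protein and
#' motif class, the best `top` core-disjoint hits (score, start, window
#' sequence) plus a per-protein significance call: a protein is significant
#' when the minimum over classes of its best score lies within
#' `[0, threshold]`.
#'
#' @param fasta Path to a FASTA file, or a [Biostrings::AAStringSet], or a
#'   named character vector of sequences.
#' @param matrices Named list with elements `conventional` and `phospho`
#'   ([PenaltyMatrix-class] each); defaults to the shipped pair.
#' @param threshold Significance threshold (default 2.5).
#' @param top Number of best hits reported per class (default 2).
#' @return A `data.frame`, one row per input protein in input order, with
#'   columns `protein_id`, then per class `<class>_score_<r>`,
#'   `<class>_start_<r>`, `<class>_seq_<r>` for r = 1..top, then
#'   `best_conventional`, `best_phospho` and logical `significant`. Proteins
#'   too short to hold a window get `NA` scores and are not significant.
#' @export
scanProteome <- function(fasta, matrices = defaultMatrixPair(),
                         threshold = 2.5, top = 2L) {
  seqs <- .asSequences(fasta)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record ID(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  stopifnot(all(c("conventional", "phospho") %in% names(matrices)))
  for (cl in c("conventional", "phospho")) {
    stopifnot(is(matrices[[cl]], "PenaltyMatrix"))
    if (motifClass(matrices[[cl]]) != cl)
      stop("matrix supplied as '", cl, "' has motifClass '",
           motifClass(matrices[[cl]]), "'")
  }
  if (length(seqs) == 0L)
    warning("empty proteome: no records to scan")
  rows <- lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    row <- list(protein_id = id)
    best_by_class <- c(conventional = NA_real_, phospho = NA_real_)
    for (cl in c("conventional", "phospho")) {
      hits <- suppressWarnings(scanSequence(seqs[[i]], matrices[[cl]], id))
      bh <- bestHits(hits, k = top)
      for (r in seq_len(top)) {
        row[[sprintf("%s_score_%d", cl, r)]] <-
          if (r <= nrow(bh)) bh$score[r] else NA_real_
        row[[sprintf("%s_start_%d", cl, r)]] <-
          if (r <= nrow(bh)) bh$start[r] else NA_integer_
        row[[sprintf("%s_seq_%d", cl, r)]] <-
          if (r <= nrow(bh)) bh$window_seq[r] else NA_character_
      }
      if (nrow(bh)) best_by_class[cl] <- bh$score[1L]
    }
    row$best_conventional <- best_by_class[["conventional"]]
    row$best_phospho <- best_by_class[["phospho"]]
    best <- suppressWarnings(min(best_by_class, na.rm = TRUE))
    row$significant <- is.finite(best) && classifySignificant(best, threshold)
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(protein_id = character(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Coerce FASTA path / AAStringSet / named character vector to a named
# character vector of upper-cased sequences.
.asSequences <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta) &&
      is.null(names(fasta))) {
    return(readFasta(fasta))
  }
  if (is(fasta, "XStringSet")) {
    seqs <- toupper(as.character(fasta))
    names(seqs) <- sub("\\s.*$", "", names(fasta))
    return(seqs)
  }
  if (is.character(fasta)) {
    if (is.null(names(fasta)))
      stop("character input must be named by protein ID (or be a file path)")
    return(toupper(fasta))
  }
  stop("unsupported proteome input of class ", class(fasta)[1L])
}
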