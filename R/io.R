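#' Read a protein FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that applies the
#' pipeline's conventions: record IDs are the first whitespace-delimited
#' token of the header, order is preserved, sequences are upper-cased, and
#' duplicate IDs or empty sequences are errors. Wrapped and unwrapped
#' sequence lines parse identically (guaranteed by Biostrings).
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of protein sequences, in file order.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ID(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(aa) == 0L))
    stop("empty sequence(s) in '", path, "': ",
         paste(ids[Biostrings::width(aa) == 0L], collapse = ", "))
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

# Deterministic TSV writer shared by all table outputs: fixed column order
# as given, no quoting, no row names.
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a pipeline table as TSV
#'
#' All tabular outputs of the pipeline use one deterministic TSV dialect:
#' header row, tab separator, no quoting, `NA` for missing values.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) .writeTsv(df, path)

#' Read a PSM count table
#'
#' The long-format IP-MS evidence table has one row per (protein, bait,
#' condition) with columns `protein_id`, `description`, `bait`
#' (`VAP_A`/`VAP_B`), `condition` (`WT`/`MUT`), `score`, `coverage`,
#' `peptides`, `psm`. Counts must be non-negative integers; a protein absent
#' from a sample is an explicit 0 row, not a missing row (rows absent from
#' the file are filled with zeros when the table is widened).
#'
#' @param path Path to the TSV.
#' @return A validated long-format `data.frame`.
#' @export
readPsmTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "bait", "condition", "peptides", "psm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("PSM table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!all(df$bait %in% c("VAP_A", "VAP_B")))
    stop("unknown bait label(s): ",
         paste(setdiff(unique(df$bait), c("VAP_A", "VAP_B")), collapse = ", "))
  if (!all(df$condition %in% c("WT", "MUT")))
    stop("unknown condition label(s): ",
         paste(setdiff(unique(df$condition), c("WT", "MUT")), collapse = ", "))
  if (any(df$psm < 0) || any(df$psm != round(df$psm)))
    stop("PSM counts must be non-negative integers")
  if (any(df$peptides < 0))
    stop("peptide counts must be non-negative")
  df
}

#' Read an ortholog mapping table
#'
#' Maps human protein IDs to their best fly gene (CG number) with the
#' prediction score and a coverage flag. One best fly gene per human
#' protein; a duplicate human ID is an error. Unmapped proteins are simply
#' absent from the table.
#'
#' @param path TSV with columns `human_id`, `fly_cg`, `diopt_score`,
#'   `coverage_pct`.
#' @return A validated `data.frame` with an added logical `coverage_ok`
#'   column (`coverage_pct > 90`).
#' @export
readOrthologMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("human_id", "fly_cg", "diopt_score", "coverage_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ortholog map '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$human_id))
    stop("duplicate fly assignment(s) for human ID(s): ",
         paste(unique(df$human_id[duplicated(df$human_id)]), collapse = ", "))
  df$coverage_ok <- df$coverage_pct > 90
  df
}

#' Read a genetic-screen outcome table
#'
#' Line-level records of the RNAi modifier screen: one row per tested RNAi
#' line with columns `gene` (fly CG number), `line_id`, `source` (library),
#' `suppression` (`none`, `+` partial, `++` definite), `viable`
#' (logical: did the cross yield adults), and optional per-gene columns
#' `norpa` (logical: also suppresses the norpA degeneration background) and
#' `erg` (`normal`, `lower`, `higher`, `rough_eye`, `untested`).
#'
#' @param path Path to the TSV.
#' @return A validated `data.frame`.
#' @export
readScreenTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "line_id", "suppression")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("screen table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  ok_supp <- c("none", "+", "++")
  bad <- setdiff(unique(df$suppression), ok_supp)
  if (length(bad))
    stop("suppression grade(s) outside the vocabulary {none, +, ++}: ",
         paste(bad, collapse = ", "))
  if ("erg" %in% names(df)) {
    ok_erg <- c("normal", "lower", "higher", "rough_eye", "untested")
    bad <- setdiff(unique(df$erg), ok_erg)
    if (length(bad))
      stop("ERG outcome(s) outside the vocabulary: ",
           paste(bad, collapse = ", "))
  }
  if (!"viable" %in% names(df)) df$viable <- TRUE
  if (is.character(df$viable)) df$viable <- toupper(df$viable) == "TRUE"
  df
}
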