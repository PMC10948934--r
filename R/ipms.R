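#' WT-over-mutant PSM ratio score
#'
#' The enrichment statistic of the pull-down: the ratio of spectral counts
#' obtained with the WT bait over those obtained with the binding-dead
#' mutant bait, with a Laplace pseudocount added to both counts so that
#' proteins absent from the mutant sample get a large finite ratio rather
#' than infinity. Strictly increasing in `psm_wt`, strictly decreasing in
#' `psm_mut`; as the pseudocount tends to 0 the value tends to the raw
#' `psm_wt / psm_mut` ratio (when `psm_mut > 0`).
#'
#' @param psm_wt,psm_mut Non-negative integer spectral counts (vectorised).
#' @param pseudocount Positive pseudocount added to both counts (default 1).
#' @return Numeric ratio score(s).
#' @examples
#' ratioScore(9, 0)   # 10
#' ratioScore(0, 9)   # 0.1
#' @export
ratioScore <- function(psm_wt, psm_mut, pseudocount = 1) {
  if (any(psm_wt < 0) || any(psm_mut < 0))
    stop("PSM counts must be non-negative")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("'pseudocount' must be positive")
  (psm_wt + pseudocount) / (psm_mut + pseudocount)
}

# Widen the long PSM table for one bait into one row per protein with
# psm_wt / psm_mut / peptides_wt columns, filling absent samples with 0.
.widenPsm <- function(psm_table, bait) {
  sub <- psm_table[psm_table$bait == bait, , drop = FALSE]
  ids <- unique(psm_table$protein_id)
  wt <- sub[sub$condition == "WT", , drop = FALSE]
  mut <- sub[sub$condition == "MUT", , drop = FALSE]
  d <- data.frame(
    protein_id = ids,
    psm_wt = wt$psm[match(ids, wt$protein_id)],
    psm_mut = mut$psm[match(ids, mut$protein_id)],
    peptides_wt = wt$peptides[match(ids, wt$protein_id)],
    stringsAsFactors = FALSE
  )
  d$psm_wt[is.na(d$psm_wt)] <- 0L
  d$psm_mut[is.na(d$psm_mut)] <- 0L
  d$peptides_wt[is.na(d$peptides_wt)] <- 0L
  d
}

#' Select FFAT-dependent interactor candidates for one bait
#'
#' A protein is selected when its WT-over-mutant [ratioScore()] is at least
#' `ratio_min` and its WT peptide count is at least `peptide_min`. The
#' original ranking criteria (enrichment plus identification score) carry no
#' published numeric cutoffs, so the defaults (`ratio_min = 2`,
#' `peptide_min = 2`) are explicit, adjustable analysis parameters.
#' Selection is a pure function of the table contents: row order is
#' irrelevant.
#'
#' @param psm_table Long-format PSM table (see [readPsmTable()]).
#' @param bait `"VAP_A"` or `"VAP_B"`.
#' @param ratio_min Minimum ratio score (default 2).
#' @param peptide_min Minimum WT peptide count (default 2).
#' @param pseudocount Passed to [ratioScore()].
#' @return Character vector of selected `protein_id`s (sorted).
#' @export
selectCandidates <- function(psm_table, bait, ratio_min = 2, peptide_min = 2,
                             pseudocount = 1) {
  if (!bait %in% c("VAP_A", "VAP_B"))
    stop("unknown bait label: ", bait)
  wide <- .widenPsm(psm_table, bait)
  rs <- ratioScore(wide$psm_wt, wide$psm_mut, pseudocount)
  sel <- rs >= ratio_min & wide$peptides_wt >= peptide_min
  sort(wide$protein_id[sel])
}

#' Combine per-bait selections across VAP-A and VAP-B
#'
#' @param sel_A,sel_B Character vectors of selected protein IDs.
#' @return A list with `union`, `intersection` and a `membership`
#'   `data.frame` (`protein_id`, `bait_membership` in
#'   `A_only`/`B_only`/`both`) whose labels partition the union.
#' @export
combineBaits <- function(sel_A, sel_B) {
  sel_A <- unique(sel_A)
  sel_B <- unique(sel_B)
  u <- sort(union(sel_A, sel_B))
  i <- sort(intersect(sel_A, sel_B))
  membership <- ifelse(u %in% i, "both",
                       ifelse(u %in% sel_A, "A_only", "B_only"))
  list(
    union = u,
    intersection = i,
    membership = data.frame(protein_id = u, bait_membership = membership,
                            stringsAsFactors = FALSE)
  )
}

#' Annotate candidates with their FFAT significance
#'
#' Joins the motif-scan results onto a candidate set: a candidate is
#' FFAT-significant when the minimum of its best conventional and best
#' Phospho-FFAT scores is within `[0, threshold]`. Candidates missing from
#' the scan results are kept and flagged (`scanned = FALSE`), never dropped.
#'
#' @param candidates Character vector of protein IDs, or a `data.frame` with
#'   a `protein_id` column.
#' @param scan_results Output of [scanProteome()].
#' @param threshold Significance threshold (default 2.5).
#' @return A list with `table` (per-candidate `data.frame`: `protein_id`,
#'   `best_conventional`, `best_phospho`, `scanned`, `significant`) and
#'   `count_significant`.
#' @export
annotateFfat <- function(candidates, scan_results, threshold = 2.5) {
  ids <- if (is.data.frame(candidates)) candidates$protein_id else candidates
  ids <- as.character(ids)
  j <- match(ids, scan_results$protein_id)
  bc <- scan_results$best_conventional[j]
  bp <- scan_results$best_phospho[j]
  scanned <- !is.na(j)
  best <- pmin(bc, bp, na.rm = TRUE)
  significant <- !is.na(best) & best >= 0 & best <= threshold
  tab <- data.frame(
    protein_id = ids,
    best_conventional = bc,
    best_phospho = bp,
    scanned = scanned,
    significant = significant,
    stringsAsFactors = FALSE
  )
  list(table = tab, count_significant = sum(significant))
}
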