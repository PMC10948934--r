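#' Join candidates to their fly orthologs
#'
#' Annotates each candidate protein with its best fly gene from the ortholog
#' map. Unmapped candidates are kept with an explicit `mapped = FALSE` flag,
#' never dropped — the funnel accounting (how many of the pull-down
#' candidates are screenable in the fly) depends on seeing them.
#'
#' @param candidates Character vector of human protein IDs, or a
#'   `data.frame` with a `protein_id` column.
#' @param ortholog_map `data.frame` from [readOrthologMap()].
#' @return A list with `table` (per-candidate: `protein_id`, `fly_gene_id`,
#'   `diopt_score`, `mapped`) and `n_mapped`.
#' @export
joinOrthologs <- function(candidates, ortholog_map) {
  ids <- if (is.data.frame(candidates)) candidates$protein_id else candidates
  ids <- as.character(ids)
  if (anyDuplicated(ortholog_map$human_id))
    stop("ortholog map has duplicate fly assignment(s) for: ",
         paste(unique(ortholog_map$human_id[
       duplicated(ortholog_map$human_id)]), collapse = ", "))
  j <- match(ids, ortholog_map$human_id)
  tab <- data.frame(
    protein_id = ids,
    fly_gene_id = ortholog_map$fly_cg[j],
    diopt_score = ortholog_map$diopt_score[j],
    mapped = !is.na(j),
    stringsAsFactors = FALSE
  )
  list(table = tab, n_mapped = sum(tab$mapped))
}

#' Genes with an RNAi line available for screening
#'
#' @param records `data.frame` with columns `fly_gene_id` and logical
#'   `rnai_available`.
#' @return Sorted character vector of screenable fly gene IDs.
#' @export
screenableGenes <- function(records) {
  stopifnot(all(c("fly_gene_id", "rnai_available") %in% names(records)))
  sort(unique(records$fly_gene_id[records$rnai_available]))
}

#' Tabulate suppressors from line-level screen records
#'
#' Applies the screen's confirmation rule: a gene is a CONFIRMED suppressor
#' when at least two independent RNAi lines each scored positive (`+`
#' partial or `++` definite suppression). A gene with exactly one tested
#' line that scored positive is tabulated as a SINGLE-LINE suppressor
#' (`confirmed = FALSE`) — the published tabulation contains such entries
#' where no second line exists — so both classes enter the tabulated set,
#' carrying their confirmation status. Genes whose crosses produced no
#' adult flies are reported separately as `inviable` and take no part in
#' tabulation. Line order within a gene never matters.
#'
#' @param screen Line-level `data.frame` from [readScreenTable()].
#' @return A list with `table` (per-gene: `gene`, `n_lines`, `n_positive`,
#'   `suppressor`, `confirmed`), `suppressors` (sorted gene IDs),
#'   `confirmed` (sorted gene IDs) and `inviable` (sorted gene IDs).
#' @export
tabulateSuppressors <- function(screen) {
  stopifnot(all(c("gene", "line_id", "suppression") %in% names(screen)))
  if (!"viable" %in% names(screen)) screen$viable <- TRUE
  genes <- unique(screen$gene)
  inviable <- sort(unique(screen$gene[!screen$viable]))
  viable_rows <- screen[screen$viable, , drop = FALSE]
  per <- lapply(setdiff(genes, inviable), function(g) {
    rows <- viable_rows[viable_rows$gene == g, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("gene '", g, "' has zero tested lines in the screen table")
    npos <- sum(rows$suppression %in% c("+", "++"))
    data.frame(gene = g, n_lines = nrow(rows), n_positive = npos,
               suppressor = (npos >= 2L) || (nrow(rows) == 1L && npos == 1L),
               confirmed = npos >= 2L,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(per)) do.call(rbind, per) else
    data.frame(gene = character(0), n_lines = integer(0),
               n_positive = integer(0), suppressor = logical(0),
               confirmed = logical(0), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(
    table = tab,
    suppressors = sort(tab$gene[tab$suppressor]),
    confirmed = sort(tab$gene[tab$confirmed]),
    inviable = inviable
  )
}

#' Partition suppressors into effector and trigger-specific classes
#'
#' A suppressor that also suppresses degeneration in the independent
#' `norpA` background acts on the shared downstream degeneration machinery
#' (an EFFECTOR); one that does not is specific to the lesion that triggers
#' degeneration in the sensitised background (TRIGGER-SPECIFIC). The two
#' classes are disjoint and their union is the suppressor set.
#'
#' @param suppressors Character vector of suppressor gene IDs.
#' @param norpa_flags Named logical vector (names = gene IDs), or a
#'   `data.frame` with columns `gene` and `norpa`. Every suppressor must be
#'   covered.
#' @return A list with sorted character vectors `effectors` and
#'   `trigger_specific`.
#' @export
classifyTriggerEffector <- function(suppressors, norpa_flags) {
  if (is.data.frame(norpa_flags)) {
    flags <- norpa_flags$norpa
    names(flags) <- norpa_flags$gene
  } else flags <- norpa_flags
  if (is.character(flags)) flags <- toupper(flags) %in% c("TRUE", "YES")
  missing <- setdiff(suppressors, names(flags))
  if (length(missing))
    stop("norpA flag missing for gene(s): ", paste(missing, collapse = ", "))
  f <- flags[suppressors]
  list(
    effectors = sort(suppressors[f]),
    trigger_specific = sort(suppressors[!f])
  )
}

#' Flag suppressors with an abnormal electroretinogram
#'
#' A gene is flagged as a phototransduction candidate when its recorded ERG
#' outcome is `lower` or `higher` in every line where an ERG was recorded
#' (both lines when two were tested). Genes showing a rough-eye phenotype in
#' any line are reported in a separate `rough_eye` list and are never
#' flagged — a rough eye points at eye development, and a single measurable
#' line cannot satisfy the both-lines rule.
#'
#' @param suppressors Character vector of suppressor gene IDs.
#' @param erg_outcomes Line-level `data.frame` with columns `gene` and `erg`
#'   (`normal`, `lower`, `higher`, `rough_eye`, `untested`).
#' @return A list with `flagged` (`data.frame`: `gene`, `direction`) and
#'   `rough_eye` (sorted gene IDs).
#' @export
flagPhototransduction <- function(suppressors, erg_outcomes) {
  stopifnot(all(c("gene", "erg") %in% names(erg_outcomes)))
  eo <- erg_outcomes[erg_outcomes$gene %in% suppressors, , drop = FALSE]
  rough <- sort(unique(eo$gene[eo$erg == "rough_eye"]))
  flagged <- lapply(setdiff(unique(eo$gene), rough), function(g) {
    outc <- eo$erg[eo$gene == g]
    recorded <- outc[outc != "untested"]
    if (length(recorded) == 0L) return(NULL)
    if (all(recorded == "lower"))
      return(data.frame(gene = g, direction = "lower",
                        stringsAsFactors = FALSE))
    if (all(recorded == "higher"))
      return(data.frame(gene = g, direction = "higher",
                        stringsAsFactors = FALSE))
    NULL
  })
  flagged <- do.call(rbind, flagged)
  if (is.null(flagged))
    flagged <- data.frame(gene = character(0), direction = character(0),
                          stringsAsFactors = FALSE)
  flagged <- flagged[order(flagged$gene), , drop = FALSE]
  rownames(flagged) <- NULL
  list(flagged = flagged, rough_eye = rough)
}

#' Assemble the triage report
#'
#' Collects every stage count of the candidate funnel (pull-down candidates
#' -> fly orthologs -> screenable genes -> tabulated suppressors -> effector
#' vs trigger-specific partition -> ERG flags) into one record, checking the
#' internal consistency laws: the two suppressor classes partition the
#' suppressor set, and every ERG-flagged gene is a suppressor. Violations
#' are treated as pipeline bugs and abort.
#'
#' @param n_candidates Number of pull-down candidate proteins.
#' @param n_orthologs Number mapped to a fly gene.
#' @param n_screenable Number with an RNAi line available.
#' @param suppressors Character vector of tabulated suppressor genes.
#' @param confirmed Character vector of confirmed (two-line) suppressors.
#' @param effectors,trigger_specific The partition from
#'   [classifyTriggerEffector()].
#' @param erg_flagged `data.frame` from [flagPhototransduction()].
#' @param rough_eye Character vector of rough-eye genes.
#' @return A `triageReport` list (also printable) with all counts and gene
#'   lists.
#' @export
summaryReport <- function(n_candidates, n_orthologs, n_screenable,
                          suppressors, confirmed, effectors,
                          trigger_specific, erg_flagged,
                          rough_eye = character(0)) {
  if (!setequal(union(effectors, trigger_specific), suppressors) ||
      length(intersect(effectors, trigger_specific)))
    stop("internal inconsistency: effector/trigger classes do not ",
         "partition the suppressor set")
  if (!all(erg_flagged$gene %in% suppressors))
    stop("internal inconsistency: ERG-flagged gene(s) outside the ",
         "suppressor set: ",
         paste(setdiff(erg_flagged$gene, suppressors), collapse = ", "))
  rep <- list(
    n_candidates = n_candidates,
    n_orthologs = n_orthologs,
    n_screenable = n_screenable,
    n_suppressors = length(suppressors),
    n_confirmed = length(confirmed),
    n_effectors = length(effectors),
    n_trigger_specific = length(trigger_specific),
    n_erg_flagged = nrow(erg_flagged),
    suppressors = sort(suppressors),
    effectors = sort(effectors),
    trigger_specific = sort(trigger_specific),
    erg_flagged = erg_flagged,
    rough_eye = sort(rough_eye)
  )
  stopifnot(rep$n_trigger_specific == rep$n_suppressors - rep$n_effectors)
  class(rep) <- "triageReport"
  rep
}

#' @export
print.triageReport <- function(x, ...) {
  cat("VAP interactome screen triage\n")
  cat(sprintf("  candidates:            %d\n", x$n_candidates))
  cat(sprintf("  with fly ortholog:     %d\n", x$n_orthologs))
  cat(sprintf("  screenable (RNAi):     %d\n", x$n_screenable))
  cat(sprintf("  tabulated suppressors: %d (%d confirmed by 2 lines)\n",
              x$n_suppressors, x$n_confirmed))
  cat(sprintf("  effectors (norpA+):    %d\n", x$n_effectors))
  cat(sprintf("  trigger-specific:      %d\n", x$n_trigger_specific))
  cat(sprintf("  ERG-flagged:           %d (%s)\n", x$n_erg_flagged,
              paste(x$erg_flagged$gene, collapse = ", ")))
  if (length(x$rough_eye))
    cat(sprintf("  rough-eye (separate):  %s\n",
                paste(x$rough_eye, collapse = ", ")))
  invisible(x)
}

#' Write a triage report as TSV + text
#'
#' Emits `report_counts.tsv` (stage, count), `report_genes.tsv` (gene,
#' class, erg) and `report.txt` (the printed report) into a directory. The
#' per-gene TSV is sufficient to recompute every count.
#'
#' @param report A `triageReport` from [summaryReport()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTriageReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- data.frame(
    stage = c("candidates", "orthologs", "screenable", "suppressors",
              "confirmed", "effectors", "trigger_specific", "erg_flagged"),
    count = c(report$n_candidates, report$n_orthologs, report$n_screenable,
              report$n_suppressors, report$n_confirmed, report$n_effectors,
              report$n_trigger_specific, report$n_erg_flagged),
    stringsAsFactors = FALSE
  )
  genes <- data.frame(
    gene = report$suppressors,
    class = ifelse(report$suppressors %in% report$effectors,
                   "effector", "trigger_specific"),
    erg = ifelse(report$suppressors %in% report$erg_flagged$gene,
                 report$erg_flagged$direction[
                   match(report$suppressors, report$erg_flagged$gene)],
                 ifelse(report$suppressors %in% report$rough_eye,
                        "rough_eye", "normal")),
    stringsAsFactors = FALSE
  )
  .writeTsv(counts, file.path(dir, "report_counts.tsv"))
  .writeTsv(genes, file.path(dir, "report_genes.tsv"))
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); print(report); sink(); close(con)
  invisible(dir)
}
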