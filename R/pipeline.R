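#' Pipeline configuration
#'
#' Bundles every tunable of the candidate-identification pipeline with its
#' default: the 19-residue window model's significance threshold (2.5,
#' closed band), the enrichment selection cutoffs (ratio >= 2 on
#' pseudocounted PSM ratios, >= 2 WT peptides), and the best-2 reporting
#' depth. A config round-trips through YAML via [readPipelineConfig()] /
#' [writePipelineConfig()].
#'
#' @param fasta,psm,orthologs,screen Input file paths (any may be `NULL`;
#'   stages without inputs are skipped).
#' @param matrix_conventional,matrix_phospho Penalty matrix TSV paths
#'   (default: the shipped pair).
#' @param threshold Motif significance threshold (default 2.5).
#' @param ratio_min,peptide_min,pseudocount Enrichment selection parameters
#'   (defaults 2, 2, 1).
#' @param top Best hits reported per motif class (default 2).
#' @param seed Integer seed for any stage that randomises (default 1).
#' @param out_dir Output directory.
#' @return A `pipelineConfig` list.
#' @export
pipelineConfig <- function(fasta = NULL, psm = NULL, orthologs = NULL,
                           screen = NULL,
                           matrix_conventional = ffatMatrixFile("conventional"),
                           matrix_phospho = ffatMatrixFile("phospho"),
                           threshold = 2.5, ratio_min = 2, peptide_min = 2,
                           pseudocount = 1, top = 2, seed = 1,
                           out_dir = "vap_triage_out") {
  cfg <- list(fasta = fasta, psm = psm, orthologs = orthologs,
              screen = screen,
              matrix_conventional = matrix_conventional,
              matrix_phospho = matrix_phospho,
              threshold = threshold, ratio_min = ratio_min,
              peptide_min = peptide_min, pseudocount = pseudocount,
              top = top, seed = seed, out_dir = out_dir)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' @rdname pipelineConfig
#' @param config A `pipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full candidate-identification pipeline
#'
#' Orchestrates the stages in screen order — enrichment ranking, motif
#' scanning, FFAT annotation, ortholog joining, suppressor tabulation,
#' trigger/effector classification, report — over whichever inputs the
#' config provides, writing each stage's table plus a JSON manifest (input
#' hashes, echoed config, package version) into `out_dir`. Outputs are
#' deterministic: re-running with identical inputs reproduces identical
#' files. Any stage error aborts naming the stage.
#'
#' @param config A [pipelineConfig()].
#' @return The output directory path, invisibly; side effect: written files
#'   (`candidates.tsv`, `scan.tsv`, `report_counts.tsv`, `report_genes.tsv`,
#'   `report.txt`, `manifest.json`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  matrices <- .stage("matrices", list(
    conventional = readPenaltyMatrix(config$matrix_conventional,
                                     motifClass = "conventional"),
    phospho = readPenaltyMatrix(config$matrix_phospho,
                                motifClass = "phospho")))
  candidates <- NULL
  combined <- NULL
  if (!is.null(config$psm)) {
    psm <- .stage("rank", readPsmTable(config$psm))
    sel_A <- .stage("rank", selectCandidates(
      psm, "VAP_A", config$ratio_min, config$peptide_min,
      config$pseudocount))
    sel_B <- .stage("rank", selectCandidates(
      psm, "VAP_B", config$ratio_min, config$peptide_min,
      config$pseudocount))
    combined <- combineBaits(sel_A, sel_B)
    candidates <- combined$membership
  }
  scan_results <- NULL
  if (!is.null(config$fasta)) {
    scan_results <- .stage("scan", scanProteome(
      config$fasta, matrices, threshold = config$threshold,
      top = config$top))
    .writeTsv(scan_results, file.path(config$out_dir, "scan.tsv"))
  }
  annotated <- NULL
  if (!is.null(candidates) && !is.null(scan_results)) {
    annotated <- .stage("annotate", annotateFfat(
      candidates, scan_results, threshold = config$threshold))
    cand_out <- merge(candidates, annotated$table, by = "protein_id",
                      sort = TRUE)
    .writeTsv(cand_out, file.path(config$out_dir, "candidates.tsv"))
  } else if (!is.null(candidates)) {
    .writeTsv(candidates, file.path(config$out_dir, "candidates.tsv"))
  }
  joined <- NULL
  if (!is.null(candidates) && !is.null(config$orthologs)) {
    map <- .stage("join", readOrthologMap(config$orthologs))
    joined <- .stage("join", joinOrthologs(candidates, map))
  }
  report <- NULL
  if (!is.null(config$screen)) {
    screen <- .stage("tabulate", readScreenTable(config$screen))
    tab <- .stage("tabulate", tabulateSuppressors(screen))
    norpa <- if ("norpa" %in% names(screen)) {
      f <- tapply(screen$norpa, screen$gene, function(v) any(v %in%
        c(TRUE, "TRUE", "Yes", "yes")))
      stats::setNames(as.logical(f), names(f))
    } else stats::setNames(rep(FALSE, length(tab$suppressors)),
                           tab$suppressors)
    cls <- .stage("classify", classifyTriggerEffector(tab$suppressors, norpa))
    erg <- if ("erg" %in% names(screen)) {
      .stage("classify", flagPhototransduction(
        tab$suppressors, screen[, c("gene", "erg")]))
    } else list(flagged = data.frame(gene = character(0),
                                     direction = character(0)),
                rough_eye = character(0))
    screen_genes <- unique(screen$gene)
    report <- .stage("report", summaryReport(
      n_candidates = if (!is.null(candidates)) nrow(candidates) else
        length(screen_genes),
      n_orthologs = if (!is.null(joined)) joined$n_mapped else
        length(screen_genes),
      n_screenable = length(screen_genes),
      suppressors = tab$suppressors, confirmed = tab$confirmed,
      effectors = cls$effectors, trigger_specific = cls$trigger_specific,
      erg_flagged = erg$flagged, rough_eye = erg$rough_eye))
    writeTriageReport(report, config$out_dir)
  }
  .writeManifest(config)
  invisible(config$out_dir)
}

.writeManifest <- function(config) {
  inputs <- Filter(Negate(is.null),
                   config[c("fasta", "psm", "orthologs", "screen",
                            "matrix_conventional", "matrix_phospho")])
  hashes <- vapply(inputs, function(p)
    unname(tools::md5sum(p)), character(1))
  manifest <- list(
    package = "vapTriage",
    version = as.character(utils::packageVersion("vapTriage")),
    config = unclass(config)[!vapply(config, is.null, logical(1))],
    input_md5 = as.list(hashes)
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
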