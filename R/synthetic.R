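# Seeded synthetic inputs with machine-readable truth records. Each
# generator takes an explicit seed, restores the caller's RNG state on exit,
# and returns (data, truth) where the truth record is sufficient to decide
# pass/fail of every downstream stage without re-reading generator code.

.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Random valid toy penalty matrix
#'
#' Draws a structurally valid [PenaltyMatrix-class] for property-style
#' testing: per column, penalties are multiples of `granularity` in
#' `[0, max_penalty]`, with at least one residue forced to zero so the
#' ideal-sequence law holds.
#'
#' @param seed Integer seed.
#' @param motifClass Motif class label for the toy matrix.
#' @param granularity Penalty step size (default 0.5).
#' @param max_penalty Largest penalty (default 5).
#' @return A valid `PenaltyMatrix`.
#' @export
randomPenaltyMatrix <- function(seed, motifClass = "conventional",
                                granularity = 0.5, max_penalty = 5) {
  .withSeed(seed, {
    steps <- seq(0, max_penalty, by = granularity)
    p <- matrix(sample(steps, 20 * 19, replace = TRUE), 20, 19,
                dimnames = list(AA_ALPHABET20, FFAT_POSITIONS))
    for (j in seq_len(19)) p[sample(20, 1), j] <- 0
    PenaltyMatrix(p, motifClass = motifClass,
                  name = sprintf("toy_seed%d", as.integer(seed)))
  })
}

# Greedy exact-budget degradation: starting from the ideal 19-mer, apply
# substitutions (at most one per position) whose penalties sum exactly to
# `budget`. Cells are considered largest-first (ties: leftmost position,
# then alphabetical residue) so the construction is deterministic.
.degradeIdeal <- function(m, budget, eps = 1e-9) {
  p <- penalties(m)
  ideal <- strsplit(idealSequence(m), "")[[1L]]
  cells <- do.call(rbind, lapply(seq_len(19), function(j) {
    pen <- p[, j]
    keep <- pen > 0
    data.frame(pos = j, residue = rownames(p)[keep], penalty = pen[keep],
               stringsAsFactors = FALSE)
  }))
  cells <- cells[order(-cells$penalty, cells$pos, cells$residue), ]
  remaining <- budget
  used_pos <- integer(0)
  win <- ideal
  while (remaining > eps) {
    ok <- !(cells$pos %in% used_pos) & cells$penalty <= remaining + eps
    if (!any(ok))
      stop("degradation budget ", budget,
           " is unreachable with the available substitutions")
    i <- which(ok)[1L]
    win[cells$pos[i]] <- cells$residue[i]
    used_pos <- c(used_pos, cells$pos[i])
    remaining <- remaining - cells$penalty[i]
  }
  paste(win, collapse = "")
}

# All window scores of a character sequence under matrix m (no data.frame
# overhead; used by the generators' rejection checks).
.windowScores <- function(chars, m) {
  p <- penalties(m)
  idx <- match(chars, AA_ALPHABET20)
  nwin <- length(chars) - 18L
  s <- numeric(nwin)
  for (pos in 1:19) s <- s + p[cbind(idx[pos:(pos + nwin - 1L)], pos)]
  s
}

#' Generate a synthetic proteome with planted FFAT motifs
#'
#' Background residues are drawn uniformly over the 20 canonical amino
#' acids (or from a supplied composition). Planted motifs start from the
#' ideal sequence of their class matrix and are degraded by substitutions
#' whose penalties sum EXACTLY to `budget` (greedy over matrix cells), so
#' the truth record knows each planted window's score without tolerance.
#' Background is rejection-sampled until, under both matrices, every window
#' whose core does not overlap a planted core scores strictly above
#' `budget + margin`, and each planted window is the unique score minimum
#' among windows overlapping its core — planted hits are therefore unique
#' minima and exactly recoverable.
#'
#' @param n_proteins Number of proteins (default 100).
#' @param length_range Protein length range, inclusive (default 150-500).
#' @param n_planted_conventional,n_planted_phospho Numbers of proteins
#'   carrying one planted motif of each class (defaults 18 + 18; disjoint
#'   protein sets).
#' @param budget Total degradation penalty per planted motif (default 2).
#' @param matrix_pair Named list `conventional`/`phospho` of matrices
#'   (default: shipped pair).
#' @param seed Integer seed.
#' @param margin Safety margin above `budget` that background windows must
#'   exceed (default 3).
#' @param composition Optional length-20 probability vector over
#'   [AA_ALPHABET20] for background residues.
#' @return A list with `sequences` (named character vector), and `truth`: a
#'   list with `planted` (`data.frame`: `protein_id`, `motif_class`,
#'   `start`, `expected_score`), `n_significant` (proteins whose planted
#'   score is within the default significance band), `params` and `seed`.
#' @export
genProteome <- function(n_proteins = 100, length_range = c(150, 500),
                        n_planted_conventional = 18, n_planted_phospho = 18,
                        budget = 2, matrix_pair = defaultMatrixPair(),
                        seed = 1, margin = 3, composition = NULL) {
  n_planted <- n_planted_conventional + n_planted_phospho
  if (n_planted > n_proteins)
    stop("more planted motifs than proteins")
  if (budget < 0) stop("'budget' must be >= 0")
  if (is.null(composition)) composition <- rep(1 / 20, 20)
  stopifnot(length(composition) == 20)
  mats <- matrix_pair
  motif <- list(
    conventional = .degradeIdeal(mats$conventional, budget),
    phospho = .degradeIdeal(mats$phospho, budget)
  )
  .withSeed(seed, {
    planted_idx <- sample(n_proteins, n_planted)
    class_of <- rep(NA_character_, n_proteins)
    class_of[planted_idx[seq_len(n_planted_conventional)]] <- "conventional"
    if (n_planted_phospho > 0)
      class_of[planted_idx[n_planted_conventional + seq_len(n_planted_phospho)]] <-
        "phospho"
    ids <- sprintf("SYNP%04d", seq_len(n_proteins))
    seqs <- character(n_proteins)
    truth_rows <- list()
    for (i in seq_len(n_proteins)) {
      L <- sample(length_range[1]:length_range[2], 1)
      cl <- class_of[i]
      start <- if (!is.na(cl)) sample(L - 18L, 1) else NA_integer_
      for (attempt in 1:200) {
        chars <- sample(AA_ALPHABET20, L, replace = TRUE, prob = composition)
        if (!is.na(cl))
          chars[start:(start + 18L)] <- strsplit(motif[[cl]], "")[[1L]]
        if (.cleanBackground(chars, mats, start, cl, budget, margin)) break
        if (attempt == 200)
          stop("could not generate clean background for protein ", ids[i])
      }
      seqs[i] <- paste(chars, collapse = "")
      if (!is.na(cl))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          protein_id = ids[i], motif_class = cl, start = start,
          expected_score = budget, stringsAsFactors = FALSE)
    }
    names(seqs) <- ids
    planted <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(protein_id = character(0), motif_class = character(0),
                 start = integer(0), expected_score = numeric(0))
    list(
      sequences = seqs,
      truth = list(
        planted = planted,
        n_significant = if (budget <= 2.5) as.integer(n_planted) else 0L,
        params = list(n_proteins = n_proteins, length_range = length_range,
                      n_planted_conventional = n_planted_conventional,
                      n_planted_phospho = n_planted_phospho, budget = budget,
                      margin = margin),
        seed = as.integer(seed)
      )
    )
  })
}

# TRUE when, under both matrices, every window whose core is disjoint from
# the planted core scores > budget + margin, and (for the planted class)
# the planted start is the unique argmin among core-overlapping windows.
.cleanBackground <- function(chars, mats, start, cl, budget, margin) {
  nwin <- length(chars) - 18L
  starts <- seq_len(nwin)
  core <- if (!is.na(cl)) start + 6L else NA_integer_
  for (mcl in c("conventional", "phospho")) {
    s <- .windowScores(chars, mats[[mcl]])
    if (is.na(cl)) {
      if (any(s <= budget + margin)) return(FALSE)
      next
    }
    overlapping <- abs((starts + 6L) - core) < 7L
    if (any(s[!overlapping] <= budget + margin)) return(FALSE)
    if (mcl == cl) {
      ov <- s[overlapping]
      planted_pos <- which(starts[overlapping] == start)
      if (any(ov[-planted_pos] <= ov[planted_pos])) return(FALSE)
    }
  }
  TRUE
}

#' Generate a synthetic IP-MS PSM experiment
#'
#' Emulates the WT-versus-binding-dead-mutant pull-down structure: true
#' interactors draw spectral counts from Poisson(`lambda_wt`) in the WT
#' sample and Poisson(`lambda_mut`) in the mutant sample; background
#' proteins draw Poisson(`lambda_background`) in both. Counts are drawn
#' independently per bait (VAP_A, VAP_B) so union/intersection structure is
#' realisable. Peptide counts, identification score and coverage are derived
#' deterministically from the PSM count. Reproducible bit-for-bit for a
#' given seed.
#'
#' @param n_true,n_background Numbers of true interactors and background
#'   proteins (defaults 50, 200).
#' @param lambda_wt,lambda_mut,lambda_background Poisson rates (defaults
#'   20, 1, 10).
#' @param seed Integer seed.
#' @return A list with `psm_table` (long-format `data.frame`, see
#'   [readPsmTable()]) and `truth` (`true_ids`, `background_ids`, rates,
#'   seed).
#' @export
genPsmExperiment <- function(n_true = 50, n_background = 200,
                             lambda_wt = 20, lambda_mut = 1,
                             lambda_background = 10, seed = 1) {
  if (lambda_wt <= 0 || lambda_background <= 0 || lambda_mut < 0)
    stop("rates must be positive (lambda_mut may be 0)")
  .withSeed(seed, {
    true_ids <- sprintf("TRUE%04d", seq_len(n_true))
    bg_ids <- sprintf("BG%04d", seq_len(n_background))
    rows <- list()
    for (bait in c("VAP_A", "VAP_B")) {
      wt_true <- stats::rpois(n_true, lambda_wt)
      mut_true <- stats::rpois(n_true, lambda_mut)
      wt_bg <- stats::rpois(n_background, lambda_background)
      mut_bg <- stats::rpois(n_background, lambda_background)
      ids <- c(true_ids, bg_ids)
      wt <- c(wt_true, wt_bg)
      mut <- c(mut_true, mut_bg)
      for (cond in c("WT", "MUT")) {
        psm <- if (cond == "WT") wt else mut
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = ids,
          description = ifelse(ids %in% true_ids,
                               "synthetic true interactor",
                               "synthetic background"),
          bait = bait, condition = cond,
          score = round(psm * 2.5, 1),
          coverage = pmin(95, round(psm * 1.7, 1)),
          peptides = as.integer(ceiling(psm / 2)),
          psm = as.integer(psm),
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(
      psm_table = tab,
      truth = list(true_ids = true_ids, background_ids = bg_ids,
                   lambda_wt = lambda_wt, lambda_mut = lambda_mut,
                   lambda_background = lambda_background,
                   seed = as.integer(seed))
    )
  })
}

#' Generate a synthetic genetic-screen table
#'
#' Emits line-level screen records with planted structure: `n_suppressors`
#' genes suppress (of which `n_single_line` have only one RNAi line and the
#' rest two positive lines), `n_effectors` of the suppressors also suppress
#' the independent degeneration background (norpA flag), and
#' `n_erg_abnormal` of the trigger-specific suppressors show a consistent
#' abnormal electroretinogram in both lines (all `lower` except the last,
#' `higher`, when two or more are requested). Ten percent of non-suppressor
#' genes get one positive and one negative line, exercising the two-line
#' confirmation rule.
#'
#' @param n_genes Total genes screened (default 388).
#' @param n_suppressors Planted suppressors (default 52).
#' @param n_effectors Suppressors also flagged in the norpA background
#'   (default 13).
#' @param n_single_line Suppressors with only one RNAi line (default 3).
#' @param n_erg_abnormal Trigger-specific suppressors with an abnormal ERG
#'   (default 6).
#' @param seed Integer seed.
#' @return A list with `screen` (line-level `data.frame`: `gene`, `line_id`,
#'   `source`, `suppression`, `viable`, `norpa`, `erg`) and `truth`
#'   (planted gene sets and expected downstream counts).
#' @export
genScreenTables <- function(n_genes = 388, n_suppressors = 52,
                            n_effectors = 13, n_single_line = 3,
                            n_erg_abnormal = 6, seed = 1) {
  if (n_effectors > n_suppressors)
    stop("n_effectors cannot exceed n_suppressors")
  if (n_single_line > n_suppressors)
    stop("n_single_line cannot exceed n_suppressors")
  if (n_erg_abnormal > n_suppressors - n_effectors)
    stop("n_erg_abnormal cannot exceed the trigger-specific count")
  if (n_suppressors > n_genes)
    stop("n_suppressors cannot exceed n_genes")
  .withSeed(seed, {
    genes <- sprintf("SYNCG%04d", seq_len(n_genes))
    supp <- sort(sample(genes, n_suppressors))
    single <- sort(sample(supp, n_single_line))
    effect <- sort(sample(supp, n_effectors))
    trigger <- setdiff(supp, effect)
    erg_ab <- sort(sample(trigger, n_erg_abnormal))
    erg_dir <- stats::setNames(rep("lower", n_erg_abnormal), erg_ab)
    if (n_erg_abnormal >= 2) erg_dir[n_erg_abnormal] <- "higher"
    rows <- list()
    for (g in genes) {
      is_supp <- g %in% supp
      n_lines <- if (g %in% single) 1L else 2L
      if (is_supp) {
        grades <- sample(c("+", "++"), n_lines, replace = TRUE)
      } else {
        # 10% of non-suppressors have one positive, one negative line
        grades <- if (stats::runif(1) < 0.1) c("+", "none") else
          rep("none", n_lines)
      }
      erg <- if (g %in% erg_ab) rep(erg_dir[[g]], n_lines) else
        rep("normal", n_lines)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g,
        line_id = sprintf("%s_L%d", g, seq_len(n_lines)),
        source = sample(c("KK", "GD", "TRiP"), n_lines, replace = TRUE),
        suppression = grades,
        viable = TRUE,
        norpa = g %in% effect,
        erg = erg,
        stringsAsFactors = FALSE)
    }
    screen <- do.call(rbind, rows)
    rownames(screen) <- NULL
    list(
      screen = screen,
      truth = list(
        suppressors = supp, single_line = single, effectors = effect,
        trigger_specific = trigger, erg_abnormal = erg_ab,
        expected_counts = c(n_suppressors = n_suppressors,
                            n_effectors = n_effectors,
                            n_trigger_specific = n_suppressors - n_effectors,
                            n_erg_flagged = n_erg_abnormal),
        seed = as.integer(seed)
      )
    )
  })
}

#' Generate a synthetic ortholog map
#'
#' Maps a fraction of candidate protein IDs to invented fly CG numbers with
#' high coverage, leaving the rest unmapped — the structure needed to test
#' the ortholog-join bookkeeping.
#'
#' @param candidate_ids Character vector of human protein IDs.
#' @param n_mapped How many of them get a fly gene (default: all but 8).
#' @param seed Integer seed.
#' @return A list with `map` (`data.frame`: `human_id`, `fly_cg`,
#'   `diopt_score`, `coverage_pct`) and `truth` (`mapped_ids`).
#' @export
genOrthologMap <- function(candidate_ids,
                           n_mapped = max(0L, length(candidate_ids) - 8L),
                           seed = 1) {
  if (n_mapped > length(candidate_ids))
    stop("n_mapped exceeds the number of candidates")
  .withSeed(seed, {
    mapped <- sort(sample(candidate_ids, n_mapped))
    map <- data.frame(
      human_id = mapped,
      fly_cg = sprintf("SYNCG%04d", seq_len(n_mapped)),
      diopt_score = sample(5:15, n_mapped, replace = TRUE),
      coverage_pct = round(stats::runif(n_mapped, 91, 100), 1),
      stringsAsFactors = FALSE)
    list(map = map, truth = list(mapped_ids = mapped,
                                 seed = as.integer(seed)))
  })
}

#' Write a truth record as JSON
#'
#' @param truth A truth record list from one of the generators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruthRecord <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
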