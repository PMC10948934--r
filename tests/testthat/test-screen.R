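# Ortholog joining, suppressor tabulation, trigger/effector partition,
# ERG flagging and the triage report.

test_that("joinOrthologs counts mapped candidates and flags the rest", {
  cand <- sprintf("H%02d", 1:10)
  gom <- genOrthologMap(cand, n_mapped = 7, seed = 3)
  jo <- joinOrthologs(cand, gom$map)
  expect_identical(jo$n_mapped, 7L)
  expect_identical(sort(jo$table$protein_id[jo$table$mapped]),
                   gom$truth$mapped_ids)
  expect_true(all(is.na(jo$table$fly_gene_id[!jo$table$mapped])))
  empty <- gom$map[0, ]
  expect_identical(joinOrthologs(cand, empty)$n_mapped, 0L)
  dup <- rbind(gom$map, gom$map[1, ])
  expect_error(joinOrthologs(cand, dup), "duplicate")
})

test_that("screenableGenes is the RNAi-available subset", {
  rec <- data.frame(fly_gene_id = sprintf("CG%02d", 1:20),
                    rnai_available = rep(c(TRUE, FALSE), c(17, 3)))
  expect_identical(length(screenableGenes(rec)), 17L)
  rec$rnai_available <- FALSE
  expect_identical(screenableGenes(rec), character(0))
})

test_that("tabulateSuppressors applies the two-line confirmation rule", {
  screen <- data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3", "g4", "g4", "g5"),
    line_id = paste0("L", 1:8),
    suppression = c("++", "+",      # g1 confirmed
                    "+", "none",    # g2 one positive of two: not tabulated
                    "++",           # g3 single line positive: tabulated
                    "none", "none", # g4 nothing
                    "none"),        # g5 single line negative
    viable = TRUE)
  tab <- tabulateSuppressors(screen)
  expect_identical(tab$suppressors, c("g1", "g3"))
  expect_identical(tab$confirmed, "g1")
  # invariant to line order within genes
  tab2 <- tabulateSuppressors(screen[sample(nrow(screen)), ])
  expect_identical(tab2$suppressors, tab$suppressors)
  expect_identical(tab2$confirmed, tab$confirmed)
})

test_that("inviable crosses are reported separately, empty genes error", {
  screen <- data.frame(
    gene = c("ok", "ok", "dead"),
    line_id = c("L1", "L2", "L3"),
    suppression = c("+", "+", "none"),
    viable = c(TRUE, TRUE, FALSE))
  tab <- tabulateSuppressors(screen)
  expect_identical(tab$inviable, "dead")
  expect_false("dead" %in% tab$suppressors)
  empty <- data.frame(gene = character(0), line_id = character(0),
                      suppression = character(0), viable = logical(0))
  expect_identical(nrow(tabulateSuppressors(empty)$table), 0L)
})

test_that("the transcribed suppressor tabulation yields the printed funnel", {
  screen <- suRdgBScreen()
  tab <- tabulateSuppressors(screen)
  expect_identical(length(tab$suppressors), 52L)
  expect_identical(length(tab$confirmed), 49L)  # 3 single-line entries
  cls <- classifyTriggerEffector(tab$suppressors,
                                 screen[, c("gene", "norpa")])
  expect_identical(length(cls$effectors), 13L)
  expect_identical(length(cls$trigger_specific), 39L)
  erg <- flagPhototransduction(tab$suppressors, screen[, c("gene", "erg")])
  expect_identical(nrow(erg$flagged), 6L)
  expect_identical(sum(erg$flagged$direction == "lower"), 5L)
  expect_identical(erg$flagged$gene[erg$flagged$direction == "higher"],
                   "CG3071")
  expect_identical(length(erg$rough_eye), 6L)
})

test_that("trigger/effector classes always partition the suppressor set", {
  expect_identical(
    classifyTriggerEffector(c("a", "b"), c(a = FALSE, b = FALSE)),
    list(effectors = character(0), trigger_specific = c("a", "b")))
  expect_error(classifyTriggerEffector(c("a", "b"), c(a = TRUE)),
               "missing.*b")
  set.seed(81)
  for (i in 1:50) {
    genes <- sprintf("g%02d", seq_len(sample(1:30, 1)))
    flags <- setNames(sample(c(TRUE, FALSE), length(genes), TRUE), genes)
    cls <- classifyTriggerEffector(genes, flags)
    expect_identical(sort(c(cls$effectors, cls$trigger_specific)),
                     sort(genes))
    expect_length(intersect(cls$effectors, cls$trigger_specific), 0)
  }
  # flipping one flag moves exactly that gene between classes
  genes <- sprintf("g%d", 1:10)
  flags <- setNames(rep(FALSE, 10), genes)
  before <- classifyTriggerEffector(genes, flags)
  flags["g4"] <- TRUE
  after <- classifyTriggerEffector(genes, flags)
  expect_identical(setdiff(after$effectors, before$effectors), "g4")
  expect_identical(setdiff(before$trigger_specific,
                           after$trigger_specific), "g4")
})

test_that("ERG flagging needs a consistent abnormality across recorded lines", {
  eo <- data.frame(
    gene = c("lo", "lo", "hi", "hi", "mix", "mix", "rg", "rg", "nm", "nm",
             "single"),
    erg = c("lower", "lower", "higher", "higher", "lower", "normal",
            "rough_eye", "lower", "normal", "normal", "lower"))
  res <- flagPhototransduction(unique(eo$gene), eo)
  expect_identical(res$flagged$gene, c("hi", "lo", "single"))
  expect_identical(res$rough_eye, "rg")
  none <- flagPhototransduction("nm", eo[eo$gene == "nm", ])
  expect_identical(nrow(none$flagged), 0L)
})

test_that("summaryReport enforces its consistency laws", {
  flg <- data.frame(gene = "s1", direction = "lower")
  rep <- summaryReport(n_candidates = 10, n_orthologs = 8, n_screenable = 7,
                       suppressors = c("s1", "s2", "s3"),
                       confirmed = c("s1", "s2"),
                       effectors = "s2", trigger_specific = c("s1", "s3"),
                       erg_flagged = flg)
  expect_identical(rep$n_trigger_specific,
                   rep$n_suppressors - rep$n_effectors)
  expect_error(summaryReport(10, 8, 7, suppressors = c("s1", "s2"),
                             confirmed = "s1", effectors = "s1",
                             trigger_specific = c("s1", "s2"),
                             erg_flagged = flg[0, ]),
               "partition")
  expect_error(summaryReport(10, 8, 7, suppressors = c("s2", "s3"),
                             confirmed = "s2", effectors = "s2",
                             trigger_specific = "s3",
                             erg_flagged = flg),
               "ERG")
})

test_that("report counts are recomputable from the emitted per-gene TSV", {
  screen <- suRdgBScreen()
  tab <- tabulateSuppressors(screen)
  cls <- classifyTriggerEffector(tab$suppressors,
                                 screen[, c("gene", "norpa")])
  erg <- flagPhototransduction(tab$suppressors, screen[, c("gene", "erg")])
  rep <- summaryReport(52, 52, 52, tab$suppressors, tab$confirmed,
                       cls$effectors, cls$trigger_specific, erg$flagged,
                       erg$rough_eye)
  dir <- withr::local_tempdir()
  writeTriageReport(rep, dir)
  genes <- read.delim(file.path(dir, "report_genes.tsv"))
  counts <- read.delim(file.path(dir, "report_counts.tsv"))
  expect_identical(nrow(genes),
                   counts$count[counts$stage == "suppressors"])
  expect_identical(sum(genes$class == "effector"),
                   counts$count[counts$stage == "effectors"])
  expect_identical(sum(genes$erg %in% c("lower", "higher")),
                   counts$count[counts$stage == "erg_flagged"])
})
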