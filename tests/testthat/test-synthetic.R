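# The synthetic generators: determinism, exact planted scores, budget
# arithmetic, and truth-record sufficiency for the downstream stages.

test_that("generators are bit-for-bit reproducible for a fixed seed", {
  a <- genProteome(n_proteins = 12, n_planted_conventional = 3,
                   n_planted_phospho = 2, seed = 42)
  b <- genProteome(n_proteins = 12, n_planted_conventional = 3,
                   n_planted_phospho = 2, seed = 42)
  expect_identical(a, b)
  c_ <- genProteome(n_proteins = 12, n_planted_conventional = 3,
                    n_planted_phospho = 2, seed = 43)
  expect_false(identical(a$sequences, c_$sequences))
  p1 <- genPsmExperiment(n_true = 10, n_background = 20, seed = 5)
  p2 <- genPsmExperiment(n_true = 10, n_background = 20, seed = 5)
  expect_identical(p1, p2)
  s1 <- genScreenTables(n_genes = 30, n_suppressors = 8, n_effectors = 2,
                        n_single_line = 1, n_erg_abnormal = 2, seed = 9)
  s2 <- genScreenTables(n_genes = 30, n_suppressors = 8, n_effectors = 2,
                        n_single_line = 1, n_erg_abnormal = 2, seed = 9)
  expect_identical(s1, s2)
  # written artifacts are byte-identical too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeFasta(a$sequences, f1); writeFasta(b$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(genProteome(n_proteins = 5,
                                       n_planted_conventional = 1,
                                       n_planted_phospho = 0, seed = 8))
  expect_identical(runif(1), before)
})

test_that("planted windows score exactly their budget, with no tolerance", {
  mats <- defaultMatrixPair()
  for (budget in c(0, 0.5, 2, 2.5, 4)) {
    gp <- genProteome(n_proteins = 6, n_planted_conventional = 2,
                      n_planted_phospho = 2, budget = budget, seed = 17,
                      length_range = c(100, 200))
    pl <- gp$truth$planted
    for (i in seq_len(nrow(pl))) {
      s <- gp$sequences[[pl$protein_id[i]]]
      w <- substr(s, pl$start[i], pl$start[i] + 18)
      expect_identical(scoreWindow(w, mats[[pl$motif_class[i]]]), budget)
      expect_identical(pl$expected_score[i], budget)
    }
  }
})

test_that("an unreachable degradation budget errors", {
  # shipped matrices have 0.5-granular penalties: 0.25 cannot be hit exactly
  expect_error(genProteome(n_proteins = 4, n_planted_conventional = 1,
                           n_planted_phospho = 0, budget = 0.25, seed = 1),
               "unreachable")
})

test_that("planted motifs are unique minima above an enforced margin", {
  gp <- genProteome(n_proteins = 20, n_planted_conventional = 5,
                    n_planted_phospho = 5, budget = 2, margin = 3,
                    seed = 19, length_range = c(100, 250))
  mats <- defaultMatrixPair()
  pl <- gp$truth$planted
  for (id in names(gp$sequences)) {
    planted_here <- pl[pl$protein_id == id, ]
    for (cl in c("conventional", "phospho")) {
      hits <- scanSequence(gp$sequences[[id]], mats[[cl]], id)
      row <- planted_here[planted_here$motif_class == cl, ]
      if (nrow(row)) {
        expect_identical(hits$start[which.min(hits$score)], row$start)
        other <- hits[abs(hits$core_start - (row$start + 6L)) >= 7, ]
        expect_true(all(other$score > 2 + 3))
      } else if (nrow(planted_here) == 0) {
        expect_true(all(hits$score > 2 + 3))
      }
    }
  }
})

test_that("the PSM simulation has the planted enrichment structure", {
  sim <- genPsmExperiment(n_true = 20, n_background = 50, seed = 11)
  tab <- sim$psm_table
  expect_identical(nrow(tab), (20L + 50L) * 4L)  # 2 baits x 2 conditions
  wt_true <- tab$psm[tab$condition == "WT" &
                       tab$protein_id %in% sim$truth$true_ids]
  mut_true <- tab$psm[tab$condition == "MUT" &
                        tab$protein_id %in% sim$truth$true_ids]
  expect_gt(mean(wt_true), mean(mut_true) * 5)
  # null case: no WT/mutant difference -> selection finds almost nothing
  null <- genPsmExperiment(n_true = 30, n_background = 0, lambda_wt = 20,
                           lambda_mut = 20, seed = 13)
  sel <- selectCandidates(null$psm_table, "VAP_A")
  expect_lte(length(sel), 3)
  # no true interactors -> only sporadic background false positives
  bgonly <- genPsmExperiment(n_true = 0, n_background = 100, seed = 13)
  selbg <- selectCandidates(bgonly$psm_table, "VAP_A")
  expect_lte(length(selbg), 12)
})

test_that("screen generator truth matches the downstream triage exactly", {
  gs <- genScreenTables(n_genes = 40, n_suppressors = 10, n_effectors = 3,
                        n_single_line = 2, n_erg_abnormal = 4, seed = 23)
  tab <- tabulateSuppressors(gs$screen)
  expect_identical(tab$suppressors, gs$truth$suppressors)
  expect_identical(sort(setdiff(gs$truth$suppressors,
                                gs$truth$single_line)), tab$confirmed)
  cls <- classifyTriggerEffector(tab$suppressors,
                                 gs$screen[, c("gene", "norpa")])
  expect_identical(cls$effectors, gs$truth$effectors)
  expect_identical(cls$trigger_specific, gs$truth$trigger_specific)
  erg <- flagPhototransduction(tab$suppressors,
                               gs$screen[, c("gene", "erg")])
  expect_identical(sort(erg$flagged$gene), gs$truth$erg_abnormal)
  # property: random parameterisations agree with their truth records
  set.seed(29)
  for (i in 1:10) {
    ns <- sample(0:15, 1)
    ne <- sample(0:ns, 1)
    nt <- ns - ne
    gs <- genScreenTables(n_genes = sample(max(ns, 1):40, 1),
                          n_suppressors = ns,
                          n_effectors = ne,
                          n_single_line = sample(0:ns, 1),
                          n_erg_abnormal = sample(0:nt, 1),
                          seed = 100 + i)
    tab <- tabulateSuppressors(gs$screen)
    expect_identical(tab$suppressors, gs$truth$suppressors)
    cls <- classifyTriggerEffector(tab$suppressors,
                                   gs$screen[, c("gene", "norpa")])
    expect_identical(cls$effectors, gs$truth$effectors)
  }
})

test_that("screen generator validates its size arithmetic", {
  expect_error(genScreenTables(n_genes = 10, n_suppressors = 5,
                               n_effectors = 6, seed = 1), "n_effectors")
  expect_error(genScreenTables(n_genes = 10, n_suppressors = 5,
                               n_effectors = 1, n_single_line = 6,
                               seed = 1), "n_single_line")
  expect_error(genScreenTables(n_genes = 4, n_suppressors = 5,
                               n_effectors = 1, n_single_line = 1,
                               n_erg_abnormal = 1, seed = 1),
               "n_suppressors")
  none <- genScreenTables(n_genes = 15, n_suppressors = 0, n_effectors = 0,
                          n_single_line = 0, n_erg_abnormal = 0, seed = 2)
  expect_identical(tabulateSuppressors(none$screen)$suppressors,
                   character(0))
})
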