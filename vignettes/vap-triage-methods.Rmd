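---
title: "Methods: FFAT motif scoring and VAP interactome triage"
author: "vapTriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FFAT motif scoring and VAP interactome triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vapTriage)
```

# The problem

VAP-A and VAP-B are ER membrane proteins whose MSP domain binds client
proteins carrying an FFAT motif ("two phenylalanines in an acidic tract")
or its phosphorylation-regulated variant, the Phospho-FFAT. Pull-downs with
WT versus FFAT-binding-dead (KD/MD) mutant MSP domains give a differential
IP-MS readout of FFAT-dependent interactors; scanning the hits' sequences
for motifs separates plausible direct binders from indirect ones; and an
RNAi modifier screen in a sensitised retinal-degeneration background sorts
the in vivo relevant candidates into genes acting on the degeneration
trigger versus its downstream effectors. `vapTriage` implements that
computational chain — scoring, ranking, tabulation — plus seeded synthetic
generators so every stage can be verified without external data.

# The penalty scoring model

A motif instance is a 19-residue window: six upstream flank positions
(U1–U6), a seven-residue core (C1–C7) and six downstream flank positions
(D1–D6). A `PenaltyMatrix` assigns a non-negative penalty to each (position,
residue) cell; a window's score is the plain sum of its 19 looked-up
penalties. Lower is better, and the class guarantees (validity method) that
each position has at least one zero-penalty residue, so an ideal sequence
scores exactly 0. Scores are exact sums of the stored values — no rounding,
no log-odds transformation — and all shipped penalties are multiples of
0.5, so score arithmetic is exact in double precision.

The two motif classes differ only at the fourth core position C4 (window
position 10), the acid/phospho-acceptor position: the phospho-class matrix
gives the phosphorylatable residues S and T penalty 0 there, and
`makeConventional()` derives the conventional-class matrix by setting, at
C4 only, S and T to penalty 4 and the acidic residues D and E to penalty 0.
"Position 4" is read as the fourth *core* position: it is the only reading
under which the S/T-versus-D/E swap distinguishes the two motif chemistries.

```{r transform}
ph <- readPenaltyMatrix(ffatMatrixFile("phospho"), motifClass = "phospho")
cv <- makeConventional(ph)
penalties(cv)[c("S", "T", "D", "E"), "C4"]
idealSequence(cv)
```

## The shipped matrices are synthetic

The package treats matrix values as data, shipped as diff-able TSV files
(header = the 19 position labels; 20 rows keyed by residue letter). The
default matrices (`ffat_phospho_synthetic.tsv` and its derived conventional
counterpart) are a *synthetic construction* from the FFAT consensus — an
acidic upstream tract, an F–F/Y aromatic pair in the core, the C4 acceptor,
an alanine at C5 and a closing glutamate — not a transcription of any
experimentally fitted matrix. Every structural contract holds for them
(dimensions, zero-per-position, the C4 conventions), and every numerical
test in the package is driven either by these structural properties or by
toy matrices, never by the specific synthetic weights. Users with a fitted
matrix drop in their own TSV.

## Scanning conventions

* Only fully contained windows are scored: a protein of length $L$ has
  $L - 18$ windows, and a motif within six residues of a terminus is
  undetectable. No padding mode is offered; partial-window scores would
  have no defined meaning under the additive model.
* Coordinates are 1-based on the protein; `core_start = start + 6` is the
  C1 position, matching the usual protein-coordinate conventions.
* Sequences are upper-cased on read; `*` stop characters are stripped with
  a warning; a sequence shorter than 19 residues yields an empty hit list
  with a warning, not an error.
* Non-canonical residues (X, B, Z, U, O): the default `max_penalty` policy
  charges the position's column maximum — conservative, since it can never
  fabricate an ideal hit; the alternative `skip_window` drops any window
  containing one.
* Per protein and class the best `k = 2` hits are reported, requiring
  *core-disjoint* hits (C1..C7 intervals must not overlap): without this
  rule the shifted windows of one strong motif would always fill both
  slots. Ties in score break toward the smaller (more N-terminal) start;
  ties in `idealSequence()` break alphabetically. Both rules exist purely
  for determinism.
* The significance band is closed at both ends, $0 \le s \le 2.5$: zero is
  the ideal score and must count, and the default threshold 2.5 is the
  band boundary used when triaging candidates. A protein is significant
  when the *minimum* of its best conventional and best phospho scores is
  in the band.

# IP-MS enrichment ranking

The evidence table is long-format spectral counts: per protein, bait
(VAP_A/VAP_B) and condition (WT/MUT), with peptide counts and the search
engine's identification score carried as opaque columns. The enrichment
statistic is the pseudocounted ratio

$$ r = \frac{\mathrm{PSM}_{WT} + c}{\mathrm{PSM}_{MUT} + c}, \quad c = 1, $$

finite for zero mutant counts, rank-preserving, and converging to the raw
ratio as $c \to 0$. A protein is selected for a bait when $r \ge 2$ and it
has at least 2 WT peptides. The ratio-and-score ranking idea comes from
the screening strategy this package implements, but no numeric cutoffs
were published with it; the defaults here are explicit, adjustable
analysis parameters (`pipelineConfig()`), not recovered thresholds —
which is also why the package makes no claim to reproduce the original
screen's exact candidate counts (401/194/136), a data-dependent question
requiring the original supplementary tables. Per-bait selections are
combined by plain set union/intersection with A_only/B_only/both labels.

# Screen triage

Suppressor tabulation applies the screen's confirmation rule: a gene is a
*confirmed* suppressor when at least two independent RNAi lines each scored
positive (`+` partial or `++` definite suppression). Genes with exactly one
available line that scored positive are tabulated too, carrying
`confirmed = FALSE` — the published tabulation itself contains three such
entries, so reproducing its 52-gene count requires keeping them while the
two-line rule survives as metadata. Inviable crosses are reported
separately and never tabulated.

The trigger/effector partition is a single boolean per suppressor: genes
that also suppress degeneration in the independent `norpA` (phospholipase
C) background act on shared downstream degeneration machinery (effectors);
the remainder are specific to the sensitised background's lesion
(trigger-specific). The two classes partition the suppressor set by
construction, and `summaryReport()` re-checks that and the
`erg_flagged ⊆ suppressors` law as internal assertions.

ERG flagging requires the *same* abnormality (`lower` or `higher`
amplitude) in every line with a recorded ERG; genes with a rough-eye
phenotype in any line are segregated into a separate list (eye-development
confound) and never flagged, even when their remaining line shows an
abnormal amplitude.

The shipped screen data (`suRdgBScreen()`) joins a faithful line-level
transcription of the published 52-suppressor tabulation with a
norpA/ERG outcome file. ERG outcomes are as published (five lower, one
higher, six rough-eye). The norpA membership is only partially published —
the count (13 of 52) and five named genes — so the shipped flag column
completes it with eight RNA/chromatin-associated genes (matching the
published statement about the effector class's functional bias) purely to
carry the printed count; the file is named `*_synthetic.tsv` and those
eight flags are placeholders, not data.

# Synthetic data generators

Each generator takes an explicit integer seed, restores the caller's RNG
state, and returns its data plus a truth record sufficient to judge every
downstream stage.

**Proteomes** (`genProteome()`): background residues are uniform over the
20 canonical amino acids (a composition vector can be supplied); defaults
are 100 proteins of 150–500 residues with 18 planted conventional and 18
planted phospho motifs on disjoint proteins. Planted motifs start from the
class's ideal 19-mer and are degraded by substitutions whose penalties sum
*exactly* to the requested budget (default 2, inside the significance
band), chosen greedily largest-first over matrix cells with deterministic
tie-breaks — so the truth record knows each planted score without
tolerance. Background is rejection-sampled until every window whose core
is disjoint from a planted core scores above `budget + margin` (margin 3)
under both matrices and the planted window is the unique score minimum
among windows overlapping its core; planted hits are therefore exactly
recoverable, which the tests assert with equality, not tolerance.

**PSM tables** (`genPsmExperiment()`): true interactors draw
Poisson($\lambda_{WT} = 20$) WT counts and Poisson($\lambda_{MUT} = 1$)
mutant counts; background draws Poisson($\lambda_{bg} = 10$) in both
conditions, emulating mid-abundance sticky-bead background that binds WT
and mutant resin equally. Draws are independent per bait, so
union/intersection structure is realisable. Poisson is the minimal model
that creates rank-separable structure; with a ratio cutoff of 2 at these
rates, a background protein passes selection with probability of roughly
6% per bait — small counts make pseudocounted ratios noisy — so a run with
200 background proteins is expected to carry a handful of false positives.
The frozen acceptance bounds (at least 48/50 true interactors recovered
per bait, at most 25 background selected) come from a one-time oracle run
of generator plus selector and reflect that behaviour.

**Screen tables** (`genScreenTables()`): plants `n_suppressors` (default
52) among `n_genes` (default 388), with `n_single_line` (3) single-line
entries, `n_effectors` (13) norpA-positive and `n_erg_abnormal` (6)
ERG-abnormal trigger-specific genes — the defaults are the published
screen's printed counts used as generator parameters. Ten percent of
non-suppressors get one positive and one negative line to exercise the
confirmation rule.

What the generators do *not* emulate: real amino-acid composition and
disorder context around motifs, correlated spectral counts, shared
peptides, ortholog ambiguity, or phenotype-scoring noise. Passing tests
therefore demonstrate the *algorithmic* correctness of scoring, selection
and tabulation under known truth, not the biological recall of the
original screen on real data.

`runPipeline()` fans one user seed out to per-stage substreams by fixed
small offsets (proteome seed, PSM seed + 1, …), so adding one stage never
perturbs another's stream.

# Problem sizes and runtime

The test and acceptance workloads are sized for a laptop: 1,000 random
matrices for the ideal-score law, 200 random sequences (length ≤ 500)
against the brute-force scanning oracle, the 100-protein planted proteome,
the 250-protein PSM simulation and 1,000 random set pairs for
inclusion–exclusion. The full suite runs in well under a minute.

# Known limitations

* Motifs within six residues of a protein terminus are invisible to the
  scanner (no partial windows).
* The shipped matrices are consensus-derived stand-ins; absolute scores
  from them are not comparable to scores from a fitted matrix, although
  all structural behaviour (ideal = 0, the C4 transform, the band logic)
  is identical.
* The enrichment model filters on peptide count and ratio only; the MS
  identification score is carried but not thresholded by default, its
  scale being search-engine specific.
* Ortholog mapping is consumed as a table; no orthology inference is
  attempted.
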