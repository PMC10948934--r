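# Independent brute-force oracles used to cross-check the scanner. These
# deliberately avoid the vectorised column-shift accumulation used by the
# implementation: every window is scored residue by residue in an explicit
# loop.

oracle_window_score <- function(window, m) {
  p <- penalties(m)
  chars <- strsplit(window, "")[[1]]
  stopifnot(length(chars) == 19)
  total <- 0
  for (j in 1:19) {
    r <- chars[j]
    total <- total + if (r %in% rownames(p)) p[r, j] else max(p[, j])
  }
  total
}

oracle_scan <- function(seq, m) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 19) return(data.frame(start = integer(0), score = numeric(0)))
  starts <- 1:(n - 18)
  scores <- vapply(starts, function(s)
    oracle_window_score(substr(seq, s, s + 18), m), numeric(1))
  data.frame(start = starts, score = scores)
}

# A random protein sequence over the canonical alphabet.
random_protein <- function(n) paste(sample(AA_ALPHABET20, n, replace = TRUE),
                                    collapse = "")

# A tiny toy matrix with a unique zero residue per position: position j's
# zero residue is the j-th letter of `zeros`; all other residues get
# penalty `other`.
unique_zero_matrix <- function(zeros, other = 1, motifClass = "conventional") {
  p <- matrix(other, 20, 19,
              dimnames = list(AA_ALPHABET20, FFAT_POSITIONS))
  zc <- strsplit(zeros, "")[[1]]
  stopifnot(length(zc) == 19)
  for (j in 1:19) p[zc[j], j] <- 0
  PenaltyMatrix(p, motifClass = motifClass, name = "unique_zero")
}
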