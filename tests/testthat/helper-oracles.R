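# Independent reference implementations used as oracles. Deliberately naive
# and slow: they share no code with the package paths they check.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# plain-R Needleman-Wunsch score, linear gaps
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  H <- matrix(0, m + 1, n + 1)
  H[, 1] <- (0:m) * gap
  H[1, ] <- (0:n) * gap
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      H[i + 1, j + 1] <- max(
        H[i, j] + if (a[i] == b[j]) match else mismatch,
        H[i, j + 1] + gap,
        H[i + 1, j] + gap
      )
    }
  }
  H[m + 1, n + 1]
}

# score an already-aligned pair of rows under the same scoring
aligned_pair_score <- function(x, y, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(x, "")[[1]]; y <- strsplit(y, "")[[1]]
  keep <- !(x == "-" & y == "-") # columns where both rows gap do not count
  x <- x[keep]; y <- y[keep]
  sum(ifelse(x == "-" | y == "-", gap, ifelse(x == y, match, mismatch)))
}

# column-wise majority vote, written independently with table()
consensus_oracle <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  out <- character(0)
  for (j in seq_len(ncol(mat))) {
    counts <- table(factor(mat[, j], levels = c("A", "C", "G", "T", "-")))
    gap <- counts[["-"]]
    bases <- counts[c("A", "C", "G", "T")]
    top <- max(bases)
    if (gap > top) next                      # strict gap plurality: drop
    out <- c(out, names(bases)[which.max(bases)]) # ties: A < C < G < T
  }
  paste(out, collapse = "")
}

has_mafft <- function() mafft_available()
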