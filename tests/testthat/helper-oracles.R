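# Independent plain-R Gotoh dynamic-programming oracle for affine-gap
# alignment scores. Deliberately written from the recurrences, sharing no
# code with the package's alignment path: a gap of length L costs
# gap_open + L * gap_extend (scores, <= 0).

oracle_score <- function(a, b, type = c("global", "local"),
                         match = 1, mismatch = -1,
                         gap_open = -2, gap_extend = -1,
                         submat = NULL) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  sc <- function(x, y) {
    if (!is.null(submat)) submat[x, y] else if (x == y) match else mismatch
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
    for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag_best <- max(M[i, j], X[i, j], Y[i, j])
      if (type == "local") diag_best <- max(diag_best, 0)
      M[i + 1, j + 1] <- sc(av[i], bv[j]) + diag_best
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
      if (type == "local") best_local <- max(best_local, M[i + 1, j + 1])
    }
  }
  if (type == "global") max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  else best_local
}

random_dna_string <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                              replace = TRUE), collapse = "")
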