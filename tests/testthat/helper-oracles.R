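# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Count all (fragment, start) matches by enumerating every substring.
oracle_occurrence <- function(seq, frags, distinct = FALSE) {
  n <- nchar(seq)
  total <- 0
  for (f in unique(frags)) {
    lf <- nchar(f)
    hits <- 0
    if (lf <= n) {
      for (s in seq_len(n - lf + 1)) {
        if (substr(seq, s, s + lf - 1) == f) hits <- hits + 1
      }
    }
    total <- total + if (distinct) as.integer(hits > 0) else hits
  }
  total / n
}

# Scan every bond against a P1/P1' rule.
oracle_digest_sites <- function(seq, p1, excl) {
  res <- strsplit(seq, "")[[1]]
  sites <- integer(0)
  for (i in seq_len(length(res) - 1)) {
    if (res[i] %in% p1 && !(res[i + 1] %in% excl)) sites <- c(sites, i)
  }
  sites
}

# Dense-grid maximiser of a coded quadratic over [-1,1]^3:
# coarse pass then local refinement to step 0.001.
oracle_grid_optimum <- function(beta) {
  evalq_ <- function(m) {
    X <- cbind(1, m[, 1], m[, 2], m[, 3], m[, 1] * m[, 2], m[, 1] * m[, 3],
               m[, 2] * m[, 3], m[, 1]^2, m[, 2]^2, m[, 3]^2)
    drop(X %*% beta)
  }
  g <- seq(-1, 1, by = 0.02)
  m <- as.matrix(expand.grid(g, g, g))
  best <- m[which.max(evalq_(m)), ]
  for (step in c(0.005, 0.001)) {
    g2 <- lapply(best, function(b) {
      v <- seq(b - 5 * step, b + 5 * step, by = step)
      pmin(1, pmax(-1, v))
    })
    m2 <- as.matrix(expand.grid(g2[[1]], g2[[2]], g2[[3]]))
    best <- m2[which.max(evalq_(m2)), ]
  }
  list(coded = unname(best), value = max(evalq_(matrix(best, 1))))
}

random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
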