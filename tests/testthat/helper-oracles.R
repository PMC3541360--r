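# Independent oracles used across the suite. These deliberately take the
# slow, literal route (substring enumeration, closed forms, exhaustive
# rank enumeration) so they share no code path with the implementation.

# Brute-force PQS oracle: decompose into maximal G-runs by a character
# walk, enumerate every run-delimited substring, accept those whose
# consecutive inter-run gaps are all legal loops and whose run count
# meets the minimum, then take the greedy leftmost-longest
# non-overlapping set.
brutePQS <- function(seq, minRun = 3L, loopMin = 1L, loopMax = 7L,
                     minTracts = 4L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (chars[i] == "G") {
      j <- i
      while (j < n && chars[j + 1L] == "G") j <- j + 1L
      if (j - i + 1L >= minRun) runs[[length(runs) + 1L]] <- c(i - 1L, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(data.frame(start = integer(), end = integer()))
  rs <- vapply(runs, `[`, integer(1), 1L)   # 0-based start
  re <- vapply(runs, `[`, integer(1), 2L)   # 0-based exclusive end
  accepted <- list()
  for (a in seq_along(runs)) for (b in a:length(runs)) {
    if (b - a + 1L < minTracts) next
    gaps <- rs[(a + 1L):b] - re[a:(b - 1L)]
    if (all(gaps >= loopMin & gaps <= loopMax))
      accepted[[length(accepted) + 1L]] <- c(rs[a], re[b])
  }
  if (!length(accepted)) return(data.frame(start = integer(), end = integer()))
  acc <- do.call(rbind, accepted)
  acc <- acc[order(acc[, 1], -acc[, 2]), , drop = FALSE]
  out <- list(); cursor <- -1L
  for (r in seq_len(nrow(acc))) {
    if (acc[r, 1] >= cursor) {
      # leftmost start, then longest at that start (already sorted)
      if (length(out) && out[[length(out)]][1] == acc[r, 1]) next
      out[[length(out) + 1L]] <- acc[r, ]
      cursor <- acc[r, 2]
    }
  }
  se <- do.call(rbind, out)
  data.frame(start = se[, 1], end = se[, 2])
}

# Textbook Pearson correlation from the closed form.
pearsonOracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sum((x - xb) * (y - yb)) /
    sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n+m, n) group assignments (tie-free inputs only).
wilcoxExactOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  ranks <- rank(pooled)
  obsU <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  U <- apply(combos, 2, function(idx)
    sum(ranks[idx]) - nx * (nx + 1) / 2)
  pLo <- mean(U <= obsU); pHi <- mean(U >= obsU)
  min(1, 2 * min(pLo, pHi))
}

# Random nucleotide string with a given G bias (other bases uniform).
randomSeq <- function(n, gFrac = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gFrac) / 3, (1 - gFrac) / 3, gFrac,
                        (1 - gFrac) / 3)), collapse = "")
}

# Write a small FASTA + annotation pair for IO tests.
writeTinyGenome <- function(contigs, transcripts, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  writeLines(unlist(lapply(names(contigs), function(nm)
    c(paste0(">", nm), contigs[[nm]]))), fa)
  tsv <- file.path(dir, "transcripts.tsv")
  utils::write.table(transcripts, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fa, annot = tsv, dir = dir)
}
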