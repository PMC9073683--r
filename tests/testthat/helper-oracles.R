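suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(S4Vectors)
})

# Shared fixtures and independent oracles.
# The brute-force pair oracle never calls the package's scanner internals:
# motif occurrences are found by direct window comparison and pairs by an
# explicit double loop, so scanner tests compare two independent routes.

randSeq <- function(n, gc = 0.36) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# all 1-based start positions of motif by direct window comparison
bruteMotif <- function(s, motif) {
  w <- nchar(motif); L <- nchar(s)
  if (w > L) return(integer(0))
  starts <- seq_len(L - w + 1L)
  starts[substring(s, starts, starts + w - 1L) == motif]
}

# all (leftStart, rightStart, spacer) pairs by explicit double loop
brutePairs <- function(s, left, right, minS = 0L, maxS = 30L) {
  lp <- bruteMotif(s, left); rp <- bruteMotif(s, right)
  wl <- nchar(left)
  out <- list()
  for (l in lp) for (r in rp) {
    N <- r - (l + wl)
    if (N >= minS && N <= maxS)
      out[[length(out) + 1L]] <- c(l, r, N)
  }
  if (!length(out))
    return(data.frame(leftStart = integer(0), rightStart = integer(0),
                      spacerLen = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(leftStart = m[, 1], rightStart = m[, 2],
                   spacerLen = m[, 3])
  df[order(df$leftStart, df$spacerLen), , drop = FALSE]
}

# paired t-test from first principles
oracleTTest <- function(x, y) {
  d <- x - y; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Pearson r and its t-based p-value from first principles
oraclePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# small GFF3 writer for tests
writeTestGff <- function(rows, path) {
  writeLines(c("##gff-version 3", rows), path)
  path
}

gffRow <- function(chr, type, start, end, strand, id) {
  paste(chr, "test", type, start, end, ".", strand, ".",
        paste0("ID=", id), sep = "\t")
}
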