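test_that("motif occurrence finding is exhaustive and overlap-aware", {
  expect_equal(motifPositions("AAAAG", "AAAG"), 2L)
  expect_equal(motifPositions("AAAAAG", "AAAG"), 3L)
  expect_equal(motifPositions("ACGTACGT", "ACGT"), c(1L, 5L))
  expect_equal(motifPositions("AAA", "AAAG"), integer(0))
  expect_equal(motifPositions("AANG", "AAAG"), integer(0))  # N never matches
  expect_error(motifPositions("ACGT", ""), "argument error")
  # poly-A run: every window counts
  expect_equal(motifPositions("AAAAAAG", "AAAG"), 4L)
  expect_equal(motifPositions(paste0(strrep("A", 10), "G"), "AAAG"), 8L)
})

test_that("pair scanning reproduces the worked examples", {
  q <- motifPairQuery("AAAG", "ACGT")
  h <- scanPairs("AAAGACGT", q)
  expect_equal(length(h), 1L)
  expect_equal(mcols(h)$spacerLen, 0L)
  expect_equal(mcols(h)$spacerSeq, "")

  h24 <- scanPairs("AAAGTTGGGCTTTCAAAATTGTTAACTCACGT", q)
  expect_equal(length(h24), 1L)
  expect_equal(mcols(h24)$spacerLen, 24L)
  expect_equal(mcols(h24)$spacerSeq, "TTGGGCTTTCAAAATTGTTAACTC")

  h14 <- scanPairs("ACGTGGATGCTATTATTAAAAG", motifPairQuery("ACGT", "AAAG"))
  expect_equal(length(h14), 1L)
  expect_equal(mcols(h14)$spacerLen, 14L)

  # one motif occurrence can participate in several hits
  h2 <- scanPairs("AAAGAAAGACGT", q)
  expect_equal(length(h2), 2L)
  expect_equal(mcols(h2)$leftStart, c(1L, 5L))
  expect_equal(mcols(h2)$spacerLen, c(4L, 0L))
})

test_that("scanner agrees with the brute-force occurrence-pair oracle", {
  q <- motifPairQuery("AAAG", "ACGT")
  set.seed(11)
  for (i in 1:30) {
    s <- randSeq(sample(200:2000, 1))
    h <- scanPairs(s, q)
    o <- brutePairs(s, "AAAG", "ACGT")
    expect_equal(mcols(h)$leftStart, o$leftStart)
    expect_equal(mcols(h)$spacerLen, o$spacerLen)
    # spacer sequences reconstruct the source
    if (length(h) > 0) {
      rebuilt <- paste0("AAAG", mcols(h)$spacerSeq, "ACGT")
      span <- substring(s, mcols(h)$leftStart,
                        mcols(h)$leftStart + nchar(rebuilt) - 1L)
      expect_equal(rebuilt, span)
    }
  }
})

test_that("strand symmetry: (M1,M2) on S equals (rc(M2),rc(M1)) on rc(S)", {
  set.seed(5)
  q1 <- motifPairQuery("AAAG", "ACGT")
  q2 <- motifPairQuery(revComp("ACGT"), revComp("AAAG"))
  for (i in 1:10) {
    s <- randSeq(3000)
    c1 <- spacerCounts(spacerProfile(s, q1))
    c2 <- spacerCounts(spacerProfile(revComp(s), q2))
    expect_equal(c1, setNames(c2, names(c1)))
  }
})

test_that("widening the spacer range never removes hits", {
  set.seed(9)
  s <- randSeq(5000)
  narrow <- scanPairs(s, motifPairQuery("AAAG", "ACGT", 5, 20))
  wide <- scanPairs(s, motifPairQuery("AAAG", "ACGT", 0, 30))
  keyN <- paste(mcols(narrow)$leftStart, mcols(narrow)$spacerLen)
  keyW <- paste(mcols(wide)$leftStart, mcols(wide)$spacerLen)
  expect_true(all(keyN %in% keyW))
})

test_that("flanked-motif hits imply core-motif hits by coordinate shift", {
  # TAAAG(N)GACGTC contains AAAG(N+1)ACGT: the core AAAG ends where TAAAG
  # ends and the ACGT starts one base into GACGTC
  set.seed(13)
  flank <- motifPairQuery("TAAAG", "GACGTC")
  core <- motifPairQuery("AAAG", "ACGT")
  base <- Biostrings::DNAStringSet(c(s1 = randSeq(4000)))
  pl <- plantPairs(base, flank, spacerLen = c(2, 8, 15), n = 6, seed = 2,
                   minGap = 40)
  hf <- scanPairs(pl$sequences, flank)
  hc <- scanPairs(pl$sequences, core)
  expect_gte(length(hf), 6L)
  keyCore <- paste(mcols(hc)$leftStart, mcols(hc)$spacerLen)
  for (i in seq_along(hf)) {
    expect_true(paste(mcols(hf)$leftStart[i] + 1L,
                      mcols(hf)$spacerLen[i] + 1L) %in% keyCore)
  }
})

test_that("profiles tally counts per spacer with coverage bookkeeping", {
  q <- motifPairQuery("AAAG", "ACGT")
  p <- spacerProfile(c(a = "AAAGACGT", b = "AAAGACGT"), q)
  expect_equal(unname(spacerCounts(p)["0"]), 2L)
  expect_equal(sum(spacerCounts(p)), 2L)
  expect_equal(totalBp(p), 16)
  expect_equal(nSequences(p), 2L)
  expect_error(spacerProfile(character(0), q), "argument error|empty")

  # hits never span sequences: adjacent halves produce no joint hit
  p2 <- spacerProfile(c(x = "AAAGTT", y = "ACGT"), q)
  expect_equal(sum(spacerCounts(p2)), 0L)

  set.seed(21)
  s <- randSeq(10000)
  p3 <- spacerProfile(s, q)
  o <- brutePairs(s, "AAAG", "ACGT")
  expect_equal(sum(spacerCounts(p3)), nrow(o))
  otab <- table(factor(o$spacerLen, levels = 0:30))
  expect_equal(unname(spacerCounts(p3)), unname(as.integer(otab)))
})

test_that("spacer collection preserves scan order and exact content", {
  q <- motifPairQuery("AAAG", "ACGT")
  h <- scanPairs("AAAGTTACGT", q)
  expect_equal(collectSpacers(h, 2), "TT")
  expect_equal(collectSpacers(h, 9), character(0))

  base <- Biostrings::DNAStringSet(c(p = randSeq(2000)))
  fixed <- "TTGGGCTTTCAAAATTGTTAACTC"
  pl <- plantPairs(base, q, spacerLen = 24, n = 3, seed = 8,
                   spacerSeqs = fixed, minGap = 40)
  hp <- scanPairs(pl$sequences, q)
  expect_true(all(fixed == collectSpacers(hp, 24)[1:3] |
                    fixed %in% collectSpacers(hp, 24)))
  expect_gte(sum(collectSpacers(hp, 24) == fixed), 3L)
})

test_that("exclusive mode drops pairs with motifs inside the spacer", {
  q <- motifPairQuery("AAAG", "ACGT")
  s <- "AAAGTTAAAGTTACGT"  # outer pair's spacer contains an AAAG
  all_ <- scanPairs(s, q)
  excl <- scanPairs(s, q, exclusive = TRUE)
  expect_equal(length(all_), 2L)
  expect_equal(length(excl), 1L)
  expect_equal(mcols(excl)$leftStart, 7L)
})

test_that("both-strands mode finds reverse-oriented pairs", {
  q <- motifPairQuery("AAAG", "ACGT")
  fwd <- "AAAGTTTACGT"
  rc <- revComp(fwd)
  h <- scanPairs(rc, q, bothStrands = TRUE)
  expect_equal(length(h), 1L)
  expect_equal(as.character(strand(h)), "-")
  expect_equal(mcols(h)$spacerLen, 3L)
  # mapped interval covers the same bases as the forward hit
  expect_equal(GenomicRanges::start(h), 1L)
  expect_equal(GenomicRanges::end(h), nchar(fwd))
})

test_that("hit export uses BED-style half-open coordinates", {
  h <- scanPairs(c(chr = "TTAAAGACGTTT"), motifPairQuery("AAAG", "ACGT"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeHitsBed(h, tsv)
  df <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(df$start, 2L)   # 1-based 3 -> 0-based 2
  expect_equal(df$end, 10L)
  expect_equal(df$spacer_len, 0L)
})
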