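test_that("simulated genomes hit the target GC and layout", {
  sim <- simulateGenome(100000, 20, gcContent = 0.36, seed = 101)
  gc <- Biostrings::letterFrequency(sim$genome, "GC", as.prob = TRUE)
  expect_true(gc >= 0.345 && gc <= 0.375)

  # all promoters full-length by construction
  ps <- extractPromoters(sim$genome, sim$genes)
  expect_true(all(Biostrings::width(promoterSequences(ps)) == 1000L))

  # byte-identical regeneration from the same seed
  sim2 <- simulateGenome(100000, 20, gcContent = 0.36, seed = 101)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))
  expect_identical(as.data.frame(sim$genes), as.data.frame(sim2$genes))

  # a different seed gives different residues
  sim3 <- simulateGenome(100000, 20, gcContent = 0.36, seed = 102)
  expect_false(identical(as.character(sim$genome),
                         as.character(sim3$genome)))

  expect_error(simulateGenome(5000, 50, seed = 1), "configuration error")
})

test_that("planted pairs are always recovered by the scanner", {
  q <- motifPairQuery("AAAG", "ACGT")
  base <- Biostrings::DNAStringSet(c(s1 = randSeq(20000), s2 = randSeq(20000)))
  pl <- plantPairs(base, q, spacerLen = 10, n = 5, seed = 3, minGap = 40)
  expect_equal(Biostrings::width(pl$sequences), Biostrings::width(base))
  hits <- scanPairs(pl$sequences, q)
  at10 <- hits[mcols(hits)$spacerLen == 10]
  expect_gte(length(at10), 5L)
  key <- paste(as.character(seqnames(at10)), mcols(at10)$leftStart)
  expect_true(all(paste(pl$truth$seq_id, pl$truth$start) %in% key))

  # planting zero sites leaves sequences untouched
  pl0 <- plantPairs(base, q, spacerLen = 10, n = 0, seed = 3)
  expect_identical(as.character(pl0$sequences), as.character(base))

  # a fixed spacer string is recovered verbatim
  fixed <- "TTGGGCTTTCAAAATTGTTAACTC"
  plf <- plantPairs(base, q, spacerLen = 24, n = 2, seed = 9,
                    spacerSeqs = fixed, minGap = 40)
  expect_true(fixed %in% collectSpacers(scanPairs(plf$sequences, q), 24))

  # infeasible packing is a configuration error
  tiny <- Biostrings::DNAStringSet(c(t = randSeq(60)))
  expect_error(plantPairs(tiny, q, spacerLen = 10, n = 10, seed = 1),
               "configuration error")
})

test_that("minus-strand regions receive reverse-complemented sites", {
  q <- motifPairQuery("AAAG", "ACGT")
  base <- Biostrings::DNAStringSet(c(chr = randSeq(5000)))
  reg <- GenomicRanges::GRanges("chr", IRanges::IRanges(1000, 2000),
                                strand = "-")
  pl <- plantPairs(base, q, spacerLen = 6, n = 3, seed = 5, regions = reg,
                   minGap = 40)
  # on the plus strand the site reads as the reverse complement ...
  plus <- scanPairs(pl$sequences, q)
  plusKeys <- paste(mcols(plus)$leftStart, mcols(plus)$spacerLen)
  expect_false(any(paste(pl$truth$start, 6) %in% plusKeys))
  # ... and the gene-oriented (reverse-complemented) region sees the pair
  rc <- Biostrings::reverseComplement(pl$sequences[[1]])
  rcHits <- scanPairs(rc, q)
  expect_gte(sum(mcols(rcHits)$spacerLen == 6), 3L)
})

test_that("condition studies realize their planted lift", {
  st <- simulateConditionStudy(nGenes = 800, lift = 1.5, seed = 7)
  # recompute the statistic through the pipeline, not the generator
  r <- likelihood(st$geneSet, genesWithSpacer(st$index),
                  geneUniverse(st$index))
  expect_equal(r$L, st$realizedLift)
  expect_lt(abs(r$L - 1.5), 0.15)

  # zero lift means no overlap at all
  st0 <- simulateConditionStudy(nGenes = 400, lift = 0, seed = 9)
  expect_equal(st0$realizedLift, 0)
  expect_length(intersect(geneIds(st0$geneSet), st0$B), 0L)

  # infeasible lift is rejected up front
  expect_error(sampleConditionSet(paste0("g", 1:50), paste0("g", 1:100),
                                  50, 3), "infeasible")
})

test_that("bernoulli sampling fluctuates around the target lift", {
  u <- paste0("g", 1:2000)
  B <- u[1:900]
  set.seed(77)
  Ls <- replicate(300, {
    A <- sampleConditionSet(B, u, 200, 1.0, method = "bernoulli")
    likelihood(A, B, u)$L
  })
  expect_lt(abs(mean(Ls) - 1), 0.05)
  expect_gt(sd(Ls), 0)
})

test_that("bundled example sequences have the documented lengths", {
  ex <- exampleSequences()
  expect_equal(unname(Biostrings::width(ex)), c(139L, 32L, 22L, 62L))
  expect_equal(names(ex), c("mps", "spacer24_example", "spacer14_example",
                            "cloning_insert"))
  # round-trip through FASTA leaves residues identical
  fa <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(ex, fa)
  expect_identical(as.character(readGenome(fa)), as.character(ex))
})
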