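# deterministic index built from in-memory promoters
idxFromPromoters <- function(seqs) {
  buildMotifGeneIndex(Biostrings::DNAStringSet(seqs),
                      motifPairQuery("AAAG", "ACGT"))
}

test_that("gene-spacer matrix holds per-gene per-spacer hit counts", {
  seqs <- c(g1 = paste0("AAAGTTTTTTTACGTTTTTTTAAAGTTTTTTTACGT", strrep("T", 30)),
            g2 = strrep("T", 60),
            g3 = paste0("AAAGACGT", strrep("T", 50)))
  idx <- idxFromPromoters(seqs)
  m <- buildGeneSpacerMatrix(idx, names(seqs))
  expect_equal(dim(m), c(3L, 31L))
  expect_equal(m["g1", "7"], 2L)
  expect_equal(m["g3", "0"], 1L)
  expect_equal(sum(m["g2", ]), 0L)  # all-zero row retained
  # row sums equal the per-gene hit counts from the scanner
  hits <- scanPairs(Biostrings::DNAStringSet(seqs),
                    motifPairQuery("AAAG", "ACGT"))
  perGene <- table(factor(as.character(seqnames(hits)),
                          levels = names(seqs)))
  expect_equal(unname(rowSums(m)), unname(as.numeric(perGene)))

  expect_error(buildGeneSpacerMatrix(idx, c("g1", "nope")),
               "reference error")

  mb <- buildGeneSpacerMatrix(idx, names(seqs), binary = TRUE)
  expect_equal(mb["g1", "7"], 1L)
})

test_that("zero-occurrence spacer columns are dropped, nothing else changes", {
  m <- matrix(0L, 4, 31, dimnames = list(paste0("g", 1:4), 0:30))
  m[1, "3"] <- 2L; m[2, "3"] <- 1L; m[3, "9"] <- 4L
  pruned <- dropZeroSpacers(m)
  expect_equal(colnames(pruned), c("3", "9"))
  expect_equal(pruned[, "3"], m[, "3"])
  expect_equal(rownames(pruned), rownames(m))

  # no zero columns: identity
  full <- matrix(1L, 3, 4, dimnames = list(letters[1:3], 1:4))
  expect_identical(dropZeroSpacers(full), full)
  # adding an all-zero column then pruning restores the original
  withZero <- cbind(full, `99` = 0L)
  expect_identical(dropZeroSpacers(withZero), full)

  expect_error(dropZeroSpacers(matrix(0L, 2, 2)), "degenerate")
})

test_that("k-means is deterministic given seed and rejects degenerate input", {
  set.seed(61)
  m <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(paste0("g", 1:40), 1:5))
  r1 <- kmeansCluster(m, 3, seed = 7)
  r2 <- kmeansCluster(m, 3, seed = 7)
  expect_identical(clusterAssignments(r1), clusterAssignments(r2))
  expect_true(abs(r1@meanSilhouette) <= 1)

  same <- matrix(1, 5, 3, dimnames = list(paste0("g", 1:5), 1:3))
  expect_error(kmeansCluster(same, 2, seed = 1), "degenerate")
  expect_error(kmeansCluster(m, 1, seed = 1), "argument error")
})

test_that("K equal to the number of rows yields singleton clusters", {
  m <- matrix(c(0, 0, 10, 10, 20, 20), 3, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), 1:2))
  r <- kmeansCluster(m, 3, seed = 2)
  expect_equal(sort(unname(clusterAssignments(r))), 1:3)
  expect_equal(r@meanSilhouette, 0)  # undefined -> zero contribution
})

test_that("silhouette selection recovers three planted gene groups", {
  set.seed(67)
  blob <- function(center, n = 15) {
    t(replicate(n, center + rpois(length(center), 0.3)))
  }
  m <- rbind(blob(c(8, 0, 0, 0)), blob(c(0, 8, 0, 0)), blob(c(0, 0, 0, 8)))
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))), c(2, 7, 15, 28))
  res <- selectK(m, 2:7, seed = 3)
  expect_equal(selectedK(res), 3L)
  expect_true(all(silhouetteByK(res) >= -1 & silhouetteByK(res) <= 1))
  truth <- rep(1:3, each = 15)
  expect_true(all(table(clusterAssignments(res), truth) %in% c(0L, 15L)))
  expect_false(res@lowSeparation)
})

test_that("a single blob is flagged as weakly separated", {
  set.seed(71)
  m <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(paste0("g", 1:60), 1:4))
  res <- selectK(m, 2:6, seed = 5)
  expect_true(res@lowSeparation)
  expect_equal(selectedK(res),
               as.integer(names(which.max(silhouetteByK(res)))))
})

test_that("clustering is invariant to row order up to label permutation", {
  set.seed(73)
  m <- rbind(matrix(rnorm(20 * 3, 0), 20, 3),
             matrix(rnorm(20 * 3, 12), 20, 3))
  rownames(m) <- paste0("g", 1:40); colnames(m) <- 1:3
  perm <- sample(nrow(m))
  r1 <- kmeansCluster(m, 2, seed = 11)
  r2 <- kmeansCluster(m[perm, ], 2, seed = 11)
  a1 <- clusterAssignments(r1)
  a2 <- clusterAssignments(r2)[names(a1)]
  expect_equal(length(unique(paste(a1, a2))), 2L)  # consistent relabeling
})

test_that("clustering outputs serialize to TSV", {
  m <- rbind(matrix(0, 5, 2), matrix(9, 5, 2))
  dimnames(m) <- list(paste0("g", 1:10), 1:2)
  res <- selectK(m, 2, seed = 1)
  fa <- withr::local_tempfile(fileext = ".tsv")
  fs <- withr::local_tempfile(fileext = ".tsv")
  writeClusteringTsv(res, fa, fs)
  asg <- read.table(fa, header = TRUE, sep = "\t")
  expect_equal(nrow(asg), 10L)
  sil <- read.table(fs, header = TRUE, sep = "\t")
  expect_equal(sil$K, 2L)
})
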