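mkProfile <- function(counts, totalBp, label = "AAAG(N)ACGT") {
  new("SpacerProfile", label = label,
      counts = setNames(as.integer(counts), seq_along(counts) - 1L),
      totalBp = totalBp, nSequences = 1L)
}

test_that("normalization divides counts by coverage and is invertible", {
  p <- mkProfile(c(rep(0, 5), 100), 1000)
  np <- normalizeProfile(p)
  expect_equal(unname(normalizedCounts(np)["5"]), 0.1)

  expect_equal(sum(normalizedCounts(normalizeProfile(
    mkProfile(rep(0, 31), 500)))), 0)

  set.seed(3)
  cnt <- rpois(31, 40)
  p2 <- mkProfile(cnt, 123456)
  expect_equal(unname(normalizedCounts(normalizeProfile(p2)) * 123456),
               as.numeric(cnt))
})

test_that("enrichment is an element-wise ratio with undefined entries flagged", {
  prom <- mkProfile(rep(2, 31), 1000)    # 0.002 per bp
  gen <- mkProfile(rep(20, 31), 10000)   # 0.002 per bp
  e1 <- enrichment(prom, gen)
  expect_equal(unname(enrichmentRatios(e1)), rep(1, 31))

  gen2 <- mkProfile(rep(10, 31), 10000)  # 0.001 per bp
  e2 <- enrichment(prom, gen2)
  expect_equal(enrichmentRange(e2), c(2, 2))

  gen3 <- mkProfile(c(0, rep(10, 30)), 10000)
  e3 <- enrichment(prom, gen3)
  expect_true(is.na(enrichmentRatios(e3)["0"]))
  expect_equal(unname(enrichmentRatios(e3)["1"]), 2)

  expect_error(enrichment(prom, mkProfile(rep(1, 31), 10, label = "other")),
               "different queries")
})

test_that("self-enrichment of a region set is exactly 1", {
  set.seed(17)
  q <- motifPairQuery("AAAG", "ACGT")
  p <- spacerProfile(randSeq(20000), q)
  e <- enrichment(p, p)
  r <- enrichmentRatios(e)
  expect_true(all(r[!is.na(r)] == 1))
})

test_that("control set is the 12 shuffled-tetramer combinations", {
  ctl <- controlQueries("left-first")
  expect_length(ctl, 12L)
  expect_true("AAGA(N)CATG" %in% names(ctl))
  expect_true("GAAA(N)TCAG" %in% names(ctl))
  motifs <- unlist(lapply(ctl, function(q) c(leftMotif(q), rightMotif(q))))
  expect_false(any(motifs %in% c("AAAG", "ACGT")))
  expect_true(all(vapply(ctl, function(q)
    identical(spacerRange(q), c(0L, 30L)), logical(1))))

  rev <- controlQueries("right-first")
  expect_true("CATG(N)AAGA" %in% names(rev))
  expect_length(rev, 12L)

  prof <- controlProfiles(c(s = "AAGATTTCATGGCATAAGA"), "left-first")
  expect_equal(nrow(prof), 12L * 31L)
  expect_gte(sum(prof$count[prof$control_label == "AAGA(N)CATG"]), 1L)
})

test_that("paired t-test matches the closed-form oracle", {
  r <- pairedTTest(c(1, 2, 3, 4), c(2, 2, 4, 3))
  expect_equal(round(testStatistic(r), 3), -0.522)
  expect_equal(degreesOfFreedom(r), 3)

  set.seed(29)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    got <- pairedTTest(x, y)
    want <- oracleTTest(x, y)
    expect_equal(testStatistic(got), want$t, tolerance = 1e-9)
    expect_equal(pValue(got), want$p, tolerance = 1e-9)
    expect_equal(degreesOfFreedom(got), want$df)
    # antisymmetry
    swap <- pairedTTest(y, x)
    expect_equal(testStatistic(swap), -testStatistic(got), tolerance = 1e-12)
    expect_equal(pValue(swap), pValue(got), tolerance = 1e-12)
  }
  expect_error(pairedTTest(1:4, 1:4), "degenerate")
  expect_error(pairedTTest(1:4, 1:3), "unequal")
})

test_that("t critical value behaves like the t quantile", {
  expect_equal(round(tCritical(30, 0.05), 2), 2.04)
  expect_lt(abs(tCritical(1e6, 0.05) - qnorm(0.975)), 1e-3)
  vals <- vapply(c(2, 5, 10, 30, 100), tCritical, numeric(1), alpha = 0.05)
  expect_true(all(diff(vals) < 0))
  expect_error(tCritical(0, 0.05), "argument error")
  expect_error(tCritical(10, 1.5), "argument error")
})

test_that("Pearson correlation matches the closed-form oracle", {
  expect_equal(testStatistic(pearsonTest(1:10, 2 * (1:10) + 1)), 1)
  expect_equal(testStatistic(pearsonTest(1:10, -(1:10))), -1)
  expect_equal(round(testStatistic(
    pearsonTest(1:6, c(2, 1, 4, 3, 6, 5))), 1), 0.8)

  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- pearsonTest(x, y)
    want <- oraclePearson(x, y)
    expect_equal(testStatistic(got), want$r, tolerance = 1e-9)
    expect_equal(pValue(got), want$p, tolerance = 1e-9)
  }
  expect_error(pearsonTest(rep(1, 5), 1:5), "degenerate")
})

test_that("orientation comparison table round-trips through TSV", {
  p1 <- mkProfile(rep(4, 31), 1000)
  p2 <- mkProfile(rep(2, 31), 1000)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeOrientationTsv(p1, p2, tsv)
  df <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 31L)
  expect_equal(df$ratio, rep(2, 31))
})
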