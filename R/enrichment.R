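# Coverage normalization, promoter-vs-genome enrichment, shuffled-tetramer
# control queries and the statistical comparisons (paired t, Pearson).
# Test machinery is delegated to stats::t.test / stats::cor.test behind the
# module surface; degenerate inputs are rejected up front so the statistics
# are never silently +/-Inf.

#' Normalize a spacer profile by genomic coverage
#'
#' Divides each per-spacer count by the total number of scanned bases,
#' giving a per-bp frequency that can be compared between region sets of
#' very different size (e.g. 1-kb promoters versus whole chromosomes).
#'
#' @param profile a \linkS4class{SpacerProfile} with positive coverage.
#' @return A \linkS4class{NormalizedProfile}.
#' @export
normalizeProfile <- function(profile) {
  stopifnot(is(profile, "SpacerProfile"))
  if (profile@totalBp <= 0) stop("argument error: totalBp must be positive")
  new("NormalizedProfile", label = profile@label,
      normalized = profile@counts / profile@totalBp,
      counts = profile@counts, totalBp = profile@totalBp)
}

.asNormalized <- function(x) {
  if (is(x, "SpacerProfile")) normalizeProfile(x) else x
}

#' Promoter-versus-genome enrichment per spacer length
#'
#' Element-wise ratio of the promoter per-bp pair frequency to the genome
#' per-bp frequency.  Spacer lengths at which the genome frequency is zero
#' are flagged undefined (\code{NA} ratio) rather than reported as zero or
#' infinite.
#'
#' @param promoter,genome \linkS4class{NormalizedProfile} (or
#'   \linkS4class{SpacerProfile}, normalized on the fly) for the same query
#'   and spacer range.
#' @return An \linkS4class{EnrichmentResult}.
#' @export
enrichment <- function(promoter, genome) {
  p <- .asNormalized(promoter); g <- .asNormalized(genome)
  if (p@label != g@label)
    stop("argument error: profiles come from different queries (",
         p@label, " vs ", g@label, ")")
  if (!identical(names(p@normalized), names(g@normalized)))
    stop("argument error: profiles cover different spacer ranges")
  ratio <- ifelse(g@normalized > 0, p@normalized / g@normalized, NA_real_)
  def <- ratio[!is.na(ratio)]
  if (!length(def)) stop("degenerate input: no defined enrichment ratios")
  new("EnrichmentResult", label = p@label,
      spacer = as.integer(names(p@normalized)),
      promoterFreq = unname(p@normalized), genomeFreq = unname(g@normalized),
      ratio = unname(ratio), minRatio = min(def), maxRatio = max(def))
}

#' Overall fold enrichment across the spacer range
#'
#' Ratio of total per-bp pair frequency (all spacer lengths pooled) in one
#' region set over another; the single-number summary used when checking
#' recovery of a planted enrichment factor.
#'
#' @inheritParams enrichment
#' @return A single numeric fold value.
#' @export
foldEnrichment <- function(promoter, genome) {
  p <- .asNormalized(promoter); g <- .asNormalized(genome)
  gs <- sum(g@counts) / g@totalBp
  if (gs == 0) stop("degenerate input: no genome hits")
  (sum(p@counts) / p@totalBp) / gs
}

#' Shuffled-tetramer control queries
#'
#' The significance of the true AAAG/ACGT pairing is assessed against 12
#' control pairings built from shuffles of the two motifs that are not
#' themselves conserved cis-elements: AAGA, AGAA, GAAA on the Dof side and
#' CATG, GCAT, GTAC, TCAG on the bZIP side.  All 3 x 4 ordered combinations
#' are generated for the requested orientation with the same spacer range.
#'
#' @param orientation \code{"left-first"} for controls mirroring
#'   AAAG(N)ACGT (shuffled-AAAG motif first), \code{"right-first"} for the
#'   ACGT(N)AAAG mirror.
#' @param minSpacer,maxSpacer spacer range passed to every control query.
#' @return Named list of 12 \linkS4class{MotifPairQuery} objects, in the
#'   deterministic order left-control-major.
#' @export
controlQueries <- function(orientation = c("left-first", "right-first"),
                           minSpacer = 0L, maxSpacer = 30L) {
  orientation <- match.arg(orientation)
  leftCtrl <- c("AAGA", "AGAA", "GAAA")
  rightCtrl <- c("CATG", "GCAT", "GTAC", "TCAG")
  out <- list()
  for (l in leftCtrl) for (r in rightCtrl) {
    q <- if (orientation == "left-first")
      motifPairQuery(l, r, minSpacer, maxSpacer)
    else motifPairQuery(r, l, minSpacer, maxSpacer)
    out[[queryLabel(q)]] <- q
  }
  out
}

#' Profile all control queries over a sequence set
#'
#' @param x sequences (as in \code{\link{scanPairs}}).
#' @param orientation passed to \code{\link{controlQueries}}.
#' @param minSpacer,maxSpacer spacer range.
#' @return Long-format data.frame with columns \code{control_label},
#'   \code{spacer_len}, \code{count}.
#' @export
controlProfiles <- function(x, orientation = c("left-first", "right-first"),
                            minSpacer = 0L, maxSpacer = 30L) {
  qs <- controlQueries(orientation, minSpacer, maxSpacer)
  do.call(rbind, lapply(qs, function(q) {
    pr <- spacerProfile(x, q)
    data.frame(control_label = q@label,
               spacer_len = as.integer(names(pr@counts)),
               count = as.integer(pr@counts), row.names = NULL)
  }))
}

#' Paired Student's t-test
#'
#' Two-tailed paired t-test on equal-length samples, e.g. the 31 per-spacer
#' counts (N = 0..30) of the two orientations.  All-identical differences
#' are rejected as degenerate rather than producing an infinite statistic.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return A \linkS4class{SpacerTest} with t, df = n-1 and the two-tailed
#'   p-value.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("argument error: unequal lengths")
  if (length(x) < 2L) stop("argument error: need n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate input: differences have zero variance")
  ht <- stats::t.test(x, y, paired = TRUE)
  new("SpacerTest", statistic = unname(ht$statistic),
      df = unname(ht$parameter), pValue = ht$p.value,
      n = length(x), method = "paired t-test")
}

#' Two-tailed critical value of Student's t
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha two-tailed significance level in (0,1), default 0.05.
#' @return The (1 - alpha/2) quantile of the t distribution; 2.04 for
#'   df = 30, alpha = 0.05.
#' @export
tCritical <- function(df, alpha = 0.05) {
  if (!is.numeric(df) || df < 1) stop("argument error: df must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("argument error: alpha must lie in (0,1)")
  stats::qt(1 - alpha / 2, df)
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with its two-tailed p-value, e.g. between the
#' two orientations' counts over spacers 6-11.
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return A \linkS4class{SpacerTest}; the \code{statistic} slot holds r and
#'   \code{df} is n-2.
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y)) stop("argument error: unequal lengths")
  if (length(x) < 3L) stop("argument error: need n >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  ht <- stats::cor.test(x, y, method = "pearson")
  new("SpacerTest", statistic = unname(ht$estimate),
      df = unname(ht$parameter), pValue = ht$p.value,
      n = length(x), method = "Pearson correlation")
}

#' Write the two-orientation per-spacer comparison table
#'
#' Columns: spacer_len, count_orient1, count_orient2, norm1, norm2, ratio
#' (norm1/norm2, '.' where undefined).
#'
#' @param profile1,profile2 \linkS4class{SpacerProfile}s for the two
#'   orientations over the same spacer range.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeOrientationTsv <- function(profile1, profile2, path) {
  n1 <- normalizeProfile(profile1)@normalized
  n2 <- normalizeProfile(profile2)@normalized
  ratio <- ifelse(n2 > 0, signif(n1 / n2, 6), NA)
  df <- data.frame(spacer_len = as.integer(names(profile1@counts)),
                   count_orient1 = as.integer(profile1@counts),
                   count_orient2 = as.integer(profile2@counts),
                   norm1 = signif(n1, 6), norm2 = signif(n2, 6),
                   ratio = ratio)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}
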