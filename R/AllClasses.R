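# Central S4 classes.  All containers are deliberately small: sequence data
# live in Biostrings/GenomicRanges objects, and these classes only add the
# bookkeeping the analysis needs (query definitions, per-spacer counts,
# thresholds, gene indexes).

#' MotifPairQuery: an ordered motif pair with an allowed spacer range
#'
#' Defines one orientation of a motif-pair search: a left motif, a right
#' motif, and the inclusive range of spacer lengths (in bp) permitted between
#' the end of the left motif and the start of the right motif.
#'
#' @slot leftMotif character(1), nucleotide string over A/C/G/T.
#' @slot rightMotif character(1), nucleotide string over A/C/G/T.
#' @slot minSpacer,maxSpacer integer(1), inclusive spacer bounds in bp.
#' @slot label character(1), display label such as \code{"AAAG(N)ACGT"}.
#'
#' @export
setClass("MotifPairQuery",
  representation(leftMotif = "character", rightMotif = "character",
                 minSpacer = "integer", maxSpacer = "integer",
                 label = "character"))

setValidity("MotifPairQuery", function(object) {
  msg <- character()
  for (m in c(object@leftMotif, object@rightMotif)) {
    if (length(m) != 1L || !nzchar(m) || grepl("[^ACGT]", m))
      msg <- c(msg, "motifs must be non-empty strings over {A,C,G,T}")
  }
  if (object@minSpacer < 0L || object@minSpacer > object@maxSpacer)
    msg <- c(msg, "need 0 <= minSpacer <= maxSpacer")
  if (length(msg)) msg else TRUE
})

#' Construct a motif-pair query
#'
#' @param leftMotif,rightMotif nucleotide strings over A/C/G/T; the left motif
#'   must occur upstream (5') of the right motif in a hit.
#' @param minSpacer,maxSpacer inclusive spacer-length range in bp
#'   (defaults 0 and 30, the range over which transcription-factor pairs are
#'   typically reported to interact).
#' @param label optional display label; defaults to
#'   \code{"<left>(N)<right>"}.
#' @return A \linkS4class{MotifPairQuery} object.
#' @examples
#' motifPairQuery("AAAG", "ACGT")
#' @export
motifPairQuery <- function(leftMotif, rightMotif, minSpacer = 0L,
                           maxSpacer = 30L, label = NULL) {
  if (is.null(label))
    label <- paste0(leftMotif, "(N)", rightMotif)
  new("MotifPairQuery", leftMotif = toupper(leftMotif),
      rightMotif = toupper(rightMotif),
      minSpacer = as.integer(minSpacer), maxSpacer = as.integer(maxSpacer),
      label = label)
}

#' @describeIn motifPairQuery Left motif accessor.
#' @param query a \linkS4class{MotifPairQuery}.
#' @export
leftMotif <- function(query) query@leftMotif

#' @describeIn motifPairQuery Right motif accessor.
#' @export
rightMotif <- function(query) query@rightMotif

#' @describeIn motifPairQuery Spacer range accessor (length-2 integer).
#' @export
spacerRange <- function(query) c(query@minSpacer, query@maxSpacer)

#' @describeIn motifPairQuery Label accessor.
#' @export
queryLabel <- function(query) query@label

#' @describeIn motifPairQuery Query for the opposite orientation
#'   (motifs swapped, same spacer range).
#' @export
swapOrientation <- function(query) {
  motifPairQuery(query@rightMotif, query@leftMotif,
                 query@minSpacer, query@maxSpacer)
}

setMethod("show", "MotifPairQuery", function(object) {
  cat("MotifPairQuery: ", object@label, "  [spacer ", object@minSpacer,
      "-", object@maxSpacer, " bp]\n", sep = "")
})

#' SpacerFrequencyProfile: per-spacer pair counts over a region set
#'
#' @slot label query label the profile belongs to.
#' @slot counts named integer vector, one entry per spacer length in the
#'   query range (names are spacer lengths in bp).
#' @slot totalBp numeric(1), summed length in bp of all scanned sequences
#'   (the "genomic coverage" used for normalization).
#' @slot nSequences integer(1), number of scanned sequences.
#'
#' @export
setClass("SpacerProfile",
  representation(label = "character", counts = "integer",
                 totalBp = "numeric", nSequences = "integer"))

setValidity("SpacerProfile", function(object) {
  msg <- character()
  if (is.null(names(object@counts)))
    msg <- c(msg, "counts must be named by spacer length")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be nonnegative")
  if (object@totalBp <= 0) msg <- c(msg, "totalBp must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn spacerProfile Named per-spacer count accessor.
#' @export
spacerCounts <- function(profile) profile@counts

#' @describeIn spacerProfile Total scanned bp (genomic coverage).
#' @export
totalBp <- function(profile) profile@totalBp

#' @describeIn spacerProfile Number of scanned sequences.
#' @export
nSequences <- function(profile) profile@nSequences

setMethod("show", "SpacerProfile", function(object) {
  cat("SpacerProfile: ", object@label, "\n  ", sum(object@counts),
      " pair hits over ", length(object@counts), " spacer lengths; ",
      object@nSequences, " sequence(s), ", format(object@totalBp,
      big.mark = ","), " bp scanned\n", sep = "")
})

#' NormalizedProfile: per-bp pair frequencies
#'
#' A \linkS4class{SpacerProfile} whose counts have been divided by the total
#' scanned bp, giving a per-bp frequency comparable across region sets of
#' different size.
#'
#' @slot label query label.
#' @slot normalized named numeric vector of per-bp frequencies.
#' @slot counts the source integer counts.
#' @slot totalBp scanned bp used as the divisor.
#' @export
setClass("NormalizedProfile",
  representation(label = "character", normalized = "numeric",
                 counts = "integer", totalBp = "numeric"))

#' @describeIn normalizeProfile Named per-bp frequency accessor.
#' @param x a \linkS4class{NormalizedProfile}.
#' @export
normalizedCounts <- function(x) x@normalized

setMethod("show", "NormalizedProfile", function(object) {
  cat("NormalizedProfile: ", object@label, " (", format(object@totalBp,
      big.mark = ","), " bp)\n", sep = "")
  print(signif(object@normalized, 4))
})

#' PromoterSet: strand-aware upstream promoter sequences
#'
#' Holds the extracted promoter sequences (5'->3' relative to each gene,
#' unless extraction was run with \code{reverseMinus = FALSE}) together with
#' the genomic intervals they came from.
#'
#' @slot sequences \code{DNAStringSet} named by gene id.
#' @slot regions \code{GRanges} of the source genomic intervals, with
#'   metadata columns \code{gene_id} and \code{truncated} (promoter shorter
#'   than requested because the gene sits near a contig edge).
#' @slot upstreamLen integer(1), requested promoter length in bp.
#' @export
setClass("PromoterSet",
  representation(sequences = "DNAStringSet", regions = "GRanges",
                 upstreamLen = "integer"))

#' @describeIn extractPromoters Promoter sequences (\code{DNAStringSet},
#'   named by gene id).
#' @param x a \linkS4class{PromoterSet}.
#' @export
promoterSequences <- function(x) x@sequences

#' @describeIn extractPromoters Source genomic intervals (\code{GRanges}).
#' @export
promoterRegions <- function(x) x@regions

#' @describeIn extractPromoters Requested upstream length in bp.
#' @export
upstreamLength <- function(x) x@upstreamLen

setMethod("length", "PromoterSet", function(x) length(x@sequences))

setMethod("show", "PromoterSet", function(object) {
  n <- length(object@sequences)
  ntr <- sum(mcols(object@regions)$truncated)
  cat("PromoterSet: ", n, " promoters (requested ", object@upstreamLen,
      " bp upstream); ", ntr, " truncated at contig edges\n", sep = "")
})

#' ConsensusRule: thresholds for per-position consensus calls
#'
#' Because the A. thaliana genome is AT-rich (about 36\% GC), a G or C
#' appearing well above its background share is already informative at a
#' lower absolute fraction than A or T.  The rule therefore uses class
#' thresholds: a position is called for A or T when its fraction strictly
#' exceeds \code{atThreshold} (default 0.40) and for G or C when it strictly
#' exceeds \code{gcThreshold} (default 0.25).
#'
#' @slot atThreshold fraction in (0,1) for A/T calls.
#' @slot gcThreshold fraction in (0,1) for G/C calls.
#' @slot tieTolerance fractions within this distance of the top passing base
#'   are reported as a joined tie call such as \code{"G/C"}.
#' @slot backgroundGC genome GC fraction recorded for reporting.
#' @export
setClass("ConsensusRule",
  representation(atThreshold = "numeric", gcThreshold = "numeric",
                 tieTolerance = "numeric", backgroundGC = "numeric"))

setValidity("ConsensusRule", function(object) {
  ok <- function(v) length(v) == 1L && v > 0 && v < 1
  if (!ok(object@atThreshold) || !ok(object@gcThreshold))
    return("thresholds must lie in (0,1)")
  TRUE
})

#' Construct a consensus-calling rule
#'
#' @param atThreshold strict lower fraction for calling A or T (default 0.40).
#' @param gcThreshold strict lower fraction for calling G or C (default 0.25).
#' @param tieTolerance absolute fraction difference treated as an exact tie
#'   (default 1e-9).
#' @param backgroundGC background genome GC content, recorded for reporting
#'   (default 0.36).
#' @return A \linkS4class{ConsensusRule}.
#' @export
consensusRule <- function(atThreshold = 0.40, gcThreshold = 0.25,
                          tieTolerance = 1e-9, backgroundGC = 0.36) {
  new("ConsensusRule", atThreshold = atThreshold, gcThreshold = gcThreshold,
      tieTolerance = tieTolerance, backgroundGC = backgroundGC)
}

setMethod("show", "ConsensusRule", function(object) {
  cat("ConsensusRule: A/T > ", object@atThreshold, ", G/C > ",
      object@gcThreshold, " (background GC ", object@backgroundGC, ")\n",
      sep = "")
})

#' PositionComposition: per-position base fractions of collected spacers
#'
#' @slot fractions numeric matrix, rows A/C/G/T (plus N when present),
#'   columns spacer positions 1..N; entries are fractions of sequences
#'   carrying that base.
#' @slot nSequences integer(1), number of spacer sequences tallied.
#' @slot spacerLen integer(1), common spacer length N.
#' @export
setClass("PositionComposition",
  representation(fractions = "matrix", nSequences = "integer",
                 spacerLen = "integer"))

#' @describeIn spacerComposition Fraction matrix accessor.
#' @param x a \linkS4class{PositionComposition}.
#' @export
baseFractions <- function(x) x@fractions

setMethod("show", "PositionComposition", function(object) {
  cat("PositionComposition: ", object@nSequences, " spacers of length ",
      object@spacerLen, "\n", sep = "")
  print(round(object@fractions, 3))
})

#' GeneSet: a condition-regulated gene list
#'
#' @slot condition condition label, e.g. \code{"jasmonic acid"}.
#' @slot direction one of \code{"up"}, \code{"down"}, \code{"up-down"}.
#' @slot geneIds unique character vector of gene identifiers.
#' @export
setClass("GeneSet",
  representation(condition = "character", direction = "character",
                 geneIds = "character"))

setValidity("GeneSet", function(object) {
  if (!object@direction %in% c("up", "down", "up-down"))
    return("direction must be 'up', 'down' or 'up-down'")
  if (anyDuplicated(object@geneIds)) return("gene ids must be unique")
  TRUE
})

#' Construct a condition gene set
#'
#' @param condition condition label (e.g. a hormone or stress).
#' @param direction regulation direction: \code{"up"}, \code{"down"} or
#'   \code{"up-down"}.
#' @param geneIds character vector of gene identifiers (deduplicated).
#' @return A \linkS4class{GeneSet}.
#' @export
geneSet <- function(condition, direction, geneIds) {
  new("GeneSet", condition = condition, direction = direction,
      geneIds = unique(as.character(geneIds)))
}

#' @describeIn geneSet Gene-id accessor.
#' @param x a \linkS4class{GeneSet}.
#' @export
geneIds <- function(x) x@geneIds

setMethod("length", "GeneSet", function(x) length(x@geneIds))

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet: ", object@condition, " (", object@direction, "), ",
      length(object@geneIds), " genes\n", sep = "")
})

#' MotifGeneIndex: which genes carry the motif pair, at which spacers
#'
#' Maps each gene whose promoter contains at least one pair hit to its
#' per-spacer hit counts, and records the full gene universe so that
#' likelihood statistics can be computed.
#'
#' @slot label query label the index was built for.
#' @slot hitCounts named list; for each indexed gene, a named integer vector
#'   of hit counts by spacer length.
#' @slot universe character vector of all genes in the scanned promoter set.
#' @slot minSpacer,maxSpacer spacer range of the query.
#' @export
setClass("MotifGeneIndex",
  representation(label = "character", hitCounts = "list",
                 universe = "character", minSpacer = "integer",
                 maxSpacer = "integer"))

setValidity("MotifGeneIndex", function(object) {
  if (!all(names(object@hitCounts) %in% object@universe))
    return("indexed genes must belong to the universe")
  TRUE
})

#' @describeIn buildMotifGeneIndex Genes with at least one hit at spacer
#'   \code{N} (all indexed genes when \code{N} is \code{NULL}).
#' @param index a \linkS4class{MotifGeneIndex}.
#' @param N spacer length in bp, or \code{NULL}.
#' @export
genesWithSpacer <- function(index, N = NULL) {
  if (is.null(N)) return(names(index@hitCounts))
  keep <- vapply(index@hitCounts,
                 function(v) as.character(N) %in% names(v), logical(1))
  names(index@hitCounts)[keep]
}

#' @describeIn buildMotifGeneIndex Full gene universe of the index.
#' @export
geneUniverse <- function(index) index@universe

#' @describeIn buildMotifGeneIndex Per-gene spacer-length sets (named list of
#'   integer vectors).
#' @export
spacerSets <- function(index) {
  lapply(index@hitCounts, function(v) as.integer(names(v)))
}

setMethod("show", "MotifGeneIndex", function(object) {
  cat("MotifGeneIndex: ", object@label, "\n  ", length(object@hitCounts),
      " of ", length(object@universe), " genes carry >=1 pair (spacer ",
      object@minSpacer, "-", object@maxSpacer, " bp)\n", sep = "")
})

#' SpacerTest: result of a two-sample or correlation test
#'
#' @slot statistic test statistic (t, or Pearson's r for correlation tests).
#' @slot df degrees of freedom.
#' @slot pValue two-tailed p-value.
#' @slot n number of paired observations.
#' @slot method short description of the test.
#' @export
setClass("SpacerTest",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 n = "integer", method = "character"))

setMethod("show", "SpacerTest", function(object) {
  cat(object@method, ": statistic = ", signif(object@statistic, 4),
      ", df = ", object@df, ", p = ", signif(object@pValue, 4),
      " (n = ", object@n, ")\n", sep = "")
})

#' @describeIn pairedTTest Statistic accessor (t, or r for Pearson).
#' @param x a \linkS4class{SpacerTest}.
#' @export
testStatistic <- function(x) x@statistic

#' @describeIn pairedTTest Two-tailed p-value accessor.
#' @export
pValue <- function(x) x@pValue

#' @describeIn pairedTTest Degrees-of-freedom accessor.
#' @export
degreesOfFreedom <- function(x) x@df

#' EnrichmentResult: promoter-versus-genome per-spacer enrichment
#'
#' @slot label query label.
#' @slot spacer integer vector of spacer lengths.
#' @slot promoterFreq,genomeFreq per-bp frequencies in the two region sets.
#' @slot ratio promoter/genome ratio; \code{NA} where the genome frequency is
#'   zero (flagged undefined rather than silently 0 or Inf).
#' @slot minRatio,maxRatio range of the defined ratios.
#' @export
setClass("EnrichmentResult",
  representation(label = "character", spacer = "integer",
                 promoterFreq = "numeric", genomeFreq = "numeric",
                 ratio = "numeric", minRatio = "numeric",
                 maxRatio = "numeric"))

#' @describeIn enrichment Per-spacer enrichment ratios (named numeric; NA
#'   where undefined).
#' @param x an \linkS4class{EnrichmentResult}.
#' @export
enrichmentRatios <- function(x) setNames(x@ratio, x@spacer)

#' @describeIn enrichment Range of defined ratios, \code{c(min, max)}.
#' @export
enrichmentRange <- function(x) c(x@minRatio, x@maxRatio)

setMethod("as.data.frame", "EnrichmentResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(spacer_len = x@spacer, promoter_norm = x@promoterFreq,
               genome_norm = x@genomeFreq, ratio = x@ratio)
  })

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult: ", object@label, "\n  ratio range [",
      signif(object@minRatio, 4), ", ", signif(object@maxRatio, 4),
      "] over ", sum(!is.na(object@ratio)), " defined spacer lengths\n",
      sep = "")
})

#' ClusteringResult: K-means partition with silhouette diagnostics
#'
#' @slot K selected number of clusters.
#' @slot assignments named integer vector, gene -> cluster id (1..K).
#' @slot silhouetteByK named numeric vector of mean silhouette widths for
#'   every K evaluated.
#' @slot meanSilhouette mean silhouette width at the selected K.
#' @slot seed RNG seed used.
#' @slot lowSeparation TRUE when the best mean silhouette indicates weak
#'   cluster structure (below 0.25), so the selected K should be reviewed.
#' @export
setClass("ClusteringResult",
  representation(K = "integer", assignments = "integer",
                 silhouetteByK = "numeric", meanSilhouette = "numeric",
                 seed = "integer", lowSeparation = "logical"))

#' @describeIn kmeansCluster Cluster assignments (named integer vector).
#' @param x a \linkS4class{ClusteringResult}.
#' @export
clusterAssignments <- function(x) x@assignments

#' @describeIn kmeansCluster Mean silhouette width per evaluated K.
#' @export
silhouetteByK <- function(x) x@silhouetteByK

#' @describeIn kmeansCluster Selected number of clusters.
#' @export
selectedK <- function(x) x@K

setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult: K = ", object@K, ", mean silhouette = ",
      signif(object@meanSilhouette, 3), " over ", length(object@assignments),
      " genes (seed ", object@seed, ")",
      if (object@lowSeparation) " [weak separation]" else "", "\n", sep = "")
})
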