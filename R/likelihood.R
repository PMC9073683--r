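# Likelihood-of-occurrence statistic: how much more often condition-regulated
# genes (event A) carry the motif pair in their promoter (event B) than
# expected by chance.  L = X / Y with X = |A n B| / |B| (fraction of
# motif-bearing genes that are condition-regulated) and Y = P(A) = |A| / U.
# L = 1 is random co-occurrence; conditions with L strictly above 1.25 are
# flagged.

#' Index genes by the spacer lengths of their promoter pair hits
#'
#' Scans every promoter for the motif-pair query and records, per gene, the
#' number of hits at each spacer length.  Genes without any hit are absent
#' from the index but still counted in the universe.
#'
#' @param x a \linkS4class{PromoterSet} or a named \code{DNAStringSet} of
#'   promoter sequences (names are gene ids).
#' @param query a \linkS4class{MotifPairQuery}.
#' @param minHits minimum number of pair hits (any spacer) for a gene to be
#'   indexed (default 1; raise for stricter readings of "multiple
#'   elements").
#' @return A \linkS4class{MotifGeneIndex}.
#' @export
buildMotifGeneIndex <- function(x, query, minHits = 1L) {
  seqs <- .asDNAStringSet(x)
  if (length(seqs) == 0L) stop("argument error: empty promoter set")
  hits <- scanPairs(seqs, query)
  universe <- names(seqs)
  byGene <- split(mcols(hits)$spacerLen, as.character(seqnames(hits)))
  byGene <- byGene[lengths(byGene) >= minHits]
  hitCounts <- lapply(byGene, function(v) {
    tb <- table(v)
    setNames(as.integer(tb), names(tb))
  })
  new("MotifGeneIndex", label = query@label, hitCounts = hitCounts,
      universe = universe, minSpacer = query@minSpacer,
      maxSpacer = query@maxSpacer)
}

#' Likelihood of occurrence for one gene set against one motif-gene set
#'
#' @param A a \linkS4class{GeneSet} (or character vector) of
#'   condition-regulated genes; must be non-empty and inside the universe.
#' @param B character vector of motif-pair-bearing genes; non-empty, inside
#'   the universe.
#' @param universe character vector of all genes under study.
#' @param threshold flagging threshold on L (strictly greater-than;
#'   default 1.25).
#' @return One-row data.frame with columns \code{condition},
#'   \code{direction}, \code{n_A}, \code{n_B}, \code{n_AB}, \code{universe},
#'   \code{X}, \code{Y}, \code{L}, \code{flagged}.
#' @examples
#' u <- paste0("g", 1:100)
#' likelihood(u[1:20], u[11:20], u)$L  # 5
#' @export
likelihood <- function(A, B, universe, threshold = 1.25) {
  condition <- NA_character_; direction <- NA_character_
  if (is(A, "GeneSet")) {
    condition <- A@condition; direction <- A@direction; A <- A@geneIds
  }
  A <- unique(A); B <- unique(B); universe <- unique(universe)
  if (length(A) == 0L || length(B) == 0L)
    stop("undefined statistic: |A| and |B| must both be positive")
  if (!all(A %in% universe) || !all(B %in% universe))
    stop("argument error: A and B must be subsets of the universe")
  nAB <- length(intersect(A, B))
  X <- nAB / length(B)
  Y <- length(A) / length(universe)
  L <- X / Y
  data.frame(condition = condition, direction = direction,
             n_A = length(A), n_B = length(B), n_AB = nAB,
             universe = length(universe), X = X, Y = Y, L = L,
             flagged = L > threshold)
}

#' Overall and per-spacer likelihood for one condition
#'
#' The overall statistic takes B as the union over the spacer range of the
#' per-spacer motif-bearing gene sets (genes with at least one hit at any N
#' in range).  Per-spacer rows are emitted alongside; spacer lengths with an
#' empty B get \code{NA} statistics rather than an error.  As an alternative
#' summary, a \code{"overall_mean"} row averages the defined per-spacer L
#' values.
#'
#' @param index a \linkS4class{MotifGeneIndex}.
#' @param A a \linkS4class{GeneSet} (or character vector).
#' @param spacerRange integer vector of spacer lengths (default the index's
#'   full range).
#' @param threshold flagging threshold (default 1.25).
#' @return data.frame with one row per spacer plus rows
#'   \code{spacer = "overall"} (union definition) and
#'   \code{"overall_mean"}; columns as in \code{\link{likelihood}} plus
#'   \code{spacer} and \code{orientation}.
#' @export
overallLikelihood <- function(index, A, spacerRange = NULL,
                              threshold = 1.25) {
  stopifnot(is(index, "MotifGeneIndex"))
  if (is.null(spacerRange)) spacerRange <- index@minSpacer:index@maxSpacer
  universe <- index@universe
  rowFor <- function(B, tag) {
    if (length(B) == 0L) {
      r <- likelihood(A, universe[1], universe, threshold)  # template shape
      r[, c("n_B", "n_AB", "X", "Y", "L")] <- NA
      r$flagged <- NA
    } else {
      r <- likelihood(A, B, universe, threshold)
    }
    cbind(data.frame(orientation = index@label, spacer = tag), r)
  }
  perSpacer <- lapply(spacerRange, function(N)
    rowFor(genesWithSpacer(index, N), as.character(N)))
  union_ <- unique(unlist(lapply(spacerRange, function(N)
    genesWithSpacer(index, N))))
  if (length(union_) == 0L)
    stop("undefined statistic: no gene carries the pair in the spacer range")
  res <- do.call(rbind, perSpacer)
  overall <- rowFor(union_, "overall")
  Ls <- res$L[!is.na(res$L)]
  overallMean <- overall
  overallMean$spacer <- "overall_mean"
  overallMean[, c("n_B", "n_AB", "X", "Y")] <- NA
  overallMean$L <- mean(Ls)
  overallMean$flagged <- mean(Ls) > threshold
  rbind(res, overall, overallMean)
}

#' Likelihood table over many condition gene sets
#'
#' @param index a \linkS4class{MotifGeneIndex}.
#' @param geneSets list of \linkS4class{GeneSet} objects.
#' @param spacerRange,threshold passed to \code{\link{overallLikelihood}}.
#' @return Row-bound data.frame over all gene sets.
#' @export
likelihoodTable <- function(index, geneSets, spacerRange = NULL,
                            threshold = 1.25) {
  do.call(rbind, lapply(geneSets, function(gs)
    overallLikelihood(index, gs, spacerRange, threshold)))
}

#' Flag conditions whose likelihood exceeds the threshold
#'
#' Strict greater-than comparison (L = 1.25 exactly is not flagged), sorted
#' by decreasing L.
#'
#' @param results data.frame from \code{\link{overallLikelihood}} or
#'   \code{\link{likelihoodTable}} (or any data.frame with an \code{L}
#'   column).
#' @param threshold flagging threshold (default 1.25).
#' @return The subset of rows with \code{L > threshold}, sorted by
#'   decreasing L.
#' @export
flagConditions <- function(results, threshold = 1.25) {
  keep <- !is.na(results$L) & results$L > threshold
  out <- results[keep, , drop = FALSE]
  out[order(-out$L), , drop = FALSE]
}

#' Read condition gene sets from a two-column TSV
#'
#' Expected columns: \code{condition_direction} (e.g.
#' \code{"jasmonic acid:down"}; anything after the last \code{:} is the
#' direction, defaulting to \code{"up-down"} when absent) and
#' \code{gene_id}.
#'
#' @param path TSV path (header optional; detected from the first line).
#' @return Named list of \linkS4class{GeneSet} objects.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  hasHeader <- identical(tolower(first[1]), "condition_direction")
  df <- read.table(path, sep = "\t", header = hasHeader,
                   col.names = c("condition_direction", "gene_id"),
                   colClasses = "character")
  out <- lapply(split(df$gene_id, df$condition_direction), function(ids) ids)
  sets <- lapply(names(out), function(cd) {
    parts <- strsplit(cd, ":", fixed = TRUE)[[1]]
    last <- parts[length(parts)]
    if (length(parts) > 1L && last %in% c("up", "down", "up-down")) {
      geneSet(paste(parts[-length(parts)], collapse = ":"), last, out[[cd]])
    } else {
      geneSet(cd, "up-down", out[[cd]])
    }
  })
  setNames(sets, names(out))
}

#' Write likelihood results as TSV
#'
#' @param results data.frame from \code{\link{likelihoodTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLikelihoodTsv <- function(results, path) {
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], function(v) signif(v, 6))
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}
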