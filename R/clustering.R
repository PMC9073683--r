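# Gene x spacer-length occurrence matrices and K-means clustering with
# silhouette-based selection of K.  K-means comes from stats::kmeans and
# silhouette widths from cluster::silhouette; matrix construction, pruning
# of uninformative spacer columns and the selection policy live here.

#' Build a gene-by-spacer occurrence matrix
#'
#' @param index a \linkS4class{MotifGeneIndex}.
#' @param geneIds genes to use as rows (default: all indexed genes).  Genes
#'   without hits get all-zero rows; ids outside the index universe are a
#'   reference error.
#' @param binary use presence/absence instead of hit counts (default
#'   \code{FALSE}; counts).
#' @return Integer matrix, rows named by gene id, columns by spacer length
#'   over the index's full range.
#' @export
buildGeneSpacerMatrix <- function(index, geneIds = NULL, binary = FALSE) {
  stopifnot(is(index, "MotifGeneIndex"))
  if (is.null(geneIds)) geneIds <- names(index@hitCounts)
  if (length(geneIds) == 0L) stop("argument error: no genes given")
  unknown <- setdiff(geneIds, index@universe)
  if (length(unknown))
    stop("reference error: gene id(s) not in universe: ",
         paste(head(unknown, 5), collapse = ", "))
  spacers <- index@minSpacer:index@maxSpacer
  m <- matrix(0L, nrow = length(geneIds), ncol = length(spacers),
              dimnames = list(geneIds, as.character(spacers)))
  for (g in intersect(geneIds, names(index@hitCounts))) {
    v <- index@hitCounts[[g]]
    m[g, names(v)] <- as.integer(v)
  }
  if (binary) m[] <- as.integer(m > 0L)
  m
}

#' Drop spacer columns with no occurrences
#'
#' Spacer lengths at which no gene has a hit carry no information for
#' clustering and are removed; retained entries and the row set are
#' unchanged.
#'
#' @param matrix gene-by-spacer matrix from
#'   \code{\link{buildGeneSpacerMatrix}}.
#' @return The matrix without all-zero columns.
#' @export
dropZeroSpacers <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) == 0L)
    stop("argument error: need a non-empty matrix")
  keep <- colSums(matrix) > 0
  if (!any(keep))
    stop("degenerate input: every spacer column is zero")
  matrix[, keep, drop = FALSE]
}

.meanSilhouette <- function(assignments, m) {
  K <- length(unique(assignments))
  if (K < 2L || K >= nrow(m)) {
    # silhouette undefined for singleton-only partitions; contribute 0
    if (K == nrow(m)) return(0)
    stop("silhouette needs 2 <= K < n rows")
  }
  sil <- cluster::silhouette(assignments, stats::dist(m))
  mean(sil[, "sil_width"])
}

#' K-means clustering of a gene-by-spacer matrix
#'
#' Euclidean K-means (no feature scaling by default, matching how the
#' occurrence counts are compared; set \code{standardize = TRUE} to z-score
#' columns first).  Deterministic given \code{(matrix, K, seed)}.
#'
#' @param matrix numeric matrix, genes in rows.
#' @param K number of clusters, \code{2 <= K <= nrow(matrix)}.
#' @param seed integer RNG seed (required; recorded in the result).
#' @param nstart random restarts passed to \code{stats::kmeans}
#'   (default 10).
#' @param standardize z-score columns before clustering (default
#'   \code{FALSE}).
#' @return A \linkS4class{ClusteringResult} for this single K.
#' @export
kmeansCluster <- function(matrix, K, seed, nstart = 10L,
                          standardize = FALSE) {
  if (!is.matrix(matrix)) stop("argument error: need a matrix")
  K <- as.integer(K)
  if (K < 2L || K > nrow(matrix))
    stop("argument error: need 2 <= K <= number of rows")
  m <- matrix
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    m <- scale(m, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  if (nrow(unique(m)) < K)
    stop("degenerate input: fewer than K distinct rows")
  set.seed(seed)
  if (K == nrow(m)) {
    # every row its own cluster: the unique zero-inertia partition
    assignments <- setNames(seq_len(nrow(m)), rownames(matrix))
  } else {
    km <- stats::kmeans(m, centers = K, nstart = nstart, iter.max = 100L)
    assignments <- setNames(as.integer(km$cluster), rownames(matrix))
  }
  msil <- .meanSilhouette(assignments, m)
  new("ClusteringResult", K = K, assignments = assignments,
      silhouetteByK = setNames(msil, K), meanSilhouette = msil,
      seed = as.integer(seed), lowSeparation = msil < 0.25)
}

#' Select K by mean silhouette width
#'
#' Fits K-means for every K in \code{kRange}, computes the mean silhouette
#' width of each partition, and returns the fit maximizing it (smallest K on
#' exact ties).  The full silhouette curve is kept in the result so the
#' automatic pick can be reviewed; \code{lowSeparation} is set when even the
#' best mean silhouette is below 0.25 (a flat, weak-structure curve, as for
#' a single blob of genes).
#'
#' @param matrix numeric matrix, genes in rows.
#' @param kRange integer vector of K values within \code{[2, nrow - 1]}
#'   (default \code{2:min(10, nrow - 1)}).
#' @param seed integer RNG seed used for every fit.
#' @param nstart,standardize passed to \code{\link{kmeansCluster}}.
#' @return A \linkS4class{ClusteringResult} at the selected K with
#'   \code{silhouetteByK} covering all evaluated K.
#' @export
selectK <- function(matrix, kRange = NULL, seed = 1L, nstart = 10L,
                    standardize = FALSE) {
  if (!is.matrix(matrix)) stop("argument error: need a matrix")
  n <- nrow(matrix)
  if (is.null(kRange)) kRange <- 2:min(10L, n - 1L)
  kRange <- as.integer(kRange)
  if (length(kRange) == 0L) stop("argument error: empty K range")
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop("argument error: kRange must lie within [2, nrow - 1]")
  fits <- lapply(sort(unique(kRange)), function(K)
    kmeansCluster(matrix, K, seed, nstart, standardize))
  sils <- vapply(fits, function(f) f@meanSilhouette, numeric(1))
  names(sils) <- vapply(fits, function(f) f@K, integer(1))
  best <- fits[[which.max(sils)]]  # which.max takes the smallest K on ties
  new("ClusteringResult", K = best@K, assignments = best@assignments,
      silhouetteByK = sils, meanSilhouette = best@meanSilhouette,
      seed = as.integer(seed), lowSeparation = max(sils) < 0.25)
}

#' Write clustering outputs as TSV
#'
#' Writes the assignments (gene, cluster) and the silhouette curve
#' (K, mean_silhouette).
#'
#' @param result a \linkS4class{ClusteringResult}.
#' @param assignmentsPath,silhouettePath output paths.
#' @return Invisible character vector of the written paths.
#' @export
writeClusteringTsv <- function(result, assignmentsPath, silhouettePath) {
  write.table(data.frame(gene_id = names(result@assignments),
                         cluster = as.integer(result@assignments)),
              assignmentsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(K = as.integer(names(result@silhouetteByK)),
                         mean_silhouette = signif(result@silhouetteByK, 6)),
              silhouettePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(assignmentsPath, silhouettePath))
}
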