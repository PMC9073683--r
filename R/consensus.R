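# Per-position base composition of collected spacer sequences and
# GC-adjusted consensus calling.

#' Per-position base composition of equal-length spacers
#'
#' Tallies, at every spacer position, the fraction of sequences carrying
#' each base.  Fractions at a position sum to 1 when all sequences are over
#' {A,C,G,T}; an N row appears (and A/C/G/T fractions sum below 1) when
#' ambiguous bases are present.
#'
#' @param spacers non-empty character vector (or \code{DNAStringSet}) of
#'   equal-length spacer sequences.
#' @return A \linkS4class{PositionComposition}.
#' @examples
#' baseFractions(spacerComposition(c("AG", "AG", "TG", "CG")))
#' @export
spacerComposition <- function(spacers) {
  if (is(spacers, "DNAStringSet")) spacers <- as.character(spacers)
  if (!is.character(spacers) || length(spacers) == 0L)
    stop("argument error: need a non-empty set of spacer sequences")
  w <- unique(nchar(spacers))
  if (length(w) != 1L)
    stop("argument error: spacer sequences must have equal length")
  if (w == 0L)
    stop("argument error: zero-length spacers have no composition")
  dss <- Biostrings::DNAStringSet(toupper(spacers))
  cm <- Biostrings::consensusMatrix(dss, as.prob = TRUE, baseOnly = TRUE)
  rownames(cm)[rownames(cm) == "other"] <- "N"
  keep <- rownames(cm) %in% c("A", "C", "G", "T") | rowSums(cm) > 0
  cm <- cm[keep, , drop = FALSE]
  colnames(cm) <- seq_len(ncol(cm))
  new("PositionComposition", fractions = cm,
      nSequences = length(spacers), spacerLen = as.integer(w))
}

#' Call a consensus from a position composition
#'
#' At each position, the bases whose fraction strictly exceeds their class
#' threshold are collected (A/T against \code{atThreshold}, G/C against
#' \code{gcThreshold}).  If none passes the call is \code{N}; if exactly one
#' passes, that base is called; if several pass, the base with the highest
#' fraction wins, with fractions within \code{tieTolerance} of the top
#' reported as a joined call such as \code{"G/C"}.
#'
#' @param composition a \linkS4class{PositionComposition}.
#' @param rule a \linkS4class{ConsensusRule} (defaults: A/T > 0.40,
#'   G/C > 0.25).
#' @return Character vector of per-position calls, length equal to the
#'   spacer length.
#' @examples
#' callConsensus(spacerComposition(c("AG", "AG", "TG", "CG")))  # "A" "G"
#' @export
callConsensus <- function(composition, rule = consensusRule()) {
  stopifnot(is(composition, "PositionComposition"), is(rule, "ConsensusRule"))
  fr <- composition@fractions
  thr <- c(A = rule@atThreshold, T = rule@atThreshold,
           G = rule@gcThreshold, C = rule@gcThreshold)
  displayOrder <- c("A", "T", "G", "C")  # ties print as "G/C", "A/T"
  vapply(seq_len(ncol(fr)), function(pos) {
    f <- setNames(rep(0, 4), displayOrder)
    common <- intersect(rownames(fr), displayOrder)
    f[common] <- fr[common, pos]
    pass <- names(f)[f > thr[names(f)]]
    if (!length(pass)) return("N")
    if (length(pass) == 1L) return(pass)
    top <- max(f[pass])
    winners <- pass[f[pass] >= top - rule@tieTolerance]
    paste(winners[order(match(winners, displayOrder))], collapse = "/")
  }, character(1))
}

#' Consensus table over all spacer lengths
#'
#' Report-style layout: one row per spacer length with at
#' least one collected spacer, one column per spacer position, cells holding
#' the consensus call (\code{N} when no base passes, joined calls for exact
#' ties, empty beyond the row's spacer length).
#'
#' @param hits a \code{GRanges} from \code{\link{scanPairs}}.
#' @param rule a \linkS4class{ConsensusRule}.
#' @param spacerRange integer range of spacer lengths to report (default
#'   1 through the maximum observed; length-0 spacers have no positions).
#' @return A data.frame with columns \code{spacer_len}, \code{n_spacers},
#'   and \code{pos1}, \code{pos2}, ...
#' @export
consensusTable <- function(hits, rule = consensusRule(), spacerRange = NULL) {
  lens <- mcols(hits)$spacerLen
  if (is.null(spacerRange)) {
    if (!length(lens)) stop("argument error: no hits to summarize")
    spacerRange <- 1:max(lens)
  }
  spacerRange <- spacerRange[spacerRange >= 1L]
  maxN <- max(spacerRange)
  rows <- lapply(spacerRange, function(N) {
    sp <- collectSpacers(hits, N)
    calls <- rep("", maxN)
    if (length(sp)) calls[1:N] <- callConsensus(spacerComposition(sp), rule)
    c(list(spacer_len = N, n_spacers = length(sp)),
      setNames(as.list(calls), paste0("pos", seq_len(maxN))))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                        stringsAsFactors = FALSE)))
}

#' Write a consensus table as TSV
#'
#' @param table data.frame from \code{\link{consensusTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConsensusTsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a position composition as long-format TSV
#'
#' Columns: position, base, fraction.
#'
#' @param composition a \linkS4class{PositionComposition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCompositionTsv <- function(composition, path) {
  fr <- composition@fractions
  df <- data.frame(position = rep(as.integer(colnames(fr)),
                                  each = nrow(fr)),
                   base = rep(rownames(fr), ncol(fr)),
                   fraction = signif(as.vector(fr), 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
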