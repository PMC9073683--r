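# Motif-pair scanning: enumerate every co-occurrence of left motif and right
# motif separated by exactly N bases, for all N in the query's spacer range.
# Single motif occurrences come from Biostrings::matchPattern (exact,
# overlapping matches; an N in the subject never matches); the pairing logic
# and per-spacer bookkeeping are implemented here.

.asDNAStringSet <- function(x) {
  if (is(x, "PromoterSet")) x <- promoterSequences(x)
  if (is(x, "DNAString")) x <- Biostrings::DNAStringSet(list(x))
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (!is(x, "DNAStringSet"))
    stop("expected a DNAStringSet, DNAString, PromoterSet or character vector")
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    names(x) <- paste0("seq", seq_along(x))
  x
}

#' Find all occurrences of a motif in a sequence
#'
#' Reports every exact occurrence, including mutually overlapping ones (a
#' poly-A run contains several AAAG starts).  Positions containing the
#' ambiguity code N never match.
#'
#' @param residues a \code{DNAString} or single nucleotide string.
#' @param motif non-empty motif string over A/C/G/T.
#' @return Integer vector of 1-based start positions, ascending.
#' @examples
#' motifPositions("AAAAAG", "AAAG")  # 3
#' @export
motifPositions <- function(residues, motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop("argument error: motif must be a non-empty string")
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif))
    stop("argument error: motif must be over {A,C,G,T}")
  if (is.character(residues)) residues <- Biostrings::DNAString(toupper(residues))
  if (nchar(motif) > length(residues)) return(integer(0))
  BiocGenerics::start(Biostrings::matchPattern(motif, residues, fixed = TRUE))
}

# pair one sequence; returns a data.frame of (leftStart, rightStart, spacerLen)
.pairPositions <- function(lp, rp, wl, minS, maxS) {
  if (length(lp) == 0L || length(rp) == 0L)
    return(data.frame(leftStart = integer(0), rightStart = integer(0),
                      spacerLen = integer(0)))
  lo <- findInterval(lp + wl + minS - 1L, rp) + 1L
  hi <- findInterval(lp + wl + maxS, rp)
  k <- pmax(hi - lo + 1L, 0L)
  keep <- k > 0L
  if (!any(keep))
    return(data.frame(leftStart = integer(0), rightStart = integer(0),
                      spacerLen = integer(0)))
  i <- rep.int(which(keep), k[keep])
  j <- sequence(k[keep]) + rep.int(lo[keep] - 1L, k[keep])
  data.frame(leftStart = lp[i], rightStart = rp[j],
             spacerLen = rp[j] - (lp[i] + wl))
}

#' Scan sequences for motif-pair co-occurrences
#'
#' Enumerates all ordered co-occurrences of \code{leftMotif(query)} followed
#' by \code{rightMotif(query)} with a spacer length inside the query range.
#' A single motif occurrence may participate in several hits, and by default
#' a pair is counted even when another motif occurrence lies inside its
#' spacer (exhaustive counting); \code{exclusive = TRUE} drops hits whose
#' spacer fully contains another occurrence of either motif (sensitivity
#' mode).  Scanning is single-strand on the given residues: promoters are
#' already gene-oriented, so orientation asymmetry between
#' \code{AAAG(N)ACGT} and \code{ACGT(N)AAAG} is preserved.
#' \code{bothStrands = TRUE} additionally scans the reverse complement and
#' maps hit intervals back to the input coordinates with strand \code{-}
#' (spacer sequences are then reported in the scanned-strand frame).
#'
#' @param x sequences to scan: \code{DNAStringSet}, \code{DNAString},
#'   character vector, or \linkS4class{PromoterSet}.
#' @param query a \linkS4class{MotifPairQuery}.
#' @param exclusive drop hits with another motif occurrence fully inside the
#'   spacer (default \code{FALSE}).
#' @param bothStrands also scan the reverse complement (default
#'   \code{FALSE}).
#' @return A \code{GRanges}; each hit spans the left motif start through the
#'   right motif end (1-based), with metadata columns \code{leftStart},
#'   \code{spacerLen}, \code{spacerSeq} and \code{label}.  Hits are ordered
#'   by sequence, then left start, then spacer length.
#' @examples
#' hits <- scanPairs("AAAGTTACGT", motifPairQuery("AAAG", "ACGT"))
#' mcols(hits)$spacerLen  # 2
#' @export
scanPairs <- function(x, query, exclusive = FALSE, bothStrands = FALSE) {
  stopifnot(is(query, "MotifPairQuery"))
  seqs <- .asDNAStringSet(x)
  left <- query@leftMotif; right <- query@rightMotif
  wl <- nchar(left); wr <- nchar(right)
  minS <- query@minSpacer; maxS <- query@maxSpacer

  # batch motif matching over the whole set, then pair per sequence with
  # plain integer arithmetic (cheap even for thousands of promoters)
  scanStrand <- function(ss, strandChar) {
    lpl <- Biostrings::startIndex(
      Biostrings::vmatchPattern(left, ss, fixed = TRUE))
    rpl <- Biostrings::startIndex(
      Biostrings::vmatchPattern(right, ss, fixed = TRUE))
    idx <- integer(0); lst <- integer(0); rst <- integer(0); spl <- integer(0)
    for (i in seq_along(ss)) {
      lp <- lpl[[i]]; rp <- rpl[[i]]
      if (is.null(lp) || is.null(rp)) next
      pp <- .pairPositions(lp, rp, wl, minS, maxS)
      if (exclusive && nrow(pp)) {
        inside <- function(occ, w) {
          # count occurrences of width w fully contained in each spacer
          vapply(seq_len(nrow(pp)), function(h) {
            a <- pp$leftStart[h] + wl; b <- pp$rightStart[h] - 1L
            if (b - a + 1L < w) return(0L)
            sum(occ >= a & occ + w - 1L <= b)
          }, integer(1))
        }
        bad <- inside(lp, wl) + inside(rp, wr) > 0L
        pp <- pp[!bad, , drop = FALSE]
      }
      if (!nrow(pp)) next
      idx <- c(idx, rep.int(i, nrow(pp)))
      lst <- c(lst, pp$leftStart); rst <- c(rst, pp$rightStart)
      spl <- c(spl, pp$spacerLen)
    }
    if (!length(idx)) return(NULL)
    # spacer sequences, one vectorized extractAt over the set
    at <- unname(S4Vectors::split(IRanges(lst + wl, width = spl),
                                  factor(idx, levels = seq_along(ss))))
    sp <- as.character(unlist(Biostrings::extractAt(ss, at),
                              use.names = FALSE))
    if (strandChar == "+") {
      rng <- IRanges(lst, rst + wr - 1L)
    } else {
      # map the pair interval from the reverse-complement frame back
      L <- Biostrings::width(ss)[idx]
      rng <- IRanges(L - (rst + wr - 1L) + 1L, L - lst + 1L)
    }
    gr <- GRanges(names(ss)[idx], rng, strand = strandChar)
    mcols(gr) <- S4Vectors::DataFrame(leftStart = lst, spacerLen = spl,
                                      spacerSeq = sp)
    gr
  }

  out <- list(scanStrand(seqs, "+"))
  if (bothStrands)
    out <- c(out, list(scanStrand(Biostrings::reverseComplement(seqs), "-")))
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) {
    hits <- suppressWarnings(do.call(c, out))
  } else {
    hits <- GRanges()
    mcols(hits) <- S4Vectors::DataFrame(leftStart = integer(0),
                                        spacerLen = integer(0),
                                        spacerSeq = character(0))
  }
  mcols(hits)$label <- rep(query@label, length(hits))
  hits
}

#' Build a per-spacer frequency profile
#'
#' Counts pair hits at every spacer length in the query range across a set
#' of sequences (hits never span two sequences) and records the total
#' scanned bp, the "genomic coverage" used later for normalization.
#'
#' @inheritParams scanPairs
#' @return A \linkS4class{SpacerProfile}.
#' @export
spacerProfile <- function(x, query, exclusive = FALSE, bothStrands = FALSE) {
  seqs <- .asDNAStringSet(x)
  if (length(seqs) == 0L) stop("argument error: empty sequence set")
  hits <- scanPairs(seqs, query, exclusive = exclusive,
                    bothStrands = bothStrands)
  rng <- query@minSpacer:query@maxSpacer
  tab <- table(factor(mcols(hits)$spacerLen, levels = rng))
  counts <- setNames(as.integer(tab), as.character(rng))
  tb <- sum(as.numeric(Biostrings::width(seqs))) * (1L + bothStrands)
  new("SpacerProfile", label = query@label, counts = counts,
      totalBp = tb, nSequences = length(seqs))
}

#' Collect the spacer sequences of hits at one spacer length
#'
#' @param hits a \code{GRanges} from \code{\link{scanPairs}}.
#' @param N spacer length in bp.
#' @return Character vector of spacer sequences (each of length \code{N}),
#'   in scan order; empty when no hit has that spacer length.
#' @export
collectSpacers <- function(hits, N) {
  stopifnot(length(N) == 1L, N >= 0)
  mcols(hits)$spacerSeq[mcols(hits)$spacerLen == N]
}

#' Write pair hits as a BED6-like TSV
#'
#' Columns: seq_id, 0-based start of the left motif, half-open end of the
#' right motif, query label, spacer length, strand.
#'
#' @param hits a \code{GRanges} from \code{\link{scanPairs}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHitsBed <- function(hits, path) {
  df <- data.frame(seq_id = as.character(seqnames(hits)),
                   start = GenomicRanges::start(hits) - 1L,
                   end = GenomicRanges::end(hits),
                   name = mcols(hits)$label,
                   spacer_len = mcols(hits)$spacerLen,
                   strand = as.character(strand(hits)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a spacer profile as TSV
#'
#' Columns: spacer_len, count, normalized_count (count per scanned bp).
#'
#' @param profile a \linkS4class{SpacerProfile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
  df <- data.frame(spacer_len = as.integer(names(profile@counts)),
                   count = as.integer(profile@counts),
                   normalized_count = signif(profile@counts /
                                             profile@totalBp, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
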