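# FASTA / GFF3 input and strand-aware promoter extraction.
# File parsing is delegated to Biostrings and rtracklayer; this module adds
# input normalization (case, U->T), gene-row selection and the promoter
# coordinate arithmetic.

#' Read a genome (or any nucleotide FASTA) into a DNAStringSet
#'
#' Residues are uppercased and RNA-style U is converted to T so that all
#' downstream matching runs over the {A,C,G,T,N} alphabet.
#'
#' @param path path to a FASTA file (wrapped or unwrapped, multi-record).
#' @return A named \code{DNAStringSet}, one element per FASTA record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt", "ACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("format error: empty FASTA file: ", path)
  if (!startsWith(first, ">"))
    stop("format error: sequence data before any FASTA header in ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("format error: no records in ", path)
  chars <- chartr("acgtunU", "ACGTTNT", as.character(raw))
  seqs <- Biostrings::DNAStringSet(toupper(chars))
  names(seqs) <- sub("\\s.*$", "", names(raw))
  if (any(Biostrings::width(seqs) == 0L))
    stop("format error: empty sequence record in ", path)
  seqs
}

#' Read gene annotations from a GFF3 file
#'
#' Keeps rows whose feature type is \code{gene}; all other feature types
#' (mRNA, exon, ...) are ignored.  Coordinates stay 1-based inclusive as in
#' the file.  Gene identifiers are taken from the \code{ID} attribute (or
#' \code{Name} when \code{ID} is absent).
#'
#' @param path path to a GFF3 file.
#' @return A \code{GRanges} with a \code{gene_id} metadata column and strand
#'   \code{+} or \code{-} for every record.
#' @export
readGeneAnnotations <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("format error: no 'gene' features in ", path)
  if (any(as.character(strand(gr)) == "*"))
    stop("format error: gene rows must have strand '+' or '-'")
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids))
    stop("format error: gene rows must carry an ID (or Name) attribute")
  out <- GRanges(seqnames(gr), IRanges(GenomicRanges::start(gr),
                                       GenomicRanges::end(gr)),
                 strand = strand(gr))
  mcols(out)$gene_id <- as.character(ids)
  out
}

#' Reverse-complement a nucleotide string
#'
#' Thin character-vector wrapper around
#' \code{Biostrings::reverseComplement}; accepts the {A,C,G,T,N} alphabet
#' (case-insensitive) and is an involution.
#'
#' @param residues character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("AAAG")  # "CTTT"
#' @export
revComp <- function(residues) {
  residues <- toupper(residues)
  if (any(grepl("[^ACGTN]", residues)))
    stop("alphabet error: sequences must be over {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(residues)))
}

#' Extract 1-kb upstream promoter sequences
#'
#' For a plus-strand gene the promoter is the \code{upstreamLen} bases ending
#' immediately before the annotated gene start; for a minus-strand gene it is
#' the \code{upstreamLen} bases starting immediately after the annotated gene
#' end, reverse-complemented (by default) so every promoter reads 5'->3'
#' relative to its gene.  Promoters are truncated at contig edges and flagged
#' when shorter than requested; a gene flush against the edge yields a
#' zero-length, flagged promoter.
#'
#' @param genome named \code{DNAStringSet} of chromosome/contig sequences.
#' @param genes \code{GRanges} of gene bodies with a \code{gene_id} metadata
#'   column (as from \code{\link{readGeneAnnotations}}).
#' @param upstreamLen promoter length in bp (default 1000).
#' @param reverseMinus reverse-complement minus-strand promoters so all
#'   promoters are gene-oriented (default \code{TRUE}).  Setting this to
#'   \code{FALSE} keeps raw plus-strand residues for sensitivity analysis;
#'   orientation-specific results are only meaningful with the default.
#' @return A \linkS4class{PromoterSet}.
#' @export
extractPromoters <- function(genome, genes, upstreamLen = 1000L,
                             reverseMinus = TRUE) {
  upstreamLen <- as.integer(upstreamLen)
  stopifnot(upstreamLen > 0L)
  chr <- as.character(seqnames(genes))
  miss <- setdiff(unique(chr), names(genome))
  if (length(miss))
    stop("reference error: sequence id(s) not in genome: ",
         paste(miss, collapse = ", "))
  chrLen <- setNames(Biostrings::width(genome), names(genome))[chr]
  plus <- as.character(strand(genes)) == "+"
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  if (any(gs < 1L) || any(ge > chrLen))
    stop("format error: gene coordinates outside chromosome bounds")

  pstart <- ifelse(plus, pmax(1L, gs - upstreamLen), ge + 1L)
  pend <- ifelse(plus, gs - 1L, pmin(chrLen, ge + upstreamLen))
  # a gene flush against the edge gives a zero-width interval
  zero <- pend < pstart
  pstart[zero] <- ifelse(plus[zero], gs[zero], ge[zero])
  pend[zero] <- pstart[zero] - 1L

  regions <- GRanges(chr, IRanges(pstart, pend), strand = strand(genes))
  mcols(regions)$gene_id <- genes$gene_id
  width_ <- pend - pstart + 1L
  mcols(regions)$truncated <- width_ < upstreamLen

  seqs <- vector("list", length(genes))
  for (cn in unique(chr)) {
    sel <- which(chr == cn)
    at <- IRanges(pstart[sel], pend[sel])
    seqs[sel] <- as.list(Biostrings::extractAt(genome[[cn]], at))
  }
  seqs <- Biostrings::DNAStringSet(seqs)
  if (reverseMinus && any(!plus))
    seqs[!plus] <- Biostrings::reverseComplement(seqs[!plus])
  names(seqs) <- genes$gene_id
  new("PromoterSet", sequences = seqs, regions = regions,
      upstreamLen = upstreamLen)
}

#' Write a promoter set to FASTA
#'
#' Headers follow \code{gene_id|seq_id|start-end|strand} with 1-based
#' inclusive genomic coordinates of the source interval.
#'
#' @param promoters a \linkS4class{PromoterSet}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writePromoterFasta <- function(promoters, path) {
  reg <- promoters@regions
  hdr <- paste0(reg$gene_id, "|", as.character(seqnames(reg)), "|",
                GenomicRanges::start(reg), "-", GenomicRanges::end(reg),
                "|", as.character(strand(reg)))
  out <- promoters@sequences
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}
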