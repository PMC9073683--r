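# Seeded synthetic-data generators: i.i.d. genomes at a target GC content
# with non-overlapping gene models, in-place planting of motif pairs at
# chosen spacers, promoter-enrichment construction with a known fold, and
# condition studies with a known likelihood lift.  These define the study
# conditions under which the pipeline is tested without any downloads.

.randomDNA <- function(n, gc = 0.36) {
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Simulate a genome with gene models
#'
#' Chromosomes are i.i.d. nucleotide sequences with
#' P(G) + P(C) = \code{gcContent} split evenly (order-0 background; the
#' A. thaliana genome is about 36\% GC).  Genes are laid out
#' non-overlapping, every gene keeping at least \code{promoterLen} bp clear
#' on both sides so all promoters are full-length by construction.  Strands
#' are assigned at random.  Output is byte-reproducible from the seed.
#'
#' @param chromLengths integer vector of chromosome lengths in bp (one
#'   entry per chromosome).
#' @param nGenes total number of genes, distributed round-robin over
#'   chromosomes.
#' @param gcContent target GC fraction in (0,1), default 0.36.
#' @param promoterLen promoter length the layout must accommodate
#'   (default 1000).
#' @param geneLen gene-body length in bp (default 2000).
#' @param seed integer RNG seed.
#' @return List with \code{genome} (named \code{DNAStringSet}) and
#'   \code{genes} (\code{GRanges} with \code{gene_id}, seqlengths set).
#' @export
simulateGenome <- function(chromLengths, nGenes, gcContent = 0.36,
                           promoterLen = 1000L, geneLen = 2000L, seed = 1L) {
  stopifnot(gcContent > 0, gcContent < 1, nGenes >= 1L)
  set.seed(seed)
  nChrom <- length(chromLengths)
  chromNames <- paste0("chr", seq_len(nChrom))
  perChrom <- tabulate(rep(seq_len(nChrom), length.out = nGenes), nChrom)
  slot_ <- geneLen + promoterLen + 100L
  need <- perChrom * slot_ + promoterLen + 100L
  if (any(chromLengths < need))
    stop("configuration error: chromosome(s) too short for the gene ",
         "layout; need at least ", paste(need, collapse = ", "), " bp")
  genome <- Biostrings::DNAStringSet(vapply(chromLengths, .randomDNA,
                                            character(1), gc = gcContent))
  names(genome) <- chromNames
  gid <- 0L
  grs <- list()
  for (ci in seq_len(nChrom)) {
    g <- perChrom[ci]
    if (g == 0L) next
    starts <- promoterLen + 100L + (seq_len(g) - 1L) * slot_ + 1L
    ids <- sprintf("g%04d", gid + seq_len(g))
    gid <- gid + g
    grs[[ci]] <- GRanges(chromNames[ci],
                         IRanges(starts, width = geneLen),
                         strand = sample(c("+", "-"), g, replace = TRUE),
                         gene_id = ids)
  }
  genes <- suppressWarnings(do.call(c, grs[!vapply(grs, is.null,
                                                   logical(1))]))
  seqlengths(genes) <- setNames(chromLengths, chromNames)[seqlevels(genes)]
  list(genome = genome, genes = genes)
}

#' Plant motif pairs into sequences
#'
#' Writes \code{left + spacer + right} over the background by substitution
#' (sequence lengths and coordinates are preserved) at non-overlapping
#' random positions, optionally restricted to given regions.  The returned
#' truth table records only planted sites; background-generated accidental
#' hits are expected and legitimate, so scans of planted sequences are a
#' superset of the truth.
#'
#' @param sequences named \code{DNAStringSet}.
#' @param query a \linkS4class{MotifPairQuery} supplying the two motifs.
#' @param spacerLen integer vector of spacer lengths, recycled over plants.
#' @param n number of sites to plant.
#' @param seed integer RNG seed.
#' @param regions optional \code{GRanges} restricting placement (e.g.
#'   promoter intervals); default anywhere.  Sites landing in a
#'   minus-strand region are written as the reverse complement of
#'   \code{left + spacer + right}, so that the site reads in the pair
#'   orientation on the region's own strand (a gene-oriented promoter
#'   scan then sees the pair as planted).
#' @param spacerSeqs fixed spacer string(s) recycled over plants (must match
#'   \code{spacerLen}); default random sequence at \code{gcContent}.
#' @param gcContent GC fraction for random spacers (default 0.36).
#' @param minGap minimum bp between planted sites (default 10).
#' @return List with \code{sequences} (modified \code{DNAStringSet}) and
#'   \code{truth} (data.frame: \code{seq_id}, \code{start} of the left
#'   motif, 1-based, \code{spacer_len}, \code{spacer_seq}).
#' @export
plantPairs <- function(sequences, query, spacerLen, n, seed,
                       regions = NULL, spacerSeqs = NULL, gcContent = 0.36,
                       minGap = 10L) {
  stopifnot(is(sequences, "DNAStringSet"), is(query, "MotifPairQuery"))
  if (n == 0L)
    return(list(sequences = sequences,
                truth = data.frame(seq_id = character(0), start = integer(0),
                                   spacer_len = integer(0),
                                   spacer_seq = character(0))))
  set.seed(seed)
  wl <- nchar(query@leftMotif); wr <- nchar(query@rightMotif)
  spacerLen <- rep_len(as.integer(spacerLen), n)
  if (!is.null(spacerSeqs)) {
    spacerSeqs <- rep_len(spacerSeqs, n)
    if (any(nchar(spacerSeqs) != spacerLen))
      stop("configuration error: fixed spacer strings must match spacerLen")
  }
  if (is.null(regions)) {
    regions <- GRanges(names(sequences),
                       IRanges(1L, Biostrings::width(sequences)))
  }
  regChr <- as.character(seqnames(regions))
  if (!all(regChr %in% names(sequences)))
    stop("reference error: region seq_id not in sequences")
  regStart <- GenomicRanges::start(regions)
  regEnd <- GenomicRanges::end(regions)
  regMinus <- as.character(strand(regions)) == "-"

  planted <- data.frame(seq_id = character(0), start = integer(0),
                        end = integer(0))
  out <- data.frame(seq_id = character(n), start = integer(n),
                    spacer_len = spacerLen, spacer_seq = "",
                    strand = "+")
  for (i in seq_len(n)) {
    w <- wl + spacerLen[i] + wr
    usable <- pmax(regEnd - regStart + 1L - w + 1L, 0L)
    if (sum(usable) == 0L)
      stop("configuration error: no region can hold a site of width ", w)
    placed <- FALSE
    for (try_ in seq_len(1000L)) {
      ri <- sample.int(length(regions), 1L, prob = usable)
      if (usable[ri] == 0L) next
      st <- regStart[ri] + sample.int(usable[ri], 1L) - 1L
      en <- st + w - 1L
      sid <- regChr[ri]
      prev <- planted[planted$seq_id == sid, , drop = FALSE]
      if (nrow(prev) == 0L ||
          all(en + minGap < prev$start | st - minGap > prev$end)) {
        planted <- rbind(planted,
                         data.frame(seq_id = sid, start = st, end = en))
        sp <- if (is.null(spacerSeqs)) .randomDNA(spacerLen[i], gcContent)
              else spacerSeqs[i]
        out$seq_id[i] <- sid; out$start[i] <- st; out$spacer_seq[i] <- sp
        out$strand[i] <- if (regMinus[ri]) "-" else "+"
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("configuration error: could not place ", n,
           " non-overlapping sites; reduce n or enlarge regions")
  }
  # apply substitutions per sequence in one replaceAt call
  for (sid in unique(out$seq_id)) {
    sel <- out$seq_id == sid
    at <- IRanges(out$start[sel],
                  width = wl + out$spacer_len[sel] + wr)
    val <- paste0(query@leftMotif, out$spacer_seq[sel], query@rightMotif)
    minus <- out$strand[sel] == "-"
    if (any(minus)) val[minus] <- revComp(val[minus])
    sequences[[sid]] <- Biostrings::replaceAt(sequences[[sid]], at, val)
  }
  list(sequences = sequences, truth = out)
}

#' Simulate a genome with a known promoter enrichment fold
#'
#' Generates an i.i.d. genome, measures its background pair rate, and plants
#' additional pairs into the promoter regions so that the expected
#' promoter/genome per-bp frequency ratio equals \code{fold} (the planted
#' hits inflate the whole-genome rate too, since promoters are part of the
#' genome; the planting count solves for that).  The number of plants is
#' \code{k = b (fold - 1) / (1/P - fold/U)} with \code{b} the measured
#' background per-bp rate, \code{P} the summed promoter bp and \code{U} the
#' genome bp, which requires \code{U/P > fold}.
#'
#' @param fold target promoter/genome enrichment (>= 1).
#' @param genomeLength single-chromosome length in bp (default 2e6).
#' @param nGenes number of genes (default 400).
#' @param query a \linkS4class{MotifPairQuery} (default AAAG(N)ACGT,
#'   spacers 0-30).
#' @param gcContent,promoterLen as in \code{\link{simulateGenome}}.
#' @param seed integer RNG seed.
#' @return List with \code{genome}, \code{genes}, \code{promoters}
#'   (\linkS4class{PromoterSet} extracted after planting), \code{fold},
#'   \code{nPlanted}, \code{backgroundRate}.
#' @export
simulateEnrichmentStudy <- function(fold, genomeLength = 2e6L,
                                    nGenes = 400L,
                                    query = motifPairQuery("AAAG", "ACGT"),
                                    gcContent = 0.36, promoterLen = 1000L,
                                    seed = 1L) {
  stopifnot(fold >= 1)
  sim <- simulateGenome(genomeLength, nGenes, gcContent, promoterLen,
                        seed = seed)
  prof0 <- spacerProfile(sim$genome, query)
  b <- sum(spacerCounts(prof0)) / totalBp(prof0)
  promGR <- promoterRegions(extractPromoters(sim$genome, sim$genes,
                                             promoterLen))
  P <- sum(GenomicRanges::width(promGR))
  U <- sum(as.numeric(Biostrings::width(sim$genome)))
  # Sites are planted into plus-strand promoters only, so the single-strand
  # genome scan and the gene-oriented promoter scan both see every plant.
  # Each planted site also forms incidental pairs with the surrounding
  # i.i.d. background (a background right motif downstream of the planted
  # left motif, a background left motif upstream of the planted right
  # motif, and motif occurrences inside the random spacer), so one plant
  # contributes 1 + gamma expected hits; the effective planted-hit count
  # k * (1 + gamma) solves  b + kEff/P = fold * (b + kEff/U).
  wl <- nchar(query@leftMotif); wr <- nchar(query@rightMotif)
  pAT <- (1 - gcContent) / 2; pGC <- gcContent / 2
  motifProb <- function(m) {
    bases <- strsplit(m, "")[[1]]
    prod(ifelse(bases %in% c("A", "T"), pAT, pGC))
  }
  a <- motifProb(query@leftMotif); cc <- motifProb(query@rightMotif)
  Ns <- query@minSpacer:query@maxSpacer
  gamma <- mean(cc * (pmax(Ns - wr + 1L, 0L) + (query@maxSpacer - Ns)) +
                a * (pmax(Ns - wl + 1L, 0L) + (query@maxSpacer - Ns)))
  denom <- 1 / P - fold / U
  if (denom <= 0)
    stop("configuration error: genome too small relative to promoters ",
         "for the target fold")
  kEff <- b * (fold - 1) / denom
  k <- as.integer(round(kEff / (1 + gamma)))
  genome <- sim$genome
  truth <- NULL
  if (k > 0L) {
    promPlus <- promGR[as.character(strand(promGR)) == "+"]
    if (length(promPlus) == 0L)
      stop("configuration error: no plus-strand promoters to plant into")
    spl <- sample(rep_len(Ns, k))
    pl <- plantPairs(genome, query, spl, k, seed = seed + 1L,
                     regions = promPlus, gcContent = gcContent,
                     minGap = 5L)
    genome <- pl$sequences
    truth <- pl$truth
  }
  list(genome = genome, genes = sim$genes,
       promoters = extractPromoters(genome, sim$genes, promoterLen),
       fold = fold, nPlanted = k, backgroundRate = b, truth = truth)
}

#' Sample a condition gene set with a target likelihood lift
#'
#' Draws a condition set A of the requested size from the universe such that
#' motif-bearing genes (B) are over-represented by the factor \code{lift}:
#' P(gene in A | gene in B) = lift * |A| / U.  With
#' \code{method = "exact"} the count |A n B| is fixed at
#' \code{round(lift * size * |B| / U)} and only the identities are random (a
#' stratified design whose realized lift equals the target up to rounding);
#' \code{method = "bernoulli"} draws every gene independently, so the
#' realized lift fluctuates with binomial noise around the target.
#'
#' @param B character vector of motif-bearing genes.
#' @param universe character vector of all genes.
#' @param size target |A|.
#' @param lift target likelihood of occurrence (>= 0; feasibility
#'   \code{lift * size / U <= 1} and \code{|A n B| <= min(size, |B|)} is
#'   checked).
#' @param method \code{"exact"} (default) or \code{"bernoulli"}.
#' @return Character vector of sampled gene ids.
#' @export
sampleConditionSet <- function(B, universe, size, lift,
                               method = c("exact", "bernoulli")) {
  method <- match.arg(method)
  stopifnot(lift >= 0, size >= 1)
  B <- unique(B); universe <- unique(universe)
  if (!all(B %in% universe))
    stop("argument error: B must be a subset of the universe")
  U <- length(universe); nB <- length(B)
  pIn <- lift * size / U
  if (pIn > 1)
    stop("configuration error: infeasible lift (lift * |A|/U > 1)")
  nonB <- setdiff(universe, B)
  if (method == "exact") {
    nAB <- as.integer(round(pIn * nB))
    if (nAB > min(size, nB) || size - nAB > length(nonB))
      stop("configuration error: infeasible lift for these set sizes")
    c(sample(B, nAB), sample(nonB, size - nAB))
  } else {
    pOut <- (size - pIn * nB) / length(nonB)
    if (pOut < 0 || pOut > 1)
      stop("configuration error: infeasible lift for these set sizes")
    c(B[stats::runif(nB) < pIn], nonB[stats::runif(length(nonB)) < pOut])
  }
}

#' Simulate a condition-association study with a known lift
#'
#' Generates \code{nGenes} i.i.d. promoters, plants one motif pair (random
#' spacer in the query range) into a fraction of them, indexes the realized
#' motif-bearing genes B with the scanner, and samples a condition gene set
#' A of size \code{round(fracCondition * nGenes)} at the target lift
#' \emph{conditional on the realized B} (which includes accidental
#' background pairs -- at 36\% GC roughly 45\% of 1-kb promoters carry one).
#'
#' @param nGenes number of genes/promoters (default 2000).
#' @param fracCondition |A| as a fraction of the universe (default 0.1).
#' @param lift target likelihood of occurrence.
#' @param query a \linkS4class{MotifPairQuery} (default AAAG(N)ACGT 0-30).
#' @param promoterLen promoter length in bp (default 1000).
#' @param gcContent background GC (default 0.36).
#' @param plantFraction fraction of promoters given one planted pair
#'   (default 0.05).
#' @param seed integer RNG seed.
#' @param method sampling method for A, see
#'   \code{\link{sampleConditionSet}}.
#' @param condition,direction labels for the returned
#'   \linkS4class{GeneSet}.
#' @return List with \code{promoters} (named \code{DNAStringSet}),
#'   \code{index} (\linkS4class{MotifGeneIndex}), \code{geneSet} (A),
#'   \code{B}, \code{targetLift} and \code{realizedLift}.
#' @export
simulateConditionStudy <- function(nGenes = 2000L, fracCondition = 0.1,
                                   lift = 1.0,
                                   query = motifPairQuery("AAAG", "ACGT"),
                                   promoterLen = 1000L, gcContent = 0.36,
                                   plantFraction = 0.05, seed = 1L,
                                   method = c("exact", "bernoulli"),
                                   condition = "synthetic condition",
                                   direction = "down") {
  method <- match.arg(method)
  set.seed(seed)
  ids <- sprintf("g%05d", seq_len(nGenes))
  proms <- Biostrings::DNAStringSet(vapply(rep(promoterLen, nGenes),
                                           .randomDNA, character(1),
                                           gc = gcContent))
  names(proms) <- ids
  nPlant <- as.integer(round(plantFraction * nGenes))
  if (nPlant > 0L) {
    tgt <- sample(ids, nPlant)
    rng <- query@minSpacer:query@maxSpacer
    regions <- GRanges(tgt, IRanges(1L, promoterLen))
    pl <- plantPairs(proms, query, sample(rng, nPlant, replace = TRUE),
                     nPlant, seed = seed + 1L, regions = regions,
                     gcContent = gcContent)
    proms <- pl$sequences
  }
  index <- buildMotifGeneIndex(proms, query)
  B <- genesWithSpacer(index)
  size <- as.integer(round(fracCondition * nGenes))
  set.seed(seed + 2L)
  A <- sampleConditionSet(B, ids, size, lift, method)
  realized <- (length(intersect(A, B)) / length(B)) /
    (length(A) / nGenes)
  list(promoters = proms, index = index,
       geneSet = geneSet(condition, direction, A), B = B,
       targetLift = lift, realizedLift = realized)
}

#' Bundled worked-example sequences
#'
#' Returns the small example sequences shipped with the package: \code{mps},
#' a 139-nt minimal promoter sequence used as the basal context in
#' binding-site comparisons; \code{spacer24_example}, an AAAG(N)ACGT
#' co-occurrence with a 24-nt spacer; \code{spacer14_example}, an
#' ACGT(N)AAAG co-occurrence with a 14-nt spacer; and \code{cloning_insert},
#' a BamHI-flanked 50-nt random cloning insert (62 nt with the flanking
#' sites).
#'
#' @return A named \code{DNAStringSet}.
#' @examples
#' width(exampleSequences())
#' @export
exampleSequences <- function() {
  fa <- system.file("extdata", "example_sequences.fa",
                    package = "motifSpacer", mustWork = TRUE)
  readGenome(fa)
}
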