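---
title: "Profiling co-occurring cis-regulatory motif pairs by spacer length"
author: "motifSpacer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling co-occurring cis-regulatory motif pairs by spacer length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(motifSpacer)
  library(Biostrings)
  library(S4Vectors)
})
```

## The question the package answers

Transcription-factor families often act in pairs: in plants, Dof-family
factors bind an `AAAG` core and bZIP-family factors bind an `ACGT` core
(the heart of G-box/OCS-type elements), and their cooperation depends not
only on the presence of both elements in a promoter but on the distance
between them — the *spacer* — and on which element comes first — the
*orientation*. `motifSpacer` quantifies that structure: it enumerates every
co-occurrence `LEFT (N) RIGHT` with spacer length `N` in a configurable
range (default 0–30 bp, about the span over which cooperating factors are
reported to interact on DNA), separately for the two orientations
`AAAG(N)ACGT` and `ACGT(N)AAAG`, in 1-kb upstream promoter regions and
genome-wide.

On top of the raw counts it computes:

* **coverage-normalized profiles** — counts divided by the total scanned
  bp, so promoter sets and whole chromosomes are comparable — and their
  **promoter/genome enrichment ratio** per spacer length;
* **shuffled-tetramer controls** — the 12 ordered combinations of
  {AAGA, AGAA, GAAA} × {CATG, GCAT, GTAC, TCAG}, shuffles of the two true
  motifs that are not themselves known cis-elements;
* **per-position consensus** of the collected spacer sequences, with
  GC-adjusted thresholds;
* a **likelihood-of-occurrence statistic** relating motif-bearing genes to
  condition-regulated gene sets; and
* **K-means clustering** of gene-by-spacer occurrence matrices with
  silhouette-based choice of K.

## Scanning model

The scanner is exact-match and exhaustive.  All occurrences of each motif
are found (including mutually overlapping ones — a run of five adenines
contains two `AAAG` starts; no exclusion rule is applied, because
exhaustive counting is the only convention another group can reproduce
without seeing the code).  A hit is
any ordered pair of a left-motif occurrence at `l` and a right-motif
occurrence at `r` with `r - (l + |left|) = N` inside the spacer range.  One
motif occurrence may take part in several hits; an optional `exclusive`
mode drops hits whose spacer fully contains another occurrence of either
motif, for sensitivity analysis.  The ambiguity code `N` in input sequences
never matches.

Scanning is single-strand on the residues given.  Promoters are extracted
5'→3' relative to their gene (minus-strand promoters are
reverse-complemented), which is the only convention under which the two
orientations are biologically distinct; a `reverseMinus = FALSE` flag
preserves raw plus-strand extraction, and a `bothStrands` scan mode exists,
both off by default.

```{r scan-example}
q <- motifPairQuery("AAAG", "ACGT")
hits <- scanPairs(c(demo = "AAAGTTGGGCTTTCAAAATTGTTAACTCACGT"), q)
mcols(hits)[, c("leftStart", "spacerLen", "spacerSeq")]
```

## Promoter extraction

Promoters are the `upstreamLen` (default 1000) bases upstream of the
annotated gene start (gene-feature coordinates; no UTR/TSS model, matching
the gene-level annotation this analysis is defined on).  Genes near a
contig edge get truncated, flagged promoters; a gene flush against the
edge yields a zero-length flagged record rather than an error.  Promoter
overlap with a neighboring gene body is not masked — no masking rule is
part of the method.  Internally all coordinates are 1-based inclusive
(the native IRanges convention); BED-style exports convert to 0-based
half-open at the file boundary.

## Normalization and enrichment

"Genomic coverage" is the total number of scanned bases of a region set —
the genome length for whole-genome scans, the summed promoter lengths for
promoter scans.  Dividing per-spacer counts by it gives a per-bp frequency;
the per-spacer ratio of promoter frequency over genome frequency is the
enrichment.  Spacer lengths where the genome frequency is zero are flagged
undefined (`NA`) rather than reported as zero or infinity.

For orientation comparisons the 31 per-spacer counts (N = 0…30) of the two
orientations are treated as paired samples: a two-tailed paired *t*-test
(30 df; the critical value at α = 0.05 is 2.04) and, over the spacer window
6–11 where both orientations show common peaks and dips, a Pearson
correlation over exactly those 6 paired values.  No multiple-testing
correction is applied — the tests are few and confirmatory.  Degenerate
inputs (all-equal differences, zero variance) are rejected with an error
instead of returning infinite statistics.

## Consensus calling

For each spacer length, the collected spacer sequences are tallied into
per-position base fractions.  Because the *A. thaliana* background is only
about 36% GC, a G or C well above its ~18% background share is already
informative at a lower absolute fraction than A or T: a position is called
for A or T when its fraction strictly exceeds 0.40 and for G or C when it
strictly exceeds 0.25.  (A defensible alternative reading of
"25% for G/C" is 25% *of* the GC content, i.e. 9% absolute; this package
implements the absolute thresholds, and both are parameters of
`consensusRule()` so the other reading is one argument away.)  When no
base passes, the call is `N`; when several pass, the highest fraction
wins, and exact ties are reported joined (`"G/C"`).  Strict inequality
matters at the boundary: a uniform 0.25/0.25/0.25/0.25 position is `N`.

## Likelihood of occurrence

For a condition gene set *A* (e.g. "downregulated under jasmonic acid")
and the set *B* of genes whose promoter carries at least one pair hit,

\[ L = \frac{|A \cap B| / |B|}{|A| / U} \]

with *U* the gene universe.  *L* = 1 is random co-occurrence; conditions
with *L* strictly above 1.25 are flagged.  "Carries the pair" is read as
at least one hit (a pair already being multiple elements); a `minHits`
parameter allows stricter readings.  The overall statistic over a spacer
range uses the union of per-spacer gene sets — averaging per-spacer *L*
values is ill-defined when some spacers have empty *B*, though that mean
is also emitted (`spacer = "overall_mean"`) for comparison.

## Clustering

Gene-by-spacer hit-count matrices (counts by default; binary presence is
an option) are pruned of all-zero spacer columns — they carry no
information — and clustered with Euclidean K-means (no feature scaling by
default; a `standardize` flag exists).  K is chosen by maximizing the mean
silhouette width over a K range, smallest K on exact ties, and the full
silhouette curve is returned so the automatic pick can be overridden by
judgment — silhouette curves over sparse occurrence data fluctuate, and a
human analyst may prefer a smaller K than the raw maximum; reproducing
that judgment is deliberately not attempted.  `lowSeparation` flags best
silhouettes below 0.25 (a flat curve, as for one undifferentiated blob).
Every stochastic call takes an explicit integer seed and records it.

## The synthetic-data generator

All statistical behavior is validated on generated data with known truth:

* **Genomes** are i.i.d. base sequences at a target GC content (default
  0.36, the *A. thaliana* genome-wide value), with non-overlapping gene
  models leaving at least a promoter length clear on both sides, so every
  promoter is full-length by construction.  An order-0 background is the
  deliberate choice: nothing in the method presumes higher-order
  structure, and it makes planted-signal arithmetic exact.
* **Planting** substitutes `left + spacer + right` over the background at
  non-overlapping positions (lengths and coordinates unchanged).  Sites
  landing in minus-strand regions are written reverse-complemented so the
  gene-oriented promoter reads the pair as planted.  Truth tables record
  planted sites only; accidental background pairs are expected (at 36% GC,
  a 1-kb promoter carries one AAAG(0–30)ACGT pair with probability ≈ 0.45)
  and tests assert superset containment, never equality.
* **Enrichment studies** plant into plus-strand promoters of a simulated
  genome so that the expected promoter/genome frequency ratio equals a
  target fold.  The planting count corrects for two facts: planted hits
  inflate the whole-genome rate too (promoters are part of the genome),
  and each planted site forms incidental pairs with the surrounding
  background (a background right motif downstream of the planted left
  motif, a background left motif upstream of the planted right motif,
  and motif occurrences inside the random spacer), contributing
  `1 + gamma` expected hits per plant with `gamma` computed from the
  i.i.d. base probabilities.  Residual bias is a few percent at high
  folds, from the planted motifs' own base composition shifting the local
  background — well inside the 10% band the recovery tests use.  Default
  problem size: one 2-Mb chromosome, 400 genes, chosen so Poisson noise
  on the measured fold is ~2–3%.
* **Condition studies** sample the condition set *A* conditional on the
  *realized* motif-bearing set *B* (planted ∪ accidental), because
  accidental pairs are so common that conditioning on the planted list
  alone would not produce the requested lift.  The default `"exact"`
  method fixes `|A ∩ B| = round(lift · |A|/U · |B|)` and randomizes only
  identities — a stratified design whose realized lift equals the target
  up to rounding; `"bernoulli"` draws genes independently and is used for
  Monte-Carlo null calibration (1000 resamples of *A* at lift 1 have mean
  L within 0.05 of 1).  Default 2000 genes with |A| = 200.

What passing these tests shows — and does not.  They demonstrate that the
counting, normalization, statistic and clustering machinery is correct and
calibrated under a known-truth background.  Real promoters are not i.i.d.:
they have CpG/compositional heterogeneity, TATA and other positional
elements, repeats, and shared ancestry between paralogous promoters, all
of which can inflate or structure pair counts in ways no synthetic test
certifies.  Conclusions about real genomes rest on the controls built into
the method itself (shuffled-tetramer queries, genome-background
normalization), not on the simulator.

## Running the analysis at full genome scale

`inst/scripts/full_reproduction.R` documents the end-to-end procedure for
the real data: TAIR10 chromosomes and gene models, 1-kb promoters, both
orientations, enrichment, orientation tests, and per-condition likelihoods
from reconstructed expression-atlas gene lists.  It is not run by the test
suite — the inputs require downloads, and the original condition gene
lists depend on atlas experiment selections that are not recoverable, so
the reproduction is documented with tolerances rather than asserted.

## Limitations

* Exact matching only; no PWM or mismatch-tolerant scanning.
* Gene-start promoters; no transcript-level TSS inference, no repeat or
  neighboring-gene masking.
* The likelihood statistic is a ratio of proportions with no significance
  machinery attached; it inherits the arbitrariness of the 1.25 flag
  threshold.
* Silhouette-selected K on sparse count matrices is advisory; inspect the
  returned curve.
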