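---
title: "Methods: simulating and calling LINE-1 insertions with l1peak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calling LINE-1 insertions with l1peak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1peak)
```

## The assay and the model behind the pipeline

LINE-1 (L1) retrotransposons copy themselves into new genomic locations
through an RNA intermediate.  The youngest, human-specific L1 family is
still active, so individual genomes differ in their L1 complement: most
insertions are inherited germline polymorphisms, some arise *de novo* in
early development, and a fraction are somatic and mosaic — present in only
part of the cells of a tissue.

The targeted assay this package models amplifies the junction between an
L1 3' end and the downstream genomic flank with hemi-specific PCR and
sequences the amplicons as 100-nt single-end reads.  A read therefore
consists of an L1-primer-derived 5' block, a genomic flank block, and a
low-quality 3' tail.  After trimming 10 nt from the 5' end and 26 nt from
the 3' end, the remaining 64-mer is pure genomic flank and can be aligned
to the reference.  Aligned reads pile up immediately 3' of each insertion
junction, on the strand of the inserted element; strand-consistent
clusters of read starts ("peaks") mark candidate insertions.

Each peak is compared against two catalogs: **KR** (known-reference)
elements present in the reference assembly, and **KNR** (known
non-reference) elements cataloged as polymorphic.  Peaks matching neither
within a proximity window are candidate **novel** insertions.  Downstream,
novel calls are compared between pooled case and control populations,
genes they disrupt are tested for over-representation, and single
insertions are quantified by droplet digital PCR (ddPCR).

## What the synthetic generator emulates — and what it does not

No raw data for this study design are publicly deposited, so the package
treats the simulator as a first-class, tested module; every pipeline stage
consumes only standard formats (FASTA/FASTQ/BED/SAM/TSV/CSV) and will
accept real data with the same shapes.

The generator emulates:

* a single-contig i.i.d. random genome at a chosen GC content (default
  41%, human-like);
* gene models (two or more exons, TSS, 3'UTR end) and KR/KNR catalog
  entries placed without mutual interference;
* planted novel insertions with per-individual zygosity (1 or 2 alleles)
  and mosaic fraction (1 for germline; a configurable sub-unity fraction
  for somatic events confined to one individual);
* six pools of ten individuals (three case, three control), matching the
  motivating design of sixty pooled brain genomes;
* amplicon reads whose trimmed 64-mer matches the reference flank
  immediately 3' of the junction on the element's strand, with sequential
  start-position jitter, PCR duplicates that re-use an existing start,
  i.i.d. base errors (default 0.2%), uniform off-target noise reads
  (default 5%), and Phred qualities (Q37 baseline, error positions demoted
  to Q20 with probability 0.5, Q15 tail) that exercise the per-base Q30
  filter;
* ddPCR droplet counts under the standard Poisson partition model.

It deliberately does **not** emulate: target-site duplications, 5'
truncations or 5' transductions (a 3'-anchored assay never observes the 5'
end); L1-mediated deletions; repeat-rich reference sequence (the random
genome is almost everywhere uniquely mappable, so the mappability and
multi-hit filters are exercised only by constructed duplications in unit
tests, not stressed genome-wide); pool-level PCR competition beyond a
simple saturation cap; or the eight separate hemi-specific degenerate
primer reactions, which are collapsed into a single read stream per pool.
A green recovery test therefore establishes that the pipeline logic is
correct under the assay's idealized geometry — not that a real repeat-rich
genome would yield the same recall.

### Read-count model

Reads for a given (pool, element) pair are Poisson with mean
`depth_per_insertion * min(sum(allele_count * mosaic_fraction), cap)`
summed over the pool's carriers, with `cap = 3` by default.  The linear
part makes a 10% mosaic insertion receive ~10% of the reads of a germline
heterozygous one — the property that lets low-frequency somatic events
drop below the read-count filters, as they do in the real assay.  The cap
emulates PCR saturation: a reference (KR) element carried homozygously by
all ten individuals of a pool should not receive 20 times the reads of a
singleton heterozygote.  The cap value is a design choice, stated once
here and fixed.

### Start-position jitter and duplicates

Fresh amplicon offsets downstream of the junction are assigned
sequentially (0, 1, 2, ...) and each subsequent read is, with probability
`duplicate_rate`, a PCR duplicate re-using a uniformly chosen existing
offset.  The number of distinct alignment starts of a peak is then
`1 + Binomial(n - 1, 1 - duplicate_rate)` fresh offsets, which is what the
`maxuniq`/`unique_alignments` filters measure.  Offsets are capped at a
50-nt jitter window so all reads of one insertion stay within one 64-nt
clustering window of the junction.

## The caller's metrics and the two filter profiles

Peaks are single-linkage clusters of same-strand read starts within a
64-nt window (the trimmed read length).  Cross-strand reads never merge.
The inferred insertion point is the leftmost read start (plus-strand
peaks) or the rightmost read end (minus-strand peaks).

Two stringency profiles are built in:

* **original**: `mean_mapq >= 30`, `mapscore > 0.5`, and at least one pool
  with `maxcount > 5` reads of which `maxuniq > 1` are unique;
* **new**: `mean_mapq >= 30`, `mappability > 0.5`,
  `mean_matchpct > 0.98`, `total_reads > 5`, `unique_alignments > 1`.

Three definitional choices were genuinely open and are resolved as
follows:

* **mapscore** is defined as the fraction of member reads that align
  uniquely, so `mapscore > 0.5` demands a majority-unique peak — the
  natural counterpart of the `mappability` criterion in the newer metric
  set.
* **mapq thresholding** is applied to the peak mean, with the per-read
  interpretation available by filtering alignments before peak building.
* The **catalog proximity window** (500 bp) mirrors the 500-bp genic
  window; both are configurable.  KR takes precedence over KNR on a double
  match.

**Mappability** is k-mer uniqueness: position *p* scores `1/n` where *n*
is the number of forward-strand occurrences of the k-mer starting at *p*;
a peak's score is the mean over the k-mer start positions it spans.  The
track is computed only at requested positions so that 5-Mb runs stay
cheap; the score of a position is independent of which others are
requested.

**Toy aligner.**  The bundled aligner is a test double: exact match of the
read's first 20 bases (via a trusted-band dictionary search) extended to
the whole read with up to 3 mismatches, both strands.  Multi-best-hit
reads get MAPQ 0; unique hits get `60/(budget+1)` quality bands, so a
perfect unique read scores 60, and 1/2/3 mismatches score 45/30/15.  Real
data should be aligned externally and ingested via `read_sam()`, which
takes `matchpct` from the NM tag (warning and 1.0 when absent).  Only the
threshold semantics — multi-hit means 0, clean unique alignments clear 30
— matter downstream, and those are preserved.

## Population comparison and statistics

Calls are merged across pools when insertion points lie within 100 bp on
the same strand (window configurable; it is not stated by the motivating
analysis).  A call's exclusivity (`cocaine-only`, `control-only`,
`shared`) follows from the populations of the pools it was detected in.
The association between exclusivity and genic context is tested with a
two-sided Fisher's exact test implemented by direct enumeration of the
hypergeometric point probabilities, with a relative tolerance of 1e-9 for
floating-point ties.  The 2x2 arrangement — (cocaine-only, control-only)
by (intragenic, intergenic) — is the only table the motivating analysis's
four printed counts form; the run report labels the arrangement
explicitly because the original choice is not documented.

"Intragenic" means: insertion point inside an exon or intron, or within
500 bp of a transcription start site or of a 3'UTR end.  Nearest-gene ties
are broken lexicographically for determinism.

### Over-representation tests

For a background of `N` genes, a term with `K` members, and an input list
of `n` genes with `x` in the term:

* hypergeometric (DAVID-style): `p = P(X >= x)`,
  `X ~ Hypergeom(N, K, n)`; fold enrichment `(x/n)/(K/N)`;
* binomial (PANTHER-style): `p = P(X >= x)`, `X ~ Binomial(n, K/N)`;
  expected count `nK/N`; fold `x/expected`.

The plain upper tail is the default; the EASE-style conservative variant
(tail at `x - 1`) is available but off, because the motivating text
specifies only "a hypergeometric distribution" and the exact production
adjustment cannot be determined from it.  The Bonferroni multiplier
defaults to the number of terms with at least one observed gene (terms
with zero observed have `p = 1`, so the choice is immaterial for them);
pass `m` to use the full library size.  Whether genes shared by both
populations enter the input list is a list-construction flag, not a
statistical change.

## ddPCR model

A droplet is positive with probability `1 - exp(-c v)` for concentration
`c` (copies/µl) and droplet volume `v` (0.85 nl by default).  From a
positive fraction `p`, `lambda = -ln(1 - p)` copies per droplet, and the
95% interval is a Clopper-Pearson binomial interval on `p` propagated
through the monotone log transform — conservative by construction, which
the coverage test (>= 93/100 replicates) verifies.  Saturated reactions
(all droplets positive) are an error, not an estimate.

The reference channel assays a two-copy diploid locus, so the
target/reference ratio is ~0.5 for a germline heterozygote, ~1.0 for a
homozygote, and proportionally lower for mosaics (20% heterozygous cells
give ~0.1).  The zygosity bands (0.35–0.65 het, 0.85–1.15 hom, < 0.05
absent) are working defaults for a qualitative "about 50%" argument, not
assay constants, and are configurable.  The ratio is scale-free, so
whether concentrations are per µl or per reaction is immaterial.

Group comparisons of normalized expression (target over each reference
assay and over the geometric mean of all references) use a two-sided
Wilcoxon rank-sum test: exact by full enumeration when both groups have at
most 10 observations (midranks for ties), otherwise the normal
approximation with tie and continuity corrections.  Real brain mRNA data
are not available, so this operation is exercised on synthetic groups
only.

## Numerical and degenerate-input choices

* All coordinates are 1-based and closed (the R/Bioconductor convention);
  BED I/O converts at the boundary.  The insertion junction coordinate `s`
  means "between bases `s` and `s+1`"; the called insertion point of a
  plus-strand peak is the first flank base `s+1`.
* All randomness flows from one master seed through fixed per-stage
  offsets, so identical configurations give byte-identical outputs and
  intermediate files.
* Truth recovery matches called insertion points to planted sites within
  100 bp; recall and precision are computed over filtered novel calls.
* Empty inputs return empty results where that is meaningful (no
  alignments -> no peaks) and errors where it is not (empty gene list for
  enrichment, zero droplets, saturated ddPCR, zero-margin 2x2).
* Unknown configuration keys are rejected rather than ignored.

## Known limitations

* The uniform random genome understates multi-mapping; genome-wide filter
  behaviour on repeat-rich references is untested by construction.
* Pooling hides individual genotypes; like the real assay, the pipeline
  reports pool-level detection only and does not deconvolve carriers.
* The toy aligner is ungapped; indel-containing flanks would be dropped
  as unmapped rather than soft-clipped.
* The acceptance-scale world plants germline insertions only (the
  recovery criterion's stated condition); somatic mosaics are exercised in
  smaller targeted tests, where their partial invisibility to the filters
  is expected behaviour, not a defect.
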