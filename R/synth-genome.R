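#' Generate a random toy reference genome
#'
#' Produces a single-contig genome of i.i.d. bases at a requested GC
#' fraction.  This stands in for a real reference assembly so that the
#' downstream pipeline (alignment, peak calling, mappability) can be
#' exercised and tested at desk scale.
#'
#' @param length contig length in bp (>= 10000).
#' @param gc_fraction target GC content, in (0, 1).
#' @param seed integer seed; the same seed always yields the same genome.
#' @param contig_name name of the contig.
#' @return a [Biostrings::DNAStringSet] with one named contig.
#' @examples
#' g <- generate_genome(50000, 0.41, seed = 7)
#' Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)
#' @export
generate_genome <- function(length, gc_fraction = 0.41, seed = 1L,
                            contig_name = "chrS1") {
  assert_scalar_number(length, "length", lower = 1)
  if (length < 10000) stopf("genome length must be >= 10000 bp, got %d", length)
  assert_scalar_number(gc_fraction, "gc_fraction")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stopf("gc_fraction must be strictly inside (0, 1)")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seq, contig_name))
  genome
}

#' Generate gene models and an L1 catalog on a toy genome
#'
#' Places non-overlapping gene models (each with >= 2 exons, a transcription
#' start site and a 3'UTR end) and point entries for known-reference (KR)
#' and known-non-reference (KNR) L1 elements.  KR elements are present in
#' every individual's genome (they are part of the reference); KNR elements
#' are cataloged polymorphic insertions.  Catalog entries are placed outside
#' exons and kept at least `spacing` bp apart so that classification against
#' the catalog is unambiguous in simulations.
#'
#' @param genome a [Biostrings::DNAStringSet] from [generate_genome()].
#' @param n_genes,n_KR,n_KNR feature counts.
#' @param seed integer seed.
#' @param gene_length_range min/max gene span in bp.
#' @param spacing minimum distance between catalog entries (bp).
#' @param margin clearance from contig ends (bp); must leave room for the
#'   read flank plus start-position jitter.
#' @return a list with elements `genes` (data.frame: gene_id, contig, start,
#'   end, strand, tss, utr3_end), `exons` (data.frame: gene_id, contig,
#'   start, end, exon_rank) and `catalog` (data.frame: contig, pos, strand,
#'   class, label), where `pos` is the insertion-junction coordinate of the
#'   element's 3' end.
#' @export
make_annotations <- function(genome, n_genes, n_KR, n_KNR, seed = 1L,
                             gene_length_range = c(2000L, 8000L),
                             spacing = 1100L, margin = 200L) {
  stopifnot(is(genome, "DNAStringSet"))
  contig <- names(genome)[1L]
  L <- Biostrings::width(genome)[1L]
  need <- n_genes * mean(gene_length_range) + (n_KR + n_KNR) * spacing
  if (need > 0.7 * L)
    stopf("genome of %d bp too small for %d genes + %d catalog entries",
          L, n_genes, n_KR + n_KNR)
  set.seed(seed)

  ## non-overlapping gene spans by rejection sampling
  taken <- IRanges::IRanges()
  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    for (try in seq_len(2000L)) {
      w <- sample(gene_length_range[1]:gene_length_range[2], 1L)
      s <- sample.int(L - w - 2L * margin, 1L) + margin
      cand <- IRanges::IRanges(s, s + w - 1L)
      if (length(IRanges::findOverlaps(cand, taken,
                                       maxgap = spacing)) == 0L) break
      cand <- NULL
    }
    if (is.null(cand))
      stopf("could not place gene %d without overlap; genome too crowded", i)
    taken <- c(taken, cand)
    strand <- sample(c("+", "-"), 1L)
    id <- sprintf("GENE%03d", i)
    n_ex <- sample(2:5, 1L)
    ## partition the span into alternating exon/intron blocks
    cuts <- sort(sample.int(w - 2L, 2L * n_ex - 2L)) ; bounds <- c(0L, cuts, w)
    starts <- s + bounds[seq(1L, length(bounds) - 1L, by = 2L)]
    ends   <- s + bounds[seq(2L, length(bounds), by = 2L)] - 1L
    ends[length(ends)] <- s + w - 1L
    keep <- ends >= starts
    genes[[i]] <- data.frame(
      gene_id = id, contig = contig, start = s, end = s + w - 1L,
      strand = strand,
      tss = if (strand == "+") s else s + w - 1L,
      utr3_end = if (strand == "+") s + w - 1L else s,
      stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(
      gene_id = id, contig = contig, start = starts[keep], end = ends[keep],
      exon_rank = seq_len(sum(keep)), stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)

  ## catalog points: outside exons, mutually spaced, clear of contig ends
  exon_ir <- if (is.null(exons)) IRanges::IRanges() else
    IRanges::IRanges(exons$start, exons$end)
  pos <- integer(0)
  n_cat <- n_KR + n_KNR
  for (i in seq_len(n_cat)) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      p <- sample.int(L - 2L * margin, 1L) + margin
      if (length(pos) && min(abs(pos - p)) < spacing) next
      if (length(IRanges::findOverlaps(IRanges::IRanges(p, p),
                                       exon_ir)) > 0L) next
      ok <- TRUE; break
    }
    if (!ok) stopf("could not place catalog entry %d; genome too crowded", i)
    pos <- c(pos, p)
  }
  cls <- c(rep("KR", n_KR), rep("KNR", n_KNR))
  catalog <- data.frame(
    contig = contig, pos = pos,
    strand = sample(c("+", "-"), n_cat, replace = TRUE),
    class = cls,
    label = sprintf("%s_L1_%03d", cls, seq_len(n_cat)),
    stringsAsFactors = FALSE)
  list(genes = genes, exons = exons, catalog = catalog)
}

#' Generate a synthetic term-to-gene map
#'
#' Builds a GMT-style mapping of annotation terms (GO-like) to background
#' genes for exercising the over-representation tests.  Term sizes are drawn
#' uniformly from `size_range` and genes sampled without replacement from
#' the background.
#'
#' @param gene_ids character vector of background gene identifiers.
#' @param n_terms number of terms.
#' @param seed integer seed.
#' @param size_range min/max genes per term.
#' @return a `term_map` list: `terms` (named list term -> character vector)
#'   and `background_size`.
#' @export
make_term_map <- function(gene_ids, n_terms = 20L, seed = 1L,
                          size_range = c(3L, 25L)) {
  if (!length(gene_ids)) stopf("empty background gene set")
  set.seed(seed)
  size_range[2] <- min(size_range[2], length(gene_ids))
  terms <- lapply(seq_len(n_terms), function(i) {
    k <- sample(size_range[1]:size_range[2], 1L)
    sort(sample(gene_ids, k))
  })
  names(terms) <- sprintf("TERM:%04d", seq_len(n_terms))
  structure(list(terms = terms, background = sort(gene_ids),
                 background_size = length(gene_ids)),
            class = "term_map")
}
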