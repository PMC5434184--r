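#' Trim amplicon reads
#'
#' The assay's reads carry an L1-primer block at the 5' end and a
#' low-quality tail at the 3' end; the standard rule removes 10 and 26 nt
#' respectively, so a 100-nt read becomes the 64-nt genomic-flank block
#' (positions 11-74, 1-based).
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] or
#'   [Biostrings::DNAStringSet].
#' @param head_trim,tail_trim bases removed from the 5' and 3' ends.
#' @return the trimmed object (qualities trimmed alongside sequences).
#' @export
trim_read <- function(reads, head_trim = 10L, tail_trim = 26L) {
  w <- Biostrings::width(reads)
  if (any(w <= head_trim + tail_trim))
    stopf("%d read(s) shorter than head_trim + tail_trim + 1 = %d",
          sum(w <= head_trim + tail_trim), head_trim + tail_trim + 1L)
  Biostrings::subseq(reads, start = head_trim + 1L, end = w - tail_trim)
}

#' Per-base quality filter
#'
#' A read passes only if every base has quality >= `min_q` -- a strict
#' per-position rule, not a mean.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet] (trimmed).
#' @param min_q minimum Phred quality required at each position.
#' @return logical vector, one element per read.
#' @export
quality_filter <- function(reads, min_q = 30L) {
  if (!is(reads, "QualityScaledDNAStringSet"))
    stopf("quality_filter needs quality-scaled reads")
  if (!length(reads)) return(logical(0))
  q <- as(Biostrings::quality(reads), "IntegerList")
  as.logical(min(q) >= min_q)
}

#' Toy seed-and-extend aligner
#'
#' Aligns constant-width (trimmed) reads to a genome by exact match of the
#' first `seed_length` bases (on the read's strand) followed by whole-read
#' comparison allowing up to `max_mismatches` substitutions; both strands
#' are searched.  The best-scoring locus (fewest mismatches) is reported.
#' Reads whose best score is shared by several loci get `mapq = 0` and
#' `is_unique = FALSE`; unique hits get
#' `mapq = min(60, 60/(max_mismatches+1) * (max_mismatches - mismatches + 1))`
#' so a perfect unique 64-mer scores 60 and each extra mismatch costs one
#' quality band.  `matchpct` is identities over the aligned length.
#' Unmapped reads are omitted with a message reporting their count.
#'
#' This is deliberately a test double for a production aligner: real
#' pipelines take MAPQ from bowtie2 and ingest its output via [read_sam()].
#' Only the downstream threshold semantics (multi-hit => 0, good unique
#' alignments >= 30) matter.
#'
#' @param reads trimmed reads ([Biostrings::DNAStringSet] or
#'   quality-scaled; qualities are ignored here).
#' @param genome a [Biostrings::DNAStringSet].
#' @param seed_length exact-match seed length.
#' @param max_mismatches mismatch budget over the whole read.
#' @param pool_id optional pool label copied onto every alignment row.
#' @return data.frame with columns read_id, pool (if given), contig, start,
#'   end, strand, mapq, matchpct, n_best_hits, is_unique.
#' @export
align_reads <- function(reads, genome, seed_length = 20L,
                        max_mismatches = 3L, pool_id = NULL) {
  if (!is(genome, "DNAStringSet") || !length(genome) ||
      all(Biostrings::width(genome) == 0L))
    stopf("empty genome")
  dna <- suppressWarnings(Biostrings::DNAStringSet(reads))
  empty <- data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      matchpct = numeric(0), n_best_hits = integer(0),
                      is_unique = logical(0))
  if (!length(dna)) return(empty)
  w <- unique(Biostrings::width(dna))
  if (length(w) != 1L)
    stopf("align_reads requires constant-width (trimmed) reads")
  if (seed_length > w) stopf("seed_length exceeds read length")

  useq <- unique(dna)
  uidx <- match(as.character(dna), as.character(useq))
  urev <- Biostrings::reverseComplement(useq)
  pd_f <- Biostrings::PDict(useq, tb.start = 1L, tb.end = seed_length)
  ## on the reverse complement the read's 5' seed sits at the 3' end
  pd_r <- Biostrings::PDict(urev, tb.start = w - seed_length + 1L,
                            tb.end = w)

  hits <- list()
  for (ci in seq_along(genome)) {
    subject <- genome[[ci]]
    for (str in c("+", "-")) {
      m <- Biostrings::matchPDict(if (str == "+") pd_f else pd_r, subject,
                                  max.mismatch = max_mismatches)
      st <- Biostrings::startIndex(m)
      n_per <- lengths(st)
      if (!sum(n_per)) next
      qi <- rep.int(seq_along(st), n_per)
      starts <- unlist(st, use.names = FALSE)
      win <- Biostrings::DNAStringSet(Biostrings::extractAt(
        subject, IRanges::IRanges(starts, width = w)))
      pat <- if (str == "+") useq else urev
      mm <- rowSums(as.matrix(win) != as.matrix(pat[qi]))
      hits[[length(hits) + 1L]] <- data.frame(
        u = qi, contig = names(genome)[ci], start = starts,
        strand = str, mm = mm, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  if (is.null(hits) || !nrow(hits)) {
    message("align_reads: ", length(dna), " read(s) unmapped (omitted)")
    return(empty)
  }

  ## best-scoring locus per unique sequence, deterministic tie order
  hits <- hits[order(hits$u, hits$mm, hits$contig,
                     hits$strand, hits$start), ]
  best_mm <- tapply(hits$mm, hits$u, min)
  hits$is_best <- hits$mm == best_mm[as.character(hits$u)]
  n_best <- tapply(hits$is_best, hits$u, sum)
  first <- hits[hits$is_best & !duplicated(hits$u), ]

  mapped_u <- first$u
  per_u <- data.frame(
    u = mapped_u, contig = first$contig, start = first$start,
    strand = first$strand, mm = first$mm,
    n_best_hits = as.integer(n_best[as.character(mapped_u)]))

  idx <- match(uidx, per_u$u)
  keep <- !is.na(idx)
  if (any(!keep))
    message("align_reads: ", sum(!keep), " read(s) unmapped (omitted)")
  idx <- idx[keep]
  band <- 60 / (max_mismatches + 1)
  out <- data.frame(
    read_id = names(dna)[keep],
    contig = per_u$contig[idx],
    start = per_u$start[idx],
    end = per_u$start[idx] + w - 1L,
    strand = per_u$strand[idx],
    mapq = ifelse(per_u$n_best_hits[idx] > 1L, 0L,
                  as.integer(round(pmin(60, band *
                    (max_mismatches - per_u$mm[idx] + 1))))),
    matchpct = (w - per_u$mm[idx]) / w,
    n_best_hits = per_u$n_best_hits[idx],
    is_unique = per_u$n_best_hits[idx] == 1L,
    stringsAsFactors = FALSE)
  if (!is.null(pool_id)) out <- cbind(pool = pool_id, out)
  rownames(out) <- NULL
  out
}
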