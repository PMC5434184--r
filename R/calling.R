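#' Cluster aligned reads into candidate-insertion peaks
#'
#' Same-strand reads whose alignment start positions lie within `window`
#' of the running cluster (single-linkage over sorted starts) are merged
#' into one peak.  The default window equals the trimmed read length, so
#' reads jittered downstream of one junction coalesce.  Cross-strand reads
#' never merge: the 3'-anchored assay reads only one flank of an insertion,
#' so one insertion yields reads on a single strand.
#'
#' Per peak the caller records the assay's standard quality metrics:
#' \describe{
#'   \item{total_reads / unique_alignments}{member reads over all pools and
#'     their distinct start positions.}
#'   \item{maxcount / maxuniq}{the maximum per-pool read count and per-pool
#'     distinct-start count.}
#'   \item{mean_mapq, mean_matchpct}{arithmetic means over member reads.}
#'   \item{mapscore}{fraction of member reads that align uniquely.}
#' }
#' The inferred `insertion_point` is the leftmost read start for plus-strand
#' peaks and the rightmost read end for minus-strand peaks (the junction is
#' where the amplicons anchor).
#'
#' @param alignments alignment data.frame from [align_reads()] or
#'   [read_sam()]; a `pool` column assigns reads to pools (absent: one
#'   implicit pool).
#' @param window clustering window in nt.
#' @return a `peaks` data.frame (one row per peak) with per-pool read and
#'   distinct-start count matrices in attributes `pool_counts` and
#'   `pool_unique`.
#' @export
build_peaks <- function(alignments, window = 64L) {
  empty <- data.frame(peak_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), insertion_point = integer(0),
                      total_reads = integer(0), unique_alignments = integer(0),
                      maxcount = integer(0), maxuniq = integer(0),
                      mean_mapq = numeric(0), mapscore = numeric(0),
                      mean_matchpct = numeric(0))
  if (is.null(alignments) || !nrow(alignments)) {
    attr(empty, "pool_counts") <- matrix(0L, 0, 0)
    attr(empty, "pool_unique") <- matrix(0L, 0, 0)
    class(empty) <- c("l1_peaks", "data.frame")
    return(empty)
  }
  a <- as.data.frame(alignments)
  if (is.null(a$pool)) a$pool <- "all"
  a <- a[order(a$contig, a$strand, a$start), ]
  grp <- paste(a$contig, a$strand, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != grp[-nrow(a)])
  gap <- c(0L, diff(a$start))
  a$peak <- cumsum(new_grp | (!new_grp & gap > window))

  pools <- sort(unique(a$pool))
  ids <- unique(a$peak)
  n <- length(ids)
  pc <- matrix(0L, n, length(pools), dimnames = list(NULL, pools))
  pu <- matrix(0L, n, length(pools), dimnames = list(NULL, pools))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- a[a$peak == ids[i], ]
    for (p in unique(m$pool)) {
      mp <- m[m$pool == p, ]
      pc[i, p] <- nrow(mp)
      pu[i, p] <- length(unique(mp$start))
    }
    strand <- m$strand[1]
    rows[[i]] <- data.frame(
      peak_id = sprintf("peak%05d", i),
      contig = m$contig[1],
      start = min(m$start), end = max(m$end), strand = strand,
      insertion_point = if (strand == "+") min(m$start) else max(m$end),
      total_reads = nrow(m),
      unique_alignments = length(unique(m$start)),
      maxcount = max(pc[i, ]), maxuniq = max(pu[i, ]),
      mean_mapq = mean(m$mapq), mapscore = mean(m$is_unique),
      mean_matchpct = mean(m$matchpct),
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  attr(peaks, "pool_counts") <- pc
  attr(peaks, "pool_unique") <- pu
  class(peaks) <- c("l1_peaks", "data.frame")
  peaks
}

## subset peaks keeping the per-pool matrices in sync
subset_peaks <- function(peaks, keep) {
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  pc <- attr(peaks, "pool_counts"); pu <- attr(peaks, "pool_unique")
  ## the matrices can be absent or stale (e.g. after a bare rbind of frames)
  if (!is.null(pc) && nrow(pc) == nrow(peaks))
    attr(out, "pool_counts") <- pc[keep, , drop = FALSE]
  if (!is.null(pu) && nrow(pu) == nrow(peaks))
    attr(out, "pool_unique") <- pu[keep, , drop = FALSE]
  class(out) <- c("l1_peaks", "data.frame")
  out
}

#' k-mer uniqueness (mappability) track
#'
#' Position `p` scores `1 / n` where `n` is the number of occurrences in
#' the genome (forward strand) of the k-mer starting at `p`; a unique
#' 64-mer scores 1, an exactly duplicated one 0.5.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param k k-mer length (default the trimmed read length).
#' @param positions k-mer start positions to score (default: every valid
#'   position on `contig`).  Restricting positions keeps large-genome runs
#'   cheap; the score of a position does not depend on which others are
#'   requested.
#' @param contig contig the positions refer to.
#' @return named numeric vector of scores, one per requested position.
#' @export
compute_mappability <- function(genome, k = 64L, positions = NULL,
                                contig = names(genome)[1L]) {
  stopifnot(is(genome, "DNAStringSet"))
  L <- Biostrings::width(genome)[match(contig, names(genome))]
  if (k > L) stopf("k = %d exceeds contig length %d", k, L)
  if (is.null(positions)) positions <- seq_len(L - k + 1L)
  if (any(positions < 1L | positions > L - k + 1L))
    stopf("positions must allow a full %d-mer", k)
  kmers <- Biostrings::DNAStringSet(Biostrings::extractAt(
    genome[[contig]], IRanges::IRanges(positions, width = k)))
  uk <- unique(kmers)
  pd <- Biostrings::PDict(uk)
  counts <- rowSums(Biostrings::vcountPDict(pd, genome))
  score <- 1 / counts[match(as.character(kmers), as.character(uk))]
  setNames(score, positions)
}

#' @rdname compute_mappability
#' @param peaks a `peaks` data.frame.
#' @details `annotate_mappability()` adds a `mappability` column: the mean
#'   track score over the k-mer start positions within each peak interval
#'   (peaks narrower than `k` are scored at their start position).
#' @export
annotate_mappability <- function(peaks, genome, k = 64L) {
  if (!nrow(peaks)) { peaks$mappability <- numeric(0); return(peaks) }
  pos_list <- lapply(seq_len(nrow(peaks)), function(i) {
    seq(peaks$start[i], max(peaks$start[i], peaks$end[i] - k + 1L))
  })
  all_pos <- unique(unlist(pos_list))
  track <- compute_mappability(genome, k, positions = all_pos,
                               contig = peaks$contig[1])
  peaks$mappability <- vapply(pos_list, function(p)
    mean(track[as.character(p)]), 1.0)
  peaks
}

#' Classify peaks against the L1 catalog
#'
#' A peak whose inferred insertion point lies within `proximity_window` bp
#' of a cataloged known-reference (KR) element 3' end is classified KR; else
#' within the window of a known-non-reference (KNR) entry, KNR; otherwise
#' novel.  KR takes precedence over KNR when both match.
#'
#' @param peaks a `peaks` data.frame.
#' @param catalog catalog data.frame (contig, pos, class, ...); may be NULL.
#' @param proximity_window matching window in bp.
#' @return `peaks` with a `catalog_class` column.
#' @export
classify_peaks <- function(peaks, catalog, proximity_window = 500L) {
  if (!nrow(peaks)) { peaks$catalog_class <- character(0); return(peaks) }
  near <- function(cls) {
    sub <- catalog[catalog$class == cls, , drop = FALSE]
    if (is.null(catalog) || !nrow(sub)) return(rep(FALSE, nrow(peaks)))
    vapply(seq_len(nrow(peaks)), function(i) {
      same <- sub$contig == peaks$contig[i]
      any(same & abs(sub$pos - peaks$insertion_point[i]) <= proximity_window)
    }, TRUE)
  }
  kr <- near("KR"); knr <- near("KNR")
  peaks$catalog_class <- ifelse(kr, "KR", ifelse(knr, "KNR", "novel"))
  peaks
}

#' Peak filter profiles
#'
#' Two named stringency profiles are built in.  The `"original"` profile
#' requires well-aligned reads (`mean_mapq >= 30`, majority-unique
#' `mapscore > 0.5`) and that at least one pool has more than 5 reads of
#' which at least two are unique (`maxcount > 5`, `maxuniq > 1`).  The
#' `"new"` profile requires `mean_mapq >= 30`, `mappability > 0.5`,
#' `mean_matchpct > 0.98`, more than 5 reads across all pools
#' (`total_reads > 5`) and at least two unique alignments
#' (`unique_alignments > 1`).
#'
#' @param name `"original"`, `"new"`, or `"custom"`.
#' @param rules for `"custom"`: data.frame with columns metric, op
#'   (one of `">"`, `">="`, `"<"`, `"<="`), value.
#' @return a `filter_profile` object.
#' @export
filter_profile <- function(name = c("original", "new", "custom"),
                           rules = NULL) {
  name <- match.arg(name)
  rule <- function(metric, op, value)
    data.frame(metric = metric, op = op, value = value,
               stringsAsFactors = FALSE)
  if (name == "original") {
    rules <- rbind(rule("mean_mapq", ">=", 30), rule("mapscore", ">", 0.5),
                   rule("maxcount", ">", 5), rule("maxuniq", ">", 1))
  } else if (name == "new") {
    rules <- rbind(rule("mean_mapq", ">=", 30), rule("mappability", ">", 0.5),
                   rule("mean_matchpct", ">", 0.98),
                   rule("total_reads", ">", 5),
                   rule("unique_alignments", ">", 1))
  } else if (is.null(rules)) {
    stopf("custom profile needs a rules data.frame")
  }
  structure(list(name = name, rules = rules), class = "filter_profile")
}

#' @export
print.filter_profile <- function(x, ...) {
  cat("filter_profile '", x$name, "':\n", sep = "")
  for (i in seq_len(nrow(x$rules)))
    cat(sprintf("  %s %s %s\n", x$rules$metric[i], x$rules$op[i],
                x$rules$value[i]))
  invisible(x)
}

#' Apply a filter profile to peaks
#'
#' A peak is retained iff every comparison in the profile holds.  A profile
#' whose thresholds are all at least as strict retains a subset of the
#' peaks (monotonicity).
#'
#' @param peaks a `peaks` data.frame with all referenced metrics populated.
#' @param profile a [filter_profile()].
#' @return the retained peaks (per-pool matrices subset alongside).
#' @export
apply_filter <- function(peaks, profile) {
  stopifnot(inherits(profile, "filter_profile"))
  missing <- setdiff(profile$rules$metric, names(peaks))
  if (length(missing))
    stopf("profile references metric(s) absent from peaks: %s",
          paste(missing, collapse = ", "))
  if (!nrow(peaks)) return(peaks)
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(profile$rules))) {
    op <- match.fun(profile$rules$op[i])
    keep <- keep & op(peaks[[profile$rules$metric[i]]],
                      profile$rules$value[i])
  }
  subset_peaks(peaks, keep)
}

#' Annotate genic context
#'
#' An insertion is "intragenic" when its insertion point falls within an
#' exon or intron of a gene, or within `promoter_window` bp of a
#' transcription start site or of a 3'UTR end; otherwise "intergenic".
#' Intragenic peaks record the nearest gene (ties broken by smallest
#' gene_id, for determinism).
#'
#' @param peaks a `peaks` data.frame.
#' @param genes gene-model data.frame (gene_id, contig, start, end, strand,
#'   tss, utr3_end); may be NULL or empty (everything intergenic).
#' @param promoter_window bp window around TSS and 3'UTR end.
#' @return `peaks` with `genic_context` and `gene_id` columns.
#' @export
annotate_genic_context <- function(peaks, genes, promoter_window = 500L) {
  n <- nrow(peaks)
  peaks$genic_context <- rep("intergenic", n)
  peaks$gene_id <- rep(NA_character_, n)
  if (!n || is.null(genes) || !nrow(genes)) return(peaks)
  for (i in seq_len(n)) {
    p <- peaks$insertion_point[i]
    g <- genes[genes$contig == peaks$contig[i], , drop = FALSE]
    if (!nrow(g)) next
    inside <- p >= g$start & p <= g$end
    near_tss <- abs(p - g$tss) <= promoter_window
    near_utr <- abs(p - g$utr3_end) <= promoter_window
    hit <- inside | near_tss | near_utr
    if (any(hit)) {
      peaks$genic_context[i] <- "intragenic"
      cand <- g[hit, , drop = FALSE]
      d <- pmax(0L, cand$start - p, p - cand$end)
      best <- which(d == min(d))
      peaks$gene_id[i] <- sort(cand$gene_id[best])[1L]
    }
  }
  peaks
}

#' Write a per-peak report
#'
#' Emits the peak table as BED6+ (name = peak id, score = total reads,
#' extra metric columns) alongside a full tab-delimited report.
#'
#' @param peaks a `peaks` data.frame.
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @export
write_peaks <- function(peaks, prefix) {
  bed <- data.frame(chrom = peaks$contig, chromStart = peaks$start - 1L,
                    chromEnd = peaks$end, name = peaks$peak_id,
                    score = peaks$total_reads, strand = peaks$strand)
  extra <- setdiff(names(peaks),
                   c("contig", "start", "end", "peak_id", "strand"))
  write.table(cbind(bed, peaks[, extra, drop = FALSE]),
              paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_tsv(as.data.frame(peaks), paste0(prefix, ".tsv"))
  invisible(prefix)
}
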