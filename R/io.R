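#' File input/output for pipeline artifacts
#'
#' Thin wrappers around Biostrings and rtracklayer for the standard formats
#' (FASTA, FASTQ, BED6), plain tab-delimited tables for the bespoke ones
#' (truth insertions, pool manifests, exon tables), and a minimal SAM
#' writer/reader for the toy aligner's output (11 mandatory columns plus an
#' NM tag; unaligned-read records are not emitted).
#'
#' @name l1peak-io
NULL

#' @rdname l1peak-io
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output/input file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname l1peak-io
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname l1peak-io
#' @param sim an `l1seq_reads` object from [simulate_l1seq_reads()].
#' @param dir output directory; one `<pool_id>.fastq` per pool.
#' @export
write_pool_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$reads), function(p) {
    f <- file.path(dir, paste0(p, ".fastq"))
    Biostrings::writeQualityScaledXStringSet(sim$reads[[p]], f)
    f
  }, "")
  invisible(paths)
}

#' @rdname l1peak-io
#' @export
read_fastq <- function(path) {
  ## the reader re-wraps the sequences and warns about dropping the mcols
  ## it itself attached; the metadata is not ours and not needed
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  S4Vectors::mcols(x) <- NULL
  x
}

#' @rdname l1peak-io
#' @param catalog catalog data.frame (contig, pos, strand, class, label).
#' @export
write_catalog_bed <- function(catalog, path) {
  gr <- GenomicRanges::GRanges(
    catalog$contig, IRanges::IRanges(catalog$pos, width = 1L),
    strand = catalog$strand,
    name = paste0(catalog$label, "|", catalog$class),
    score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname l1peak-io
#' @export
read_catalog_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  parts <- strsplit(gr$name, "|", fixed = TRUE)
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class = vapply(parts, `[`, "", 2L),
    label = vapply(parts, `[`, "", 1L),
    stringsAsFactors = FALSE)
}

#' @rdname l1peak-io
#' @param annotations list from [make_annotations()].
#' @param prefix file prefix; writes `<prefix>_genes.bed` (gene spans) and
#'   `<prefix>_exons.tsv`.
#' @export
write_gene_models <- function(annotations, prefix) {
  g <- annotations$genes
  gr <- GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start, g$end),
                               strand = g$strand, name = g$gene_id,
                               score = 0L)
  rtracklayer::export(gr, paste0(prefix, "_genes.bed"), format = "BED")
  write.table(annotations$exons, paste0(prefix, "_exons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname l1peak-io
#' @export
read_gene_models <- function(prefix) {
  gr <- rtracklayer::import(paste0(prefix, "_genes.bed"), format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  genes <- data.frame(
    gene_id = gr$name,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = strand,
    tss = ifelse(strand == "+", GenomicRanges::start(gr),
                 GenomicRanges::end(gr)),
    utr3_end = ifelse(strand == "+", GenomicRanges::end(gr),
                      GenomicRanges::start(gr)),
    stringsAsFactors = FALSE)
  exons <- read.delim(paste0(prefix, "_exons.tsv"), stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}

#' @rdname l1peak-io
#' @param x a data.frame (truth table, pool manifest, peak report, ...).
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname l1peak-io
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname l1peak-io
#' @param alignments alignment data.frame from [align_reads()].
#' @param genome the genome the reads were aligned to (for `@SQ` headers).
#' @export
write_sam <- function(alignments, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome)[i],
                       Biostrings::width(genome)[i]), con)
  if (nrow(alignments)) {
    a <- alignments
    flag <- ifelse(a$strand == "-", 16L, 0L)
    w <- a$end - a$start + 1L
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                       a$read_id, flag, a$contig, a$start, a$mapq, w,
                       round((1 - a$matchpct) * w)), con)
  }
  invisible(path)
}

#' @rdname l1peak-io
#' @details `read_sam()` ingests standard single-end SAM records: the
#'   aligned span is taken from POS and the CIGAR-consumed reference
#'   length, percent match from the NM tag over the aligned length (with a
#'   warning and matchpct = 1 when NM is absent), and uniqueness from
#'   MAPQ > 0 unless an NH/X0 hit-count tag is present.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      matchpct = numeric(0), n_best_hits = integer(0),
                      is_unique = logical(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[`, "", i)
  flag <- as.integer(get(2L))
  cigar <- get(6L)
  ## reference-consuming CIGAR length (M/D/N/=/X)
  ref_len <- vapply(strsplit(gsub("([MIDNSHP=X])", "\\1 ", cigar), " "),
    function(ops) {
      n <- as.integer(gsub("[A-Z=]", "", ops))
      sum(n[grepl("[MDN=X]", ops)])
    }, 1L)
  nm <- vapply(f, function(x) {
    hit <- grep("^NM:i:", x, value = TRUE)
    if (length(hit)) as.integer(sub("^NM:i:", "", hit[1])) else NA_integer_
  }, 1L)
  nh <- vapply(f, function(x) {
    hit <- grep("^(NH|X0):i:", x, value = TRUE)
    if (length(hit)) as.integer(sub("^(NH|X0):i:", "", hit[1])) else
      NA_integer_
  }, 1L)
  if (anyNA(nm)) {
    warning("NM tag absent for ", sum(is.na(nm)),
            " record(s); treating matchpct as 1.0")
    nm[is.na(nm)] <- 0L
  }
  start <- as.integer(get(4L))
  mapq <- as.integer(get(5L))
  n_best <- ifelse(!is.na(nh), nh, ifelse(mapq > 0L, 1L, 2L))
  data.frame(
    read_id = get(1L), contig = get(3L), start = start,
    end = start + ref_len - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = mapq, matchpct = 1 - nm / ref_len,
    n_best_hits = n_best, is_unique = n_best == 1L,
    stringsAsFactors = FALSE)
}

#' @rdname l1peak-io
#' @param term_map a `term_map` from [make_term_map()] or [read_gmt()].
#' @export
write_gmt <- function(term_map, path) {
  lines <- vapply(names(term_map$terms), function(t)
    paste(c(t, "na", term_map$terms[[t]]), collapse = "\t"), "")
  writeLines(c(sprintf("#background_size\t%d", term_map$background_size),
               lines), path)
  invisible(path)
}

#' @rdname l1peak-io
#' @param background_size background size when the GMT carries no
#'   `#background_size` header line.
#' @export
read_gmt <- function(path, background_size = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#background_size\t", lines, value = TRUE)
  if (length(hdr)) background_size <- as.integer(strsplit(hdr, "\t")[[1]][2])
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(f, function(x) x[-(1:2)])
  names(terms) <- vapply(f, `[`, "", 1L)
  if (is.null(background_size))
    background_size <- length(unique(unlist(terms)))
  structure(list(terms = terms, background_size = background_size),
            class = "term_map")
}

#' @rdname l1peak-io
#' @param counts a `droplet_counts` object or data.frame of such rows.
#' @export
write_droplet_csv <- function(counts, path) {
  if (inherits(counts, "droplet_counts"))
    counts <- as.data.frame(unclass(counts))
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname l1peak-io
#' @export
read_droplet_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
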