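#' Merge calls across pools and assign population exclusivity
#'
#' Peaks detected in different pools whose insertion points lie within
#' `merge_window` bp on the same strand are treated as the same call.  A
#' call's exclusivity follows from the populations of the pools it was
#' detected in: `cocaine-only`, `control-only`, or `shared`.  When genic
#' context is annotated, intragenic/intergenic counts per exclusivity class
#' are tabulated.
#'
#' @param peaks either a joint `peaks` data.frame from [build_peaks()]
#'   (pool detection taken from its per-pool count matrix), or a named list
#'   of per-pool peak data.frames.
#' @param manifest pool manifest from [make_pools()] (pool_id, population).
#' @param merge_window cross-pool merge window in bp.
#' @param min_reads_detect per-pool read count needed to call a peak
#'   "detected" in that pool (joint-peaks input only).
#' @return a `population_callset` list: `calls` (one row per merged call
#'   with detected pools, exclusivity, genic context) and `counts` (table
#'   of exclusivity x genic context).
#' @export
compare_pools <- function(peaks, manifest, merge_window = 100L,
                          min_reads_detect = 1L) {
  pool_pop <- unique(manifest[, c("pool_id", "population")])
  if (is.data.frame(peaks)) {
    pc <- attr(peaks, "pool_counts")
    if (is.null(pc)) stopf("joint peaks input needs a pool_counts attribute")
    if (!all(colnames(pc) %in% pool_pop$pool_id))
      stopf("pool id(s) absent from manifest: %s",
            paste(setdiff(colnames(pc), pool_pop$pool_id), collapse = ", "))
    flat <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
      det <- colnames(pc)[pc[i, ] >= min_reads_detect]
      if (!length(det)) return(NULL)
      data.frame(contig = peaks$contig[i], strand = peaks$strand[i],
                 insertion_point = peaks$insertion_point[i],
                 genic_context = if (!is.null(peaks$genic_context))
                   peaks$genic_context[i] else NA_character_,
                 gene_id = if (!is.null(peaks$gene_id)) peaks$gene_id[i]
                   else NA_character_,
                 pool_id = det, stringsAsFactors = FALSE)
    }))
  } else {
    if (!all(names(peaks) %in% pool_pop$pool_id))
      stopf("pool id(s) absent from manifest: %s",
            paste(setdiff(names(peaks), pool_pop$pool_id), collapse = ", "))
    flat <- do.call(rbind, lapply(names(peaks), function(p) {
      pk <- peaks[[p]]
      if (is.null(pk) || !nrow(pk)) return(NULL)
      data.frame(contig = pk$contig, strand = pk$strand,
                 insertion_point = pk$insertion_point,
                 genic_context = if (!is.null(pk$genic_context))
                   pk$genic_context else NA_character_,
                 gene_id = if (!is.null(pk$gene_id)) pk$gene_id
                   else NA_character_,
                 pool_id = p, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(flat) || !nrow(flat)) {
    calls <- data.frame(call_id = character(0), contig = character(0),
                        strand = character(0), insertion_point = integer(0),
                        genic_context = character(0), gene_id = character(0),
                        pools = character(0), exclusivity = character(0))
    return(structure(list(calls = calls,
                          counts = table(factor(), factor())),
                     class = "population_callset"))
  }

  ## single-linkage merge of insertion points within the window, per
  ## (contig, strand)
  flat <- flat[order(flat$contig, flat$strand, flat$insertion_point), ]
  grp <- paste(flat$contig, flat$strand, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != grp[-nrow(flat)])
  gap <- c(0L, diff(flat$insertion_point))
  flat$call <- cumsum(new_grp | (!new_grp & gap > merge_window))

  calls <- do.call(rbind, lapply(split(flat, flat$call), function(m) {
    pools <- sort(unique(m$pool_id))
    pops <- unique(pool_pop$population[match(pools, pool_pop$pool_id)])
    excl <- if (length(pops) > 1L) "shared" else paste0(pops, "-only")
    data.frame(contig = m$contig[1], strand = m$strand[1],
               insertion_point = as.integer(round(median(m$insertion_point))),
               genic_context = m$genic_context[1], gene_id = m$gene_id[1],
               pools = paste(pools, collapse = ","), exclusivity = excl,
               stringsAsFactors = FALSE)
  }))
  calls <- cbind(call_id = sprintf("call%05d", seq_len(nrow(calls))), calls,
                 stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  pops <- unique(pool_pop$population)
  lev <- c(paste0(pops, "-only"), "shared")
  counts <- table(
    exclusivity = factor(calls$exclusivity, levels = lev),
    genic_context = factor(calls$genic_context,
                           levels = c("intragenic", "intergenic")))
  structure(list(calls = calls, counts = counts),
            class = "population_callset")
}

#' @export
print.population_callset <- function(x, ...) {
  cat("population_callset:", nrow(x$calls), "merged calls\n")
  print(x$counts)
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value computed by summing, over all tables with the
#' observed margins, the hypergeometric point probabilities no larger than
#' the observed table's (with a relative tolerance of 1e-9 for
#' floating-point ties).  The result is invariant under transposition and
#' row/column swaps.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value in \[0, 1\].
#' @examples
#' # intragenic/intergenic x cocaine-only/control-only novel calls
#' fisher_exact_2x2(matrix(c(90, 115, 82, 108), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stopf("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stopf("cells must be non-negative integers")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  if (r1 + r2 == 0L || c1 == 0L || sum(table[, 2]) == 0L ||
      r1 == 0L || r2 == 0L)
    stopf("a margin of the table is zero")
  x <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(x, r1, r2, c1)
  p_obs <- dhyper(table[1, 1], r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-9)])
  min(1, p)
}

#' Mean novel insertions per sequenced individual
#'
#' @param total_novel total novel calls across all samples.
#' @param n_individuals number of sequenced individuals.
#' @return quotient rounded to 1 decimal place.
#' @examples
#' per_individual_rate(1117, 60)  # 18.6
#' per_individual_rate(853, 60)   # 14.2
#' @export
per_individual_rate <- function(total_novel, n_individuals) {
  assert_scalar_number(total_novel, "total_novel", 0)
  if (!is.numeric(n_individuals) || n_individuals <= 0)
    stopf("n_individuals must be positive")
  round(total_novel / n_individuals, 1L)
}
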