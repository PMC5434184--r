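#' Simulation configuration
#'
#' Bundles the simulation parameters with their default "stated world":
#' 100-nt single-end amplicon reads, ~20 junction-spanning reads per carried
#' insertion per pool, a 20% PCR duplicate rate, 0.2% per-base error rate
#' and a modest off-target noise fraction.
#'
#' @param genome_length,gc_fraction toy genome size and GC content.
#' @param n_genes,n_KR,n_KNR,n_novel feature counts.
#' @param depth_per_insertion expected reads per heterozygous germline
#'   carrier per pool.
#' @param duplicate_rate probability a read is a PCR duplicate (identical
#'   start) of an earlier read of the same insertion, in [0, 1).
#' @param base_error_rate i.i.d. per-base substitution error probability.
#' @param noise_read_fraction fraction of emitted reads that are off-target
#'   (drawn uniformly from the genome).
#' @param read_length read length in nt; must be >= 37 so the 10 + 26 nt
#'   trim rule leaves at least one base.
#' @param signal_cap saturation cap on the per-pool carrier signal (sum of
#'   allele_count x mosaic_fraction), emulating PCR saturation.
#' @param jitter_window number of distinct amplicon start offsets available
#'   downstream of a junction.
#' @param knr_carrier_prob probability that an individual carries a given
#'   cataloged non-reference (KNR) element.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5e6, gc_fraction = 0.41,
                       n_genes = 60L, n_KR = 25L, n_KNR = 15L,
                       n_novel = 40L,
                       depth_per_insertion = 20,
                       duplicate_rate = 0.2,
                       base_error_rate = 0.002,
                       noise_read_fraction = 0.05,
                       read_length = 100L,
                       signal_cap = 3,
                       jitter_window = 50L,
                       knr_carrier_prob = 0.3,
                       seed = 1L) {
  assert_scalar_number(duplicate_rate, "duplicate_rate", 0, 1 - 1e-9)
  assert_scalar_number(base_error_rate, "base_error_rate", 0, 1)
  assert_scalar_number(noise_read_fraction, "noise_read_fraction", 0, 1 - 1e-9)
  if (read_length < 37)
    stopf("read_length must be >= 37 so trimming leaves >= 1 nt")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

L1_PRIMER_SURROGATE <- "GGGAGATATA"  # constant 10-nt 5' block, trimmed away

#' Simulate pooled L1-seq amplicon reads
#'
#' Emits per-pool FASTQ-ready reads for every planted insertion and every
#' catalog element.  Each read is `read_length` nt: a constant 10-nt L1
#' primer surrogate, a genomic-flank block that after the standard 10 + 26
#' trim is the `read_length - 36`-mer immediately 3' of the insertion
#' junction on the inserted element's strand, and a low-quality 26-nt tail.
#' Amplicon start offsets downstream of the junction are assigned
#' sequentially (0, 1, 2, ...) and PCR duplicates re-use an existing offset,
#' so the number of distinct alignment start positions of a peak reflects
#' the duplicate rate.  KR elements are carried homozygously by every
#' individual; KNR carrier sets are randomized per individual.  Per-pool
#' read counts are Poisson with mean
#' `depth_per_insertion * min(sum(allele_count * mosaic_fraction), signal_cap)`
#' over the pool's carriers, so a 10% mosaic insertion receives ~10% of the
#' reads of a germline heterozygous one.  Base errors are i.i.d.; the
#' baseline quality is Q37 with error positions demoted to Q20 with
#' probability 0.5 (exercising the downstream per-base Q30 filter).
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param truth `truth_insertions` from [plant_insertions()] (may be NULL).
#' @param catalog catalog data.frame from [make_annotations()] (may be NULL).
#' @param pools pool manifest from [make_pools()].
#' @param config a [sim_config()].
#' @return an `l1seq_reads` list: `reads` (named list pool_id ->
#'   [Biostrings::QualityScaledDNAStringSet]), `meta` (per-read data.frame
#'   with category insertion/catalog/noise, source id, genomic origin of the
#'   trimmed block) and `counts` (reads per category).
#' @export
simulate_l1seq_reads <- function(genome, truth, catalog, pools, config) {
  stopifnot(is(genome, "DNAStringSet"), inherits(config, "sim_config"))
  contig <- names(genome)[1L]
  L <- Biostrings::width(genome)[1L]
  flank <- config$read_length - 36L
  max_off <- config$jitter_window - 1L
  set.seed(derive_seed(config$seed, 3L))

  ## one carrier table covering planted insertions and catalog elements
  src <- list()
  if (!is.null(truth) && nrow(truth)) {
    src[[1]] <- data.frame(source_id = truth$insertion_id,
                           category = "insertion",
                           site = truth$site, strand = truth$strand,
                           individual_id = truth$individual_id,
                           allele_count = truth$allele_count,
                           mosaic_fraction = truth$mosaic_fraction,
                           stringsAsFactors = FALSE)
  }
  if (!is.null(catalog) && nrow(catalog)) {
    kr <- catalog[catalog$class == "KR", , drop = FALSE]
    if (nrow(kr)) {
      src[[length(src) + 1L]] <- do.call(rbind, lapply(seq_len(nrow(kr)),
        function(i) data.frame(source_id = kr$label[i], category = "catalog",
                               site = kr$pos[i], strand = kr$strand[i],
                               individual_id = pools$individual_id,
                               allele_count = 2L, mosaic_fraction = 1.0,
                               stringsAsFactors = FALSE)))
    }
    knr <- catalog[catalog$class == "KNR", , drop = FALSE]
    if (nrow(knr)) {
      src[[length(src) + 1L]] <- do.call(rbind, lapply(seq_len(nrow(knr)),
        function(i) {
          carrier <- runif(nrow(pools)) < config$knr_carrier_prob
          if (!any(carrier)) return(NULL)
          data.frame(source_id = knr$label[i], category = "catalog",
                     site = knr$pos[i], strand = knr$strand[i],
                     individual_id = pools$individual_id[carrier],
                     allele_count = 1L + rbinom(sum(carrier), 1L, 0.1),
                     mosaic_fraction = 1.0, stringsAsFactors = FALSE)
        }))
    }
  }
  carriers <- if (length(src)) do.call(rbind, src) else
    data.frame(source_id = character(0), category = character(0),
               site = integer(0), strand = character(0),
               individual_id = character(0), allele_count = integer(0),
               mosaic_fraction = numeric(0))

  bad <- carriers$site - (flank + max_off) < 1L |
         carriers$site + flank + max_off > L
  if (any(bad))
    stopf("insertion site(s) %s too close to a contig edge for a full flank",
          paste(unique(carriers$source_id[bad]), collapse = ", "))

  carriers$pool_id <- pools$pool_id[match(carriers$individual_id,
                                          pools$individual_id)]
  if (anyNA(carriers$pool_id))
    stopf("carrier individual absent from pool manifest")

  ## expected reads per (pool, source): saturating carrier signal
  if (nrow(carriers)) {
    carriers$dose <- carriers$allele_count * carriers$mosaic_fraction
    sig <- aggregate(dose ~ pool_id + source_id + category + site + strand,
                     data = carriers, FUN = sum)
    names(sig)[names(sig) == "dose"] <- "signal"
  } else {
    sig <- data.frame(pool_id = character(0), source_id = character(0),
                      category = character(0), site = integer(0),
                      strand = character(0), signal = numeric(0))
  }
  sig$lambda <- config$depth_per_insertion * pmin(sig$signal, config$signal_cap)
  sig$n_reads <- rpois(nrow(sig), sig$lambda)
  sig <- sig[sig$n_reads > 0L, , drop = FALSE]

  ## expand to individual reads with duplicate-aware offsets
  meta <- vector("list", nrow(sig))
  for (i in seq_len(nrow(sig))) {
    n <- sig$n_reads[i]
    offs <- integer(n)
    n_fresh <- 1L
    for (j in seq_len(n)[-1]) {
      if (runif(1) < config$duplicate_rate) {
        offs[j] <- offs[sample.int(j - 1L, 1L)]
      } else {
        offs[j] <- n_fresh %% config$jitter_window
        n_fresh <- n_fresh + 1L
      }
    }
    meta[[i]] <- data.frame(
      pool_id = sig$pool_id[i], category = sig$category[i],
      source_id = sig$source_id[i], site = sig$site[i],
      strand = sig$strand[i], offset = offs, stringsAsFactors = FALSE)
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(pool_id = character(0), category = character(0),
               source_id = character(0), site = integer(0),
               strand = character(0), offset = integer(0))

  ## off-target noise reads, uniform over the genome
  n_signal <- nrow(meta)
  f <- config$noise_read_fraction
  n_noise <- round(f / (1 - f) * n_signal)
  if (n_noise > 0L) {
    npool <- sample(unique(pools$pool_id), n_noise, replace = TRUE)
    nstrand <- sample(c("+", "-"), n_noise, replace = TRUE)
    ## pick a pseudo-site such that the flank block stays inside the contig
    nsite <- sample.int(L - 2L * (flank + max_off), n_noise) + flank + max_off
    meta <- rbind(meta, data.frame(
      pool_id = npool, category = "noise",
      source_id = sprintf("NOISE%05d", seq_len(n_noise)),
      site = nsite, strand = nstrand, offset = 0L,
      stringsAsFactors = FALSE))
  }
  if (!nrow(meta))
    return(structure(list(reads = list(), meta = meta,
                          counts = c(insertion = 0L, catalog = 0L, noise = 0L)),
                     class = "l1seq_reads"))

  ## genomic block of the trimmed portion
  plus <- meta$strand == "+"
  meta$contig <- contig
  meta$true_start <- ifelse(plus, meta$site + 1L + meta$offset,
                            meta$site - flank + 1L - meta$offset)
  blocks <- Biostrings::extractAt(
    genome[[contig]],
    IRanges::IRanges(meta$true_start, width = flank))
  blocks <- Biostrings::DNAStringSet(blocks)
  if (any(!plus))
    blocks[!plus] <- Biostrings::reverseComplement(blocks[!plus])

  ## assemble full reads: primer + flank block + random tail
  bases <- c("A", "C", "G", "T")
  tails <- matrix(sample(bases, 26L * nrow(meta), replace = TRUE),
                  nrow = nrow(meta))
  tails <- apply(tails, 1L, paste, collapse = "")
  seqs <- paste0(L1_PRIMER_SURROGATE, as.character(blocks), tails)

  rl <- config$read_length
  base_qual <- paste0(strrep(rawToChar(as.raw(37L + 33L)), rl - 26L),
                      strrep(rawToChar(as.raw(15L + 33L)), 26L))
  quals <- rep(base_qual, nrow(meta))

  ## i.i.d. substitution errors; error positions demoted to Q20 w.p. 0.5
  if (config$base_error_rate > 0) {
    n_err <- rbinom(nrow(meta), rl, config$base_error_rate)
    for (i in which(n_err > 0L)) {
      at <- sample.int(rl, n_err[i])
      s <- strsplit(seqs[i], "")[[1]]
      s[at] <- vapply(s[at], function(b) sample(setdiff(bases, b), 1L), "")
      seqs[i] <- paste(s, collapse = "")
      demote <- at[runif(length(at)) < 0.5]
      if (length(demote)) {
        q <- strsplit(quals[i], "")[[1]]
        q[demote] <- rawToChar(as.raw(20L + 33L))
        quals[i] <- paste(q, collapse = "")
      }
    }
  }

  meta$read_id <- sprintf("%s:%s:%05d", meta$pool_id, meta$source_id,
                          seq_len(nrow(meta)))
  reads <- split(seq_len(nrow(meta)), meta$pool_id)
  reads <- lapply(reads, function(idx) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs[idx], meta$read_id[idx])),
      Biostrings::PhredQuality(quals[idx]))
    x
  })
  counts <- c(insertion = sum(meta$category == "insertion"),
              catalog = sum(meta$category == "catalog"),
              noise = sum(meta$category == "noise"))
  structure(list(reads = reads, meta = meta, counts = counts),
            class = "l1seq_reads")
}

#' @export
print.l1seq_reads <- function(x, ...) {
  cat("l1seq_reads:", sum(x$counts), "reads in", length(x$reads), "pools (",
      paste(names(x$counts), x$counts, collapse = ", "), ")\n")
  invisible(x)
}
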