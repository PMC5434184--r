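#' Default pipeline configuration
#'
#' The default configuration is the package's reference "stated world": a
#' 5 Mb toy genome at human-like 41% GC, 6 pools of 10 individuals (3 case
#' "cocaine", 3 "control"), 25 known-reference and 15 known-non-reference
#' catalog elements, 40 germline novel insertions, ~20 reads per carried
#' insertion per pool, 20% PCR duplicates, 0.2% base errors and 5%
#' off-target reads, analysed with the "new" filter profile.
#'
#' @param ... named overrides of top-level sections, e.g.
#'   `default_config(genome = list(length = 1e6))` (partial lists are merged
#'   over the defaults).
#' @return a validated `l1peak_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    profile = "new",
    genome = list(length = 5e6, gc_fraction = 0.41),
    ## genes (incl. introns) cover ~30% of the toy genome, so a realistic
    ## fraction of novel insertions lands intragenic
    annotations = list(n_genes = 60L, n_KR = 25L, n_KNR = 15L,
                       gene_length_range = c(10000L, 40000L)),
    pools = list(n_pools_per_pop = 3L, n_per_pool = 10L),
    insertions = list(n_novel = 40L, germline_fraction = 1.0,
                      mosaic_fraction_range = c(0.05, 0.5)),
    reads = list(depth_per_insertion = 20, duplicate_rate = 0.2,
                 base_error_rate = 0.002, noise_read_fraction = 0.05,
                 read_length = 100L, signal_cap = 3, jitter_window = 50L,
                 knr_carrier_prob = 0.3),
    align = list(seed_length = 20L, max_mismatches = 3L, min_q = 30L),
    calling = list(window = 64L, proximity_window = 500L,
                   promoter_window = 500L),
    compare = list(merge_window = 100L, truth_match_window = 100L),
    enrich = list(test = "hypergeometric", n_terms = 20L,
                  include_overlap = TRUE))
  over <- list(...)
  validate_config(cfg, over, where = "config")
  for (k in names(over)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(over[[k]]))
      modifyList(cfg[[k]], over[[k]]) else over[[k]]
  }
  class(cfg) <- c("l1peak_config", "list")
  cfg
}

validate_config <- function(template, value, where) {
  unknown <- setdiff(names(value), names(template))
  if (length(unknown))
    stopf("unknown %s key(s): %s", where, paste(unknown, collapse = ", "))
  for (k in names(value))
    if (is.list(template[[k]]) && is.list(value[[k]]))
      validate_config(template[[k]], value[[k]], paste(where, k, sep = "$"))
  invisible(TRUE)
}

#' @rdname default_config
#' @param config an `l1peak_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate -> trim/quality-filter/align -> peak call ->
#' classify/annotate -> filter -> population compare -> enrichment on a
#' synthetic truth set, and reports recovery statistics against the truth.
#' All randomness derives from `config$seed`; two runs with the same
#' configuration produce identical reports (and byte-identical intermediate
#' files when `outdir` is set).
#'
#' When `outdir` is given, every intermediate is written in its standard
#' format (FASTA genome, BED catalogs and gene spans, tab-delimited truth
#' and manifest, per-pool FASTQ, per-pool SAM, BED6+/TSV peaks, JSON
#' report) and reads/alignments are round-tripped through those files, so
#' the run also exercises the I/O paths.
#'
#' @param config an `l1peak_config` from [default_config()].
#' @param outdir output directory, or NULL to run in memory.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list: `report` (the JSON-serializable run report),
#'   plus the intermediate objects `genome`, `annotations`, `manifest`,
#'   `truth`, `peaks`, `filtered`, `callset`, `enrichment`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "l1peak_config"))
  say <- function(...) if (!quiet) message("[l1peak] ", ...)
  io <- !is.null(outdir)
  if (io) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  ## --- simulate ---------------------------------------------------------
  say("simulating genome and annotations")
  genome <- generate_genome(config$genome$length, config$genome$gc_fraction,
                            seed = derive_seed(config$seed, 1L))
  ann <- make_annotations(genome, config$annotations$n_genes,
                          config$annotations$n_KR, config$annotations$n_KNR,
                          seed = derive_seed(config$seed, 2L),
                          gene_length_range =
                            config$annotations$gene_length_range)
  manifest <- make_pools(config$pools$n_pools_per_pop,
                         config$pools$n_per_pool)
  truth <- plant_insertions(
    genome, manifest, config$insertions$n_novel,
    germline_fraction = config$insertions$germline_fraction,
    mosaic_fraction_range = config$insertions$mosaic_fraction_range,
    seed = derive_seed(config$seed, 4L), annotations = ann)
  scfg <- sim_config(
    genome_length = config$genome$length,
    gc_fraction = config$genome$gc_fraction,
    n_genes = config$annotations$n_genes, n_KR = config$annotations$n_KR,
    n_KNR = config$annotations$n_KNR, n_novel = config$insertions$n_novel,
    depth_per_insertion = config$reads$depth_per_insertion,
    duplicate_rate = config$reads$duplicate_rate,
    base_error_rate = config$reads$base_error_rate,
    noise_read_fraction = config$reads$noise_read_fraction,
    read_length = config$reads$read_length,
    signal_cap = config$reads$signal_cap,
    jitter_window = config$reads$jitter_window,
    knr_carrier_prob = config$reads$knr_carrier_prob,
    seed = config$seed)
  say("simulating reads")
  sim <- simulate_l1seq_reads(genome, truth, ann$catalog, manifest, scfg)

  if (io) {
    write_genome_fasta(genome, file.path(outdir, "genome.fa"))
    write_catalog_bed(ann$catalog, file.path(outdir, "catalog.bed"))
    write_gene_models(ann, file.path(outdir, "annot"))
    write_tsv(manifest, file.path(outdir, "pools.tsv"))
    write_tsv(as.data.frame(truth), file.path(outdir, "truth.tsv"))
    write_pool_fastq(sim, file.path(outdir, "fastq"))
  }

  ## --- trim / filter / align -------------------------------------------
  say("aligning ", sum(sim$counts), " reads")
  aln <- list()
  for (p in names(sim$reads)) {
    reads <- if (io)
      read_fastq(file.path(outdir, "fastq", paste0(p, ".fastq")))
    else sim$reads[[p]]
    trimmed <- trim_read(reads)
    pass <- quality_filter(trimmed, min_q = config$align$min_q)
    a <- align_reads(trimmed[pass], genome,
                     seed_length = config$align$seed_length,
                     max_mismatches = config$align$max_mismatches,
                     pool_id = p)
    if (io) {
      sam <- file.path(outdir, paste0(p, ".sam"))
      write_sam(a, genome, sam)
      a2 <- read_sam(sam)
      a2 <- cbind(pool = p, a2, stringsAsFactors = FALSE)
      a <- a2
    }
    aln[[p]] <- a
  }
  alignments <- do.call(rbind, aln)

  ## --- call / classify / filter ----------------------------------------
  say("calling peaks")
  peaks <- build_peaks(alignments, window = config$calling$window)
  peaks <- annotate_mappability(peaks, genome,
                                k = config$reads$read_length - 36L)
  peaks <- classify_peaks(peaks, ann$catalog,
                          proximity_window = config$calling$proximity_window)
  peaks <- annotate_genic_context(peaks, ann$genes,
                                  promoter_window =
                                    config$calling$promoter_window)
  profile <- filter_profile(config$profile)
  filtered <- apply_filter(peaks, profile)
  novel <- subset_peaks(filtered, filtered$catalog_class == "novel")
  if (io) write_peaks(filtered, file.path(outdir, "peaks"))

  ## --- truth recovery ---------------------------------------------------
  tw <- config$compare$truth_match_window
  sites <- unique(truth[, c("insertion_id", "contig", "site")])
  hit <- vapply(seq_len(nrow(sites)), function(i)
    any(novel$contig == sites$contig[i] &
          abs(novel$insertion_point - sites$site[i]) <= tw), TRUE)
  called_true <- vapply(seq_len(nrow(novel)), function(i)
    any(sites$contig == novel$contig[i] &
          abs(sites$site - novel$insertion_point[i]) <= tw), TRUE)
  recall <- if (nrow(sites)) mean(hit) else NA_real_
  precision <- if (nrow(novel)) mean(called_true) else NA_real_

  ## --- population comparison -------------------------------------------
  say("comparing populations")
  callset <- compare_pools(novel, manifest,
                           merge_window = config$compare$merge_window)
  cts <- callset$counts
  fisher_p <- if (all(dim(cts) == c(3L, 2L)) &&
                  all(rowSums(cts[1:2, ]) > 0) && all(colSums(cts[1:2, ]) > 0))
    fisher_exact_2x2(cts[1:2, ]) else NA_real_

  ## --- enrichment -------------------------------------------------------
  tm <- make_term_map(ann$genes$gene_id, n_terms = config$enrich$n_terms,
                      seed = derive_seed(config$seed, 5L))
  keep_excl <- c("cocaine-only", if (config$enrich$include_overlap) "shared")
  coc_genes <- unique(stats::na.omit(
    callset$calls$gene_id[callset$calls$exclusivity %in% keep_excl &
                            callset$calls$genic_context == "intragenic"]))
  enrichment <- if (length(coc_genes)) {
    if (config$enrich$test == "binomial")
      binomial_enrichment(coc_genes, tm)
    else hypergeometric_enrichment(coc_genes, tm)
  } else NULL

  n_ind <- nrow(manifest)
  excl_counts <- as.list(setNames(as.integer(rowSums(cts)), rownames(cts)))
  report <- list(
    seed = config$seed, profile = config$profile,
    reads = as.list(sim$counts),
    n_peaks = nrow(peaks),
    class_partition = as.list(table(factor(peaks$catalog_class,
                                           c("KR", "KNR", "novel")))),
    n_filtered = nrow(filtered),
    n_novel_filtered = nrow(novel),
    recall = recall, precision = precision,
    exclusivity = excl_counts,
    exclusivity_by_context = as.data.frame.matrix(cts),
    fisher_p = fisher_p,
    fisher_table = "cocaine-only/control-only x intragenic/intergenic",
    novel_per_individual = per_individual_rate(nrow(callset$calls), n_ind),
    enrichment_top = if (!is.null(enrichment))
      head(as.data.frame(enrichment), 5L) else NULL)
  if (io)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  say(sprintf("done: recall %.3f, precision %.3f over %d truth insertions",
              recall, precision, nrow(sites)))
  invisible(list(report = report, genome = genome, annotations = ann,
                 manifest = manifest, truth = truth, peaks = peaks,
                 filtered = filtered, novel = novel, callset = callset,
                 enrichment = enrichment))
}
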