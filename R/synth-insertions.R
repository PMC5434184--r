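#' Build a pool manifest
#'
#' The assay sequences pooled libraries: several individuals per pool and
#' several pools per population.  The default manifest mirrors a design of
#' 3 case ("cocaine") and 3 control pools of 10 individuals each.
#'
#' @param n_pools_per_pop pools per population.
#' @param n_per_pool individuals per pool.
#' @param populations population labels (cases first).
#' @return data.frame with columns pool_id, population, individual_id;
#'   individual ids are unique across pools.
#' @export
make_pools <- function(n_pools_per_pop = 3L, n_per_pool = 10L,
                       populations = c("cocaine", "control")) {
  stopifnot(length(populations) == 2L, n_pools_per_pop >= 1, n_per_pool >= 1)
  pools <- expand.grid(p = seq_len(n_pools_per_pop), pop = populations,
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(pools)), function(i) {
    data.frame(
      pool_id = sprintf("pool%d", i),
      population = pools$pop[i],
      individual_id = sprintf("ind%03d", (i - 1L) * n_per_pool +
                                seq_len(n_per_pool)),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plant novel L1 insertions with per-individual zygosity and mosaicism
#'
#' Each planted insertion is a single junction coordinate `site` (the
#' insertion sits between reference bases `site` and `site + 1`) with a
#' strand for the inserted element and a carrier table: which individuals
#' carry it, on how many alleles (1 = heterozygous, 2 = homozygous) and in
#' what fraction of cells (`mosaic_fraction`; 1 for germline insertions,
#' < 1 for somatic mosaics confined to a fraction of neurons).
#'
#' Sites are kept `min_distance` bp away from catalog entries and from each
#' other so that planted insertions are unambiguously "novel" to the
#' classifier, and clear of contig ends so full flank reads exist.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param pools pool manifest from [make_pools()].
#' @param n_novel number of insertions to plant.
#' @param germline_fraction fraction of insertions that are germline
#'   (mosaic_fraction = 1); the rest are somatic mosaics in one individual.
#' @param mosaic_fraction_range range of cell fractions for somatic events.
#' @param seed integer seed.
#' @param annotations optional list from [make_annotations()]; catalog
#'   positions are avoided.
#' @param max_carriers germline carrier counts are drawn from
#'   `1:max_carriers` with probability proportional to 1/k (rare variants
#'   are common, common variants rare).
#' @param hom_prob probability a germline carrier is homozygous.
#' @param min_distance minimum distance to catalog entries and other
#'   insertions (bp).
#' @param margin clearance from contig ends (bp).
#' @return data.frame of class `truth_insertions`: one row per
#'   (insertion, carrier) with columns insertion_id, contig, site, strand,
#'   individual_id, allele_count, mosaic_fraction.
#' @export
plant_insertions <- function(genome, pools, n_novel,
                             germline_fraction = 1.0,
                             mosaic_fraction_range = c(0.05, 0.5),
                             seed = 1L, annotations = NULL,
                             max_carriers = 8L, hom_prob = 0.1,
                             min_distance = 1100L, margin = 200L) {
  stopifnot(is(genome, "DNAStringSet"), nrow(pools) > 0)
  assert_scalar_number(germline_fraction, "germline_fraction", 0, 1)
  contig <- names(genome)[1L]
  L <- Biostrings::width(genome)[1L]
  avoid <- if (!is.null(annotations)) annotations$catalog$pos else integer(0)
  if (n_novel * min_distance > 0.8 * (L - 2 * margin))
    stopf("n_novel = %d exceeds available genome space", n_novel)
  set.seed(seed)

  sites <- integer(0)
  for (i in seq_len(n_novel)) {
    ok <- FALSE
    for (try in seq_len(5000L)) {
      s <- sample.int(L - 2L * margin, 1L) + margin
      if (length(c(sites, avoid)) &&
          min(abs(c(sites, avoid) - s)) < min_distance) next
      ok <- TRUE; break
    }
    if (!ok) stopf("could not place insertion %d; genome too crowded", i)
    sites <- c(sites, s)
  }

  inds <- pools$individual_id
  is_germline <- runif(n_novel) < germline_fraction
  rows <- lapply(seq_len(n_novel), function(i) {
    id <- sprintf("NOV%03d", i)
    strand <- sample(c("+", "-"), 1L)
    if (is_germline[i]) {
      k <- sample.int(max_carriers, 1L, prob = 1 / seq_len(max_carriers))
      carriers <- sample(inds, min(k, length(inds)))
      data.frame(insertion_id = id, contig = contig, site = sites[i],
                 strand = strand, individual_id = carriers,
                 allele_count = 1L + rbinom(length(carriers), 1L, hom_prob),
                 mosaic_fraction = 1.0, stringsAsFactors = FALSE)
    } else {
      data.frame(insertion_id = id, contig = contig, site = sites[i],
                 strand = strand, individual_id = sample(inds, 1L),
                 allele_count = 1L,
                 mosaic_fraction = runif(1, mosaic_fraction_range[1],
                                         mosaic_fraction_range[2]),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("truth_insertions", "data.frame")
  out
}
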