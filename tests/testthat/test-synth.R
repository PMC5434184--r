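test_that("generate_genome is seed-deterministic and hits requested GC", {
  g1 <- generate_genome(50000, 0.41, seed = 7)
  g2 <- generate_genome(50000, 0.41, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(g1),
                         as.character(generate_genome(50000, 0.41, seed = 8))))

  g <- generate_genome(100000, 0.5, seed = 1)
  gc <- Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)[1]
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)

  expect_error(generate_genome(0, 0.5), "length")
  expect_error(generate_genome(50000, 0), "gc_fraction")
})

test_that("make_annotations places the requested features and round-trips BED", {
  g <- toy_genome()
  ann <- make_annotations(g, n_genes = 5, n_KR = 3, n_KNR = 2, seed = 3)
  expect_equal(nrow(ann$catalog), 5)
  expect_equal(sum(ann$catalog$class == "KR"), 3)
  expect_equal(sum(ann$catalog$class == "KNR"), 2)
  expect_equal(length(unique(ann$genes$gene_id)), 5)
  # every gene has >= 2 exons inside its span, non-overlapping and sorted
  for (id in ann$genes$gene_id) {
    ex <- ann$exons[ann$exons$gene_id == id, ]
    gene <- ann$genes[ann$genes$gene_id == id, ]
    expect_gte(nrow(ex), 2)
    expect_true(all(ex$start >= gene$start & ex$end <= gene$end))
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
    expect_true(gene$tss %in% c(gene$start, gene$end))
  }
  # catalog entries never fall inside exons
  ex_ir <- IRanges::IRanges(ann$exons$start, ann$exons$end)
  hits <- IRanges::findOverlaps(IRanges::IRanges(ann$catalog$pos, width = 1),
                                ex_ir)
  expect_equal(length(hits), 0)

  tmp <- tempfile(fileext = ".bed")
  write_catalog_bed(ann$catalog, tmp)
  back <- read_catalog_bed(tmp)
  expect_equal(back$pos, ann$catalog$pos)
  expect_equal(back$class, ann$catalog$class)
  expect_equal(back$strand, ann$catalog$strand)

  gm <- tempfile()
  write_gene_models(ann, gm)
  back <- read_gene_models(gm)
  expect_equal(back$genes[, c("gene_id", "start", "end", "tss")],
               ann$genes[, c("gene_id", "start", "end", "tss")])
  expect_equal(back$exons$start, ann$exons$start)

  expect_error(make_annotations(generate_genome(10000, 0.5, 1),
                                n_genes = 20, n_KR = 10, n_KNR = 10),
               "too small")
})

test_that("plant_insertions respects zygosity/mosaic invariants", {
  g <- toy_genome()
  mani <- make_pools(1, 5)
  tr <- plant_insertions(g, mani, 6, germline_fraction = 1, seed = 2)
  expect_true(all(tr$mosaic_fraction == 1))
  expect_true(all(tr$allele_count %in% 1:2))
  expect_identical(tr, plant_insertions(g, mani, 6, germline_fraction = 1,
                                        seed = 2))

  som <- plant_insertions(g, mani, 6, germline_fraction = 0,
                          mosaic_fraction_range = c(0.05, 0.5), seed = 2)
  expect_true(all(som$mosaic_fraction < 1 & som$mosaic_fraction > 0))
  # somatic events are confined to a single individual
  expect_true(all(table(som$insertion_id) == 1))

  expect_error(plant_insertions(generate_genome(12000, .5, 1), mani, 50,
                                seed = 1),
               "space|crowded")
})

test_that("simulated reads carry the genomic flank at the junction", {
  g <- toy_genome()
  mani <- make_pools(1, 2)
  tr <- plant_insertions(g, mani, 4, germline_fraction = 1, seed = 5)
  cfg <- sim_config(depth_per_insertion = 20, duplicate_rate = 0,
                    base_error_rate = 0, noise_read_fraction = 0, seed = 5)
  sim <- simulate_l1seq_reads(g, tr, catalog = NULL, mani, cfg)
  expect_gt(sum(sim$counts), 0)
  expect_equal(sim$counts[["catalog"]], 0)
  expect_equal(sim$counts[["noise"]], 0)

  gseq <- as.character(g[[1]])
  jit <- cfg$jitter_window
  for (p in names(sim$reads)) {
    reads <- sim$reads[[p]]
    meta <- sim$meta[sim$meta$pool_id == p, ]
    for (i in seq_along(reads)) {
      k64 <- as.character(Biostrings::subseq(reads[[i]], 11, 74))
      m <- meta[meta$read_id == names(reads)[i], ]
      site <- m$site
      flank <- if (m$strand == "+")
        substr(gseq, site + 1, site + 64 + jit)
      else as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(gseq, site - 63 - jit, site))))
      # trimmed block occurs in the flank, anchored at the junction side
      expect_true(grepl(k64, flank, fixed = TRUE))
      if (m$offset == 0)
        expect_identical(substr(flank, 1, 64), k64)
    }
  }
})

test_that("read counts conserve categories and scale with mosaic fraction", {
  g <- toy_genome()
  mani <- make_pools(1, 2)
  tr <- plant_insertions(g, mani, 3, germline_fraction = 1, seed = 9)
  ann <- make_annotations(g, 3, 2, 1, seed = 9)
  cfg <- sim_config(noise_read_fraction = 0.1, seed = 4)
  sim <- simulate_l1seq_reads(g, tr, ann$catalog, mani, cfg)
  expect_equal(sum(sim$counts), nrow(sim$meta))
  expect_equal(sum(lengths(sim$reads)), nrow(sim$meta))
  expect_equal(as.vector(table(factor(sim$meta$category,
                                      c("insertion", "catalog", "noise")))),
               unname(sim$counts[c("insertion", "catalog", "noise")]))

  # identical config + seed => byte-identical FASTQ
  d1 <- tempfile(); d2 <- tempfile()
  write_pool_fastq(sim, d1)
  write_pool_fastq(simulate_l1seq_reads(g, tr, ann$catalog, mani, cfg), d2)
  f <- list.files(d1)
  expect_identical(lapply(file.path(d1, f), readLines),
                   lapply(file.path(d2, f), readLines))

  # a 10% mosaic receives ~10% of the reads of a germline het carrier
  ind <- mani$individual_id[1]
  t2 <- data.frame(
    insertion_id = c("GERM", "MOSA"), contig = names(g)[1],
    site = c(10000L, 30000L), strand = "+", individual_id = ind,
    allele_count = 1L, mosaic_fraction = c(1.0, 0.1))
  class(t2) <- c("truth_insertions", "data.frame")
  counts <- vapply(1:30, function(s) {
    cfg <- sim_config(depth_per_insertion = 20, duplicate_rate = 0,
                      base_error_rate = 0, noise_read_fraction = 0, seed = s)
    sim <- simulate_l1seq_reads(g, t2, NULL, mani, cfg)
    c(sum(sim$meta$source_id == "GERM"), sum(sim$meta$source_id == "MOSA"))
  }, c(1, 1))
  ratio <- sum(counts[2, ]) / sum(counts[1, ])
  expect_gt(ratio, 0.05)
  expect_lt(ratio, 0.2)
})

test_that("PCR duplicates reduce distinct start positions as expected", {
  g <- toy_genome()
  mani <- make_pools(1, 1)
  tr <- plant_insertions(g, mani, 1, germline_fraction = 1, seed = 1)
  tr <- tr[1, ]; tr$allele_count <- 1L
  class(tr) <- c("truth_insertions", "data.frame")
  distinct <- vapply(1:40, function(s) {
    cfg <- sim_config(depth_per_insertion = 20, duplicate_rate = 0.5,
                      base_error_rate = 0, noise_read_fraction = 0, seed = s)
    sim <- simulate_l1seq_reads(g, tr, NULL, mani, cfg)
    length(unique(sim$meta$true_start)) / nrow(sim$meta)
  }, 1.0)
  # fresh-offset fraction ~ (1 + (n-1)(1-d))/n ~ 0.525 for n = 20, d = 0.5
  expect_gt(mean(distinct), 0.40)
  expect_lt(mean(distinct), 0.65)
})

test_that("simulate_droplets follows the Poisson partition model", {
  d0 <- simulate_droplets(0, 1000, 10000, seed = 1)
  expect_equal(d0$positives_target, 0)

  # lambda = conc x volume = 1 => positive fraction 1 - e^-1 ~ 0.6321
  d <- simulate_droplets(1 / 0.00085, 0, 10000, droplet_volume = 0.00085,
                         seed = 2)
  expect_lt(abs(d$positives_target - 6321), 150)

  expect_identical(simulate_droplets(500, 900, 5000, seed = 3),
                   simulate_droplets(500, 900, 5000, seed = 3))
  expect_error(simulate_droplets(-1, 0, 100), "target_copies_per_ul")
})
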