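test_that("build_peaks clusters reads and computes the quality metrics", {
  # 10 reads on + strand with starts 1000..1005 -> one peak
  a <- do.call(rbind, lapply(c(1000:1005, 1000, 1001, 1002, 1003),
                             function(s) aln_row(s, read_id = NULL)))
  a$read_id <- sprintf("r%02d", seq_len(nrow(a)))
  pk <- build_peaks(a, window = 64)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$unique_alignments, 6)
  expect_equal(pk$insertion_point, 1000)
  expect_equal(pk$total_reads, 10)
  expect_equal(pk$maxcount, 10)
  expect_equal(pk$maxuniq, 6)

  # two read groups 10 kb apart -> two peaks
  b <- rbind(a, do.call(rbind, lapply(11000:11004, aln_row)))
  pk2 <- build_peaks(b, window = 64)
  expect_equal(nrow(pk2), 2)

  # 8 identical-start reads -> unique_alignments = 1 (fails maxuniq > 1)
  c8 <- do.call(rbind, lapply(rep(5000, 8), aln_row))
  c8$read_id <- sprintf("d%d", 1:8)
  pk3 <- build_peaks(c8)
  expect_equal(pk3$unique_alignments, 1)
  expect_equal(pk3$maxuniq, 1)

  # minus-strand peak anchors at the rightmost read end; strands never merge
  d <- rbind(aln_row(2000, "+"), aln_row(2010, "-"), aln_row(2020, "-"))
  pk4 <- build_peaks(d)
  expect_equal(nrow(pk4), 2)
  minus <- pk4[pk4$strand == "-", ]
  expect_equal(minus$insertion_point, 2020 + 63)

  # per-pool bookkeeping: totals across the pool matrix match
  e <- rbind(aln_row(3000, pool = "p1"), aln_row(3001, pool = "p1"),
             aln_row(3002, pool = "p2"))
  pk5 <- build_peaks(e)
  expect_equal(unname(rowSums(attr(pk5, "pool_counts"))), pk5$total_reads)
  expect_equal(pk5$maxcount, 2)

  expect_equal(nrow(build_peaks(NULL)), 0)
})

test_that("peak membership matches brute-force single-linkage clustering", {
  set.seed(99)
  for (rep in 1:5) {
    starts <- sort(sample(1:3000, 40, replace = TRUE))
    a <- do.call(rbind, lapply(starts, aln_row))
    a$read_id <- sprintf("r%03d", seq_len(nrow(a)))
    pk <- build_peaks(a, window = 64)
    oracle <- brute_force_clusters(starts, 64)
    expect_equal(nrow(pk), length(unique(oracle)))
    # cluster sizes agree (order-independent comparison)
    expect_equal(sort(pk$total_reads),
                 sort(unname(as.vector(table(oracle)))))
  }
})

test_that("mappability scores k-mer uniqueness", {
  # genome with an exactly duplicated 64-mer
  set.seed(5)
  core <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  dup <- substr(core, 501, 564)
  gseq <- paste0(core, dup)
  genome <- Biostrings::DNAStringSet(c(chrT = gseq))

  tr <- compute_mappability(genome, k = 64, positions = c(100, 501, 12001))
  expect_equal(unname(tr[1]), 1.0)
  expect_equal(unname(tr[2]), 0.5)   # duplicated 64-mer
  expect_equal(unname(tr[3]), 0.5)   # its copy

  expect_error(compute_mappability(genome, k = 20000), "exceeds")

  # peak over unique sequence gets mappability 1
  pk <- build_peaks(aln_row(1000, contig = "chrT"))
  pk <- annotate_mappability(pk, genome)
  expect_equal(pk$mappability, 1.0)
})

test_that("classify_peaks honors the proximity window and KR precedence", {
  catalog <- data.frame(
    contig = "chrS1", pos = c(10000L, 20000L), strand = "+",
    class = c("KR", "KNR"), label = c("kr1", "knr1"))
  mk_peak <- function(ip) {
    pk <- build_peaks(aln_row(ip))
    pk$insertion_point <- ip
    pk
  }
  expect_equal(classify_peaks(mk_peak(10100), catalog)$catalog_class, "KR")
  expect_equal(classify_peaks(mk_peak(20100), catalog)$catalog_class, "KNR")
  # boundary: exactly 500 matches, 501 does not
  expect_equal(classify_peaks(mk_peak(10500), catalog)$catalog_class, "KR")
  expect_equal(classify_peaks(mk_peak(10501), catalog)$catalog_class,
               "novel")
  # KR precedence on a double match
  both <- data.frame(contig = "chrS1", pos = c(30000L, 30010L),
                     strand = "+", class = c("KNR", "KR"),
                     label = c("knr", "kr"))
  expect_equal(classify_peaks(mk_peak(30005), both)$catalog_class, "KR")
  # every peak gets exactly one class
  set.seed(1)
  many <- do.call(rbind, lapply(sample(1:40000, 30) + 10000, mk_peak))
  cls <- classify_peaks(many, catalog)$catalog_class
  expect_true(all(cls %in% c("KR", "KNR", "novel")))
  expect_equal(length(cls), 30)
})

test_that("filter profiles match their stated thresholds", {
  pk <- build_peaks(do.call(rbind, lapply(1000:1005, aln_row)))
  pk$mappability <- 1.0

  # passes "original": maxcount 6 > 5, maxuniq 6 > 1, mean_mapq 60,
  # mapscore 1
  expect_equal(nrow(apply_filter(pk, filter_profile("original"))), 1)
  expect_equal(nrow(apply_filter(pk, filter_profile("new"))), 1)

  # total reads = 5 fails "new" (strict >)
  pk5 <- build_peaks(do.call(rbind, lapply(1000:1004, aln_row)))
  pk5$mappability <- 1.0
  expect_equal(nrow(apply_filter(pk5, filter_profile("new"))), 0)

  # mean_matchpct exactly 0.98 fails "new" (strict >)
  pk98 <- pk
  pk98$mean_matchpct <- 0.98
  expect_equal(nrow(apply_filter(pk98, filter_profile("new"))), 0)

  # spot values from the stated original profile
  pko <- pk
  pko$maxcount <- 6; pko$maxuniq <- 2; pko$mean_mapq <- 35
  pko$mapscore <- 0.6
  expect_equal(nrow(apply_filter(pko, filter_profile("original"))), 1)
  pko$maxcount <- 5
  expect_equal(nrow(apply_filter(pko, filter_profile("original"))), 0)

  expect_error(apply_filter(pk[, setdiff(names(pk), "mapscore")],
                            filter_profile("original")),
               "mapscore")
})

test_that("stricter profiles retain a subset (monotonicity)", {
  set.seed(8)
  peaks <- do.call(rbind, lapply(1:50, function(i) {
    pk <- build_peaks(do.call(rbind, lapply(
      seq(i * 1000, i * 1000 + sample(0:8, 1)), aln_row)))
    pk$mean_mapq <- sample(c(10, 29, 30, 45, 60), 1)
    pk$mapscore <- runif(1)
    pk$mean_matchpct <- runif(1, 0.9, 1)
    pk$mappability <- runif(1)
    pk
  }))
  base <- filter_profile("new")
  stricter <- filter_profile("custom", rules = within(base$rules, {
    value <- value + c(10, 0.2, 0.005, 4, 2)
  }))
  kept_base <- apply_filter(peaks, base)$peak_id
  kept_strict <- apply_filter(peaks, stricter)$peak_id
  expect_true(all(kept_strict %in% kept_base))
})

test_that("genic context uses exon/intron bodies and 500 bp end windows", {
  genes <- data.frame(
    gene_id = c("GENE002", "GENE001"), contig = "chrS1",
    start = c(10000L, 10800L), end = c(11000L, 12000L),
    strand = c("+", "+"), tss = c(10000L, 10800L),
    utr3_end = c(11000L, 12000L))
  ctx <- function(ip) {
    pk <- build_peaks(aln_row(ip))
    pk$insertion_point <- ip
    annotate_genic_context(pk, genes)
  }
  expect_equal(ctx(10500)$genic_context, "intragenic")   # inside the body
  expect_equal(ctx(9501)$genic_context, "intragenic")    # 499 bp from TSS
  expect_equal(ctx(9500)$genic_context, "intragenic")    # exactly 500
  expect_equal(ctx(9499)$genic_context, "intergenic")    # 501 bp away
  # nearest-gene tie inside the overlap region -> lexicographically smallest
  expect_equal(ctx(10900)$gene_id, "GENE001")
  # empty gene set
  expect_equal(ctx(10500)$genic_context, "intragenic")
  pk <- build_peaks(aln_row(10500))
  expect_equal(annotate_genic_context(pk, NULL)$genic_context, "intergenic")
})
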