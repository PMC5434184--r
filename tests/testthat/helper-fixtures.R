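# Shared fixtures, built in code.  The "demo world" (the package's default
# configuration: 5 Mb genome, 6 pools of 10, 40 germline novel insertions)
# is expensive, so it is run lazily once per test session and shared.

.l1peak_cache <- new.env(parent = emptyenv())

demo_run <- function() {
  if (is.null(.l1peak_cache$demo)) {
    cfg <- default_config(seed = 20170406 %% 100000)
    .l1peak_cache$demo <- run_pipeline(cfg, quiet = TRUE)
  }
  .l1peak_cache$demo
}

# a small world for cheap integration-style tests
small_config <- function(seed = 7L, ...) {
  base <- list(
    genome = list(length = 3e5),
    annotations = list(n_genes = 10L, n_KR = 5L, n_KNR = 3L,
                       gene_length_range = c(2000L, 8000L)),
    insertions = list(n_novel = 8L),
    enrich = list(n_terms = 8L),
    seed = seed)
  do.call(default_config, utils::modifyList(base, list(...)))
}

# deterministic toy genome with known, unique content
toy_genome <- function(length = 50000L, seed = 11L) {
  generate_genome(length, gc_fraction = 0.41, seed = seed)
}

# hand-built alignment row(s) for peak-caller unit tests
aln_row <- function(start, strand = "+", pool = "pool1", mapq = 60L,
                    matchpct = 1.0, n_best = 1L, width = 64L,
                    contig = "chrS1", read_id = NULL) {
  data.frame(
    read_id = if (is.null(read_id)) sprintf("r%s_%d", strand, start)
      else read_id,
    pool = pool, contig = contig, start = start, end = start + width - 1L,
    strand = strand, mapq = mapq, matchpct = matchpct,
    n_best_hits = n_best, is_unique = n_best == 1L,
    stringsAsFactors = FALSE)
}

# brute-force single-linkage clustering of starts (oracle for build_peaks)
brute_force_clusters <- function(starts, window) {
  n <- length(starts)
  adj <- abs(outer(starts, starts, "-")) <= window
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# exact hypergeometric upper tail by direct combinatorial summation
brute_hyper_tail <- function(x, N, K, n) {
  if (x == 0) return(1.0)
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# exact binomial upper tail by direct summation
brute_binom_tail <- function(x, n, p) {
  if (x == 0) return(1.0)
  ks <- x:n
  sum(choose(n, ks) * p^ks * (1 - p)^(n - ks))
}

# Fisher 2x2 by explicit combinatorial enumeration over the free cell
brute_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(r1 + r2, c1)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) /
    choose(r1 + r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}
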