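#' Gene-set over-representation tests
#'
#' Two classic over-representation statistics over a term-to-gene map:
#' the DAVID-style hypergeometric upper tail and the PANTHER-style binomial
#' upper tail, both with Bonferroni correction.  For a background of `N`
#' annotated genes, a term annotating `K` of them and an input list of `n`
#' genes of which `x` are in the term:
#' \describe{
#'   \item{hypergeometric}{`p = P(X >= x)`, `X ~ Hypergeom(N, K, n)`;
#'     fold enrichment = `(x/n) / (K/N)`.}
#'   \item{binomial}{`p = P(X >= x)`, `X ~ Binomial(n, K/N)`; expected
#'     count = `n K / N`; fold enrichment = `x / expected`.}
#' }
#' Input genes not in the background are dropped with a message.  The
#' Bonferroni multiplier `m` defaults to the number of terms with at least
#' one observed gene; pass `m` to override (e.g. all terms tested).
#'
#' An optional EASE-style conservative variant of the hypergeometric test
#' (`ease = TRUE`) scores the tail at `x - 1`, penalising single-gene
#' overlaps; it is off by default.
#'
#' @param gene_list character vector of input genes.
#' @param term_map a `term_map` (list `terms`, `background_size`) from
#'   [make_term_map()] or [read_gmt()].
#' @param m Bonferroni multiplier; NULL for the default.
#' @param ease use the EASE-adjusted hypergeometric tail.
#' @return data.frame (class `enrichment_result`) with columns term_id,
#'   term_size, observed, expected, percent_of_list, fold_enrichment,
#'   p_raw, p_bonferroni, ordered by p_raw.
#' @examples
#' tm <- structure(list(terms = list(T1 = paste0("g", 1:5)),
#'                      background_size = 20), class = "term_map")
#' hypergeometric_enrichment(paste0("g", c(1:3, 10:12)), tm)
#' @export
hypergeometric_enrichment <- function(gene_list, term_map, m = NULL,
                                      ease = FALSE) {
  enrich_core(gene_list, term_map, m, test = "hypergeometric", ease = ease)
}

#' @rdname hypergeometric_enrichment
#' @export
binomial_enrichment <- function(gene_list, term_map, m = NULL) {
  enrich_core(gene_list, term_map, m, test = "binomial")
}

enrich_core <- function(gene_list, term_map, m, test, ease = FALSE) {
  stopifnot(inherits(term_map, "term_map"))
  N <- term_map$background_size
  if (!length(term_map$terms) || N < 1L) stopf("empty background")
  gene_list <- unique(gene_list)
  ## the background universe may include genes annotated to no term; its
  ## identities are only known when the map carries them
  background <- if (!is.null(term_map$background)) term_map$background else
    unique(unlist(term_map$terms))
  out_bg <- setdiff(gene_list, background)
  if (length(out_bg) && !is.null(term_map$background)) {
    message("dropping ", length(out_bg),
            " input gene(s) not in the background")
    gene_list <- setdiff(gene_list, out_bg)
  }
  n <- length(gene_list)
  if (!n) stopf("empty gene list")
  rows <- lapply(names(term_map$terms), function(t) {
    genes <- term_map$terms[[t]]
    K <- length(genes)
    x <- length(intersect(gene_list, genes))
    expected <- n * K / N
    if (test == "hypergeometric") {
      x_tail <- if (ease) max(0L, x - 1L) else x
      p <- if (x_tail == 0L) 1.0 else
        phyper(x_tail - 1L, K, N - K, n, lower.tail = FALSE)
      fold <- if (expected > 0) (x / n) / (K / N) else NA_real_
    } else {
      p <- if (x == 0L) 1.0 else
        pbinom(x - 1L, n, K / N, lower.tail = FALSE)
      fold <- if (expected > 0) x / expected else NA_real_
    }
    data.frame(term_id = t, term_size = K, observed = x,
               expected = expected, percent_of_list = 100 * x / n,
               fold_enrichment = fold, p_raw = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  ## m defaults to the number of terms with signal, which can be smaller
  ## than the number of rows reported; observed = 0 rows have p_raw = 1
  ## so the cap makes the multiplier choice immaterial for them
  if (is.null(m)) m <- sum(res$observed >= 1L)
  res$p_bonferroni <- pmin(1, m * res$p_raw)
  res <- res[order(res$p_raw, res$term_id), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Bonferroni correction
#'
#' @param p_values raw p-values in \[0, 1\].
#' @param m number of tests (defaults to `length(p_values)`); must be at
#'   least the number of values.
#' @return adjusted p-values `min(1, m * p)` (order-preserving).
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  if (m < length(p_values)) stopf("m must be >= number of p-values")
  pmin(1, m * p_values)
}

#' Fold enrichment from printed observed/expected counts
#'
#' Convenience for recomputing a table's fold-enrichment column from its
#' observed and expected gene counts: `fold = observed / expected`.
#'
#' @param observed,expected gene counts.
#' @return fold enrichment.
#' @examples
#' fold_enrichment(26, 10.4)  # 2.5
#' @export
fold_enrichment <- function(observed, expected) {
  if (any(expected <= 0)) stopf("expected count must be positive")
  observed / expected
}
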