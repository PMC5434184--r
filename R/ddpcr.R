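#' Poisson concentration estimate from droplet counts
#'
#' In ddPCR, template molecules partition into droplets as Poisson, so from
#' the fraction of positive droplets `p` the mean copies per droplet is
#' `lambda = -ln(1 - p)` and the concentration is `lambda / droplet_volume`
#' copies per microliter.  The 95% interval is a Clopper-Pearson binomial
#' interval on `p` propagated through the (monotone) log transform.
#'
#' @param counts a `droplet_counts` object (or any list with
#'   total_droplets, positives_target, positives_reference, droplet_volume).
#' @param channel `"target"` or `"reference"`.
#' @param conf confidence level of the interval.
#' @return a `concentration_estimate` list: lambda (copies/droplet),
#'   copies_per_ul, ci_lower, ci_upper (copies/ul), positives, total.
#' @examples
#' d <- simulate_droplets(1000, 2000, 15000, seed = 1)
#' poisson_concentration(d, "target")
#' @export
poisson_concentration <- function(counts, channel = c("target", "reference"),
                                  conf = 0.95) {
  channel <- match.arg(channel)
  total <- counts$total_droplets
  pos <- counts[[paste0("positives_", channel)]]
  vol <- counts$droplet_volume
  if (is.null(total) || total <= 0L) stopf("zero droplets")
  if (is.null(pos) || pos < 0L || pos > total)
    stopf("positive count outside [0, total]")
  if (pos == total)
    stopf("all droplets positive (saturated); no finite estimate")
  p <- pos / total
  lambda <- -log(1 - p)
  alpha <- 1 - conf
  p_lo <- if (pos == 0L) 0 else qbeta(alpha / 2, pos, total - pos + 1L)
  p_hi <- qbeta(1 - alpha / 2, pos + 1L, total - pos)
  structure(list(
    channel = channel, lambda = lambda,
    copies_per_ul = lambda / vol,
    ci_lower = -log(1 - p_lo) / vol,
    ci_upper = -log(1 - p_hi) / vol,
    positives = pos, total = total, droplet_volume = vol),
    class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("%s: lambda = %.4f copies/droplet, %.1f copies/ul (95%% CI %.1f-%.1f)\n",
              x$channel, x$lambda, x$copies_per_ul, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Allele ratio and zygosity interpretation
#'
#' The reference channel assays a two-copy diploid locus, so a germline
#' heterozygous insertion gives a target/reference copy ratio of ~0.5 and a
#' homozygous one ~1.0; markedly lower ratios indicate the insertion is
#' present in only a fraction of cells (somatic mosaicism).  The bands are
#' working defaults, not assay constants, and are configurable.
#'
#' @param target,reference `concentration_estimate`s for the two channels.
#' @param het_band,hom_band ratio bands called heterozygous / homozygous.
#' @param absent_threshold ratios below this are called absent.
#' @return an `allele_ratio_result` list: ratio, zygosity_call.
#' @export
allele_ratio <- function(target, reference,
                         het_band = c(0.35, 0.65),
                         hom_band = c(0.85, 1.15),
                         absent_threshold = 0.05) {
  if (reference$copies_per_ul <= 0) stopf("zero reference concentration")
  ratio <- target$copies_per_ul / reference$copies_per_ul
  call <- if (ratio < absent_threshold) "absent"
    else if (ratio >= het_band[1] && ratio <= het_band[2]) "heterozygous"
    else if (ratio >= hom_band[1] && ratio <= hom_band[2]) "homozygous"
    else "mosaic-candidate"
  structure(list(ratio = ratio, zygosity_call = call),
            class = "allele_ratio_result")
}

#' Normalize expression against reference assays
#'
#' For each sample, forms the ratio of the target concentration to each
#' named reference assay and to the geometric mean of all references (the
#' usual multi-normalizer correction for input quantity/quality).
#'
#' @param records data.frame with columns sample_id, group, target_conc and
#'   one column per reference assay.
#' @param reference_cols names of the reference columns (>= 1).
#' @return `records` with added `ratio_<reference>` columns and
#'   `ratio_geomean`.
#' @export
normalize_expression <- function(records, reference_cols) {
  stopifnot(is.data.frame(records), length(reference_cols) >= 1L)
  missing <- setdiff(c("target_conc", reference_cols), names(records))
  if (length(missing))
    stopf("records lack column(s): %s", paste(missing, collapse = ", "))
  refs <- as.matrix(records[, reference_cols, drop = FALSE])
  if (any(refs <= 0)) stopf("reference concentrations must be > 0")
  for (rc in reference_cols)
    records[[paste0("ratio_", rc)]] <- records$target_conc / records[[rc]]
  records$ratio_geomean <- records$target_conc /
    apply(refs, 1L, geo_mean)
  records
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact p-value by full enumeration of rank assignments when both groups
#' have at most `exact_max` observations (midranks for ties); otherwise the
#' normal approximation with tie and continuity corrections.  The two-sided
#' exact p is `min(1, 2 * min(P(W <= w), P(W >= w)))` for the observed
#' rank sum `w` of the first group.
#'
#' @param groupA,groupB numeric vectors (non-empty).
#' @param exact_max enumeration threshold per group.
#' @return two-sided p-value in (0, 1].
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
wilcoxon_rank_sum <- function(groupA, groupB, exact_max = 10L) {
  nA <- length(groupA); nB <- length(groupB)
  if (!nA || !nB) stopf("both groups must be non-empty")
  r <- rank(c(groupA, groupB))
  w <- sum(r[seq_len(nA)])
  if (nA <= exact_max && nB <= exact_max) {
    sets <- combn(nA + nB, nA)
    ws <- colSums(matrix(r[sets], nrow = nA))
    tol <- 1e-9
    p <- 2 * min(mean(ws <= w + tol), mean(ws >= w - tol))
    return(min(1, p))
  }
  mu <- nA * (nA + nB + 1) / 2
  ties <- table(r)
  n <- nA + nB
  sigma2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1.0)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, max(2 * pnorm(z, lower.tail = FALSE), .Machine$double.xmin))
}

#' Simulated heterozygous-carrier allele-ratio experiment
#'
#' End-to-end check of the ddPCR quantification model: droplets are
#' simulated for an individual heterozygous for an insertion (one
#' insertion-allele copy per genome) against a two-copy diploid reference
#' locus at matched genome concentration, each channel is quantified with
#' [poisson_concentration()] and the target/reference ratio taken from
#' [allele_ratio()]; the mean ratio over `n_reps` seeded replicates is
#' returned and should recover ~0.5.
#'
#' @param n_reps number of replicates.
#' @param genome_copies_per_ul haploid genome concentration; the target
#'   allele is at 1x and the reference locus at 2x this concentration.
#' @param total_droplets droplets per channel per replicate.
#' @param droplet_volume droplet volume in microliters.
#' @param seed integer seed.
#' @return list: mean_ratio, ratios (per replicate), zygosity_calls.
#' @export
simulate_het_allele_ratio <- function(n_reps = 50L,
                                      genome_copies_per_ul = 1000,
                                      total_droplets = 15000L,
                                      droplet_volume = 0.00085,
                                      seed = 1L) {
  ratios <- numeric(n_reps)
  calls <- character(n_reps)
  for (i in seq_len(n_reps)) {
    d <- simulate_droplets(genome_copies_per_ul, 2 * genome_copies_per_ul,
                           total_droplets, droplet_volume,
                           seed = derive_seed(seed, 100L + i))
    ar <- allele_ratio(poisson_concentration(d, "target"),
                       poisson_concentration(d, "reference"))
    ratios[i] <- ar$ratio
    calls[i] <- ar$zygosity_call
  }
  list(mean_ratio = mean(ratios), ratios = ratios, zygosity_calls = calls)
}
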