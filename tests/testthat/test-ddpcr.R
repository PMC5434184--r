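dc <- function(pos_t, pos_r = 0L, total = 10000L, vol = 0.00085) {
  structure(list(total_droplets = total, positives_target = pos_t,
                 positives_reference = pos_r, droplet_volume = vol),
            class = "droplet_counts")
}

test_that("poisson_concentration inverts the partition model", {
  expect_equal(poisson_concentration(dc(0), "target")$lambda, 0)
  # 6321/10000 positives -> lambda = -ln(1 - 0.6321) ~ 1.000
  est <- poisson_concentration(dc(6321), "target")
  expect_equal(est$lambda, -log(1 - 0.6321), tolerance = 1e-12)
  expect_equal(est$lambda, 1.0, tolerance = 1e-3)
  expect_equal(est$copies_per_ul, est$lambda / 0.00085)
  expect_true(est$ci_lower <= est$copies_per_ul &&
                est$copies_per_ul <= est$ci_upper)
  expect_error(poisson_concentration(dc(10000), "target"), "saturated")
  expect_error(poisson_concentration(dc(1, total = 0), "target"), "droplets")
})

test_that("the 95% interval covers the true concentration", {
  true_conc <- 1 / 0.00085   # lambda = 1
  covered <- vapply(1:100, function(s) {
    d <- simulate_droplets(true_conc, 0, 10000, seed = 5000 + s)
    est <- poisson_concentration(d, "target")
    est$ci_lower <= true_conc && true_conc <= est$ci_upper
  }, TRUE)
  expect_gte(sum(covered), 93)
})

test_that("allele_ratio bands map ratios to zygosity calls", {
  est <- function(conc) structure(list(copies_per_ul = conc),
                                  class = "concentration_estimate")
  expect_equal(allele_ratio(est(500), est(1000))$zygosity_call,
               "heterozygous")
  expect_equal(allele_ratio(est(1000), est(1000))$zygosity_call,
               "homozygous")
  # 20% of cells heterozygous -> ratio ~ 0.1 -> mosaic candidate
  r <- allele_ratio(est(100), est(1000))
  expect_equal(r$ratio, 0.1)
  expect_equal(r$zygosity_call, "mosaic-candidate")
  expect_equal(allele_ratio(est(0), est(1000))$zygosity_call, "absent")
  expect_error(allele_ratio(est(1), est(0)), "reference")
})

test_that("simulated heterozygous carriers recover a ~50% allele ratio", {
  res <- simulate_het_allele_ratio(n_reps = 50, seed = 123)
  expect_gt(res$mean_ratio, 0.48)
  expect_lt(res$mean_ratio, 0.52)
  expect_true(all(res$zygosity_calls == "heterozygous"))
})

test_that("normalize_expression forms per-reference and geomean ratios", {
  rec <- data.frame(sample_id = c("s1", "s2"), group = c("cocaine", "control"),
                    target_conc = c(4, 8), GAPDH = c(2, 2), ACTB = c(4, 4),
                    TBP = c(8, 8))
  out <- normalize_expression(rec, c("GAPDH", "ACTB", "TBP"))
  expect_equal(out$ratio_geomean, c(1, 2))   # geomean(2,4,8) = 4
  expect_equal(out$ratio_GAPDH, c(2, 4))

  # single reference: geomean equals it
  one <- normalize_expression(rec, "ACTB")
  expect_equal(one$ratio_geomean, one$ratio_ACTB)

  # equal scaling of target and references leaves ratios unchanged
  sc <- rec
  sc[, c("target_conc", "GAPDH", "ACTB", "TBP")] <-
    sc[, c("target_conc", "GAPDH", "ACTB", "TBP")] * 7
  expect_equal(normalize_expression(sc, c("GAPDH", "ACTB", "TBP"))$ratio_geomean,
               out$ratio_geomean)

  bad <- rec; bad$GAPDH[1] <- 0
  expect_error(normalize_expression(bad, c("GAPDH", "ACTB")), "> 0")
})

test_that("wilcoxon_rank_sum: exact enumeration, ties, and approximation", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)

  # exact path agrees with the reference implementation (no ties)
  set.seed(17)
  for (i in 1:10) {
    a <- sample(1:1000, 6); b <- sample(2000:3000, 7) / 3
    expect_equal(wilcoxon_rank_sum(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # approximate path agrees with exact within 0.02 at n = 10 vs 10
  set.seed(18)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10, mean = runif(1, 0, 1.5))
    p_ex <- wilcoxon_rank_sum(a, b, exact_max = 10)
    p_ap <- wilcoxon_rank_sum(a, b, exact_max = 5)
    expect_lt(abs(p_ex - p_ap), 0.02)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("droplet CSV round-trips and the CLI quantification path works", {
  d <- simulate_droplets(800, 1600, 15000, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_droplet_csv(d, f)
  back <- read_droplet_csv(f)
  expect_equal(back$positives_target, d$positives_target)
  est <- poisson_concentration(as.list(back[1, ]), "reference")
  expect_equal(est$positives, d$positives_reference)
})
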