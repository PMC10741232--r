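test_that("HWE chi-square reproduces hand-verified cases", {
  # heterozygote excess among 107 patients: (61, 46, 0)
  h <- hwe_chi_square(c(61, 46, 0))
  expect_equal(h$chi2, 8.021, tolerance = 5e-3 / 8)
  expect_false(h$in_hwe)
  expect_equal(h$maf, 46 / 214)

  expect_equal(hwe_chi_square(c(25, 50, 25))$chi2, 0)
  # all homozygotes, equal classes: chi2 = n
  expect_equal(hwe_chi_square(c(50, 0, 50))$chi2, 100)
  mono <- hwe_chi_square(c(40, 0, 0))
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p, 1)
  expect_error(hwe_chi_square(c(-1, 2, 3)), "negative")
})

test_that("HWE chi-square agrees with the goodness-of-fit oracle", {
  # independent oracle: stats::chisq.test against HWE cell probabilities
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    cnt <- as.vector(stats::rmultinom(1, n, c(0.4, 0.4, 0.2)))
    q <- (2 * cnt[3] + cnt[2]) / (2 * n)
    if (q == 0 || q == 1) next
    oracle <- suppressWarnings(
      stats::chisq.test(cnt, p = c((1 - q)^2, 2 * q * (1 - q), q^2)))
    expect_equal(hwe_chi_square(cnt)$chi2, unname(oracle$statistic),
                 tolerance = 1e-12)
  }
})

test_that("exact HWE test behaves sensibly on sparse classes", {
  expect_equal(hwe_exact(c(85, 1, 0)), 1)
  # strong het excess: exact and chi-square agree on significance
  expect_lt(hwe_exact(c(61, 46, 0)), 0.05)
  expect_gt(hwe_exact(c(25, 50, 25)), 0.5)
})

test_that("pooled MAF matches the reference allele counts", {
  expect_equal(pooled_maf(c(168, 46), c(138, 30)), 76 / 382)
  expect_equal(pooled_maf(c(150, 90), c(118, 56)), 146 / 414)
  expect_equal(pooled_maf(c(10, 10), c(7, 7)), 0.5)
  expect_error(pooled_maf(c(0, 0), c(0, 0)), "zero")
})

test_that("Woolf odds ratios and CIs reproduce hand-verified tables", {
  or <- odds_ratio_woolf(c(168, 46, 138, 30))
  expect_lt(abs(or$oddsratio - 0.794), 5e-3)
  expect_lt(abs(or$ci_low - 0.4757), 5e-3)
  expect_lt(abs(or$ci_high - 1.325), 5e-3)
  or2 <- odds_ratio_woolf(c(207, 1, 171, 1))
  expect_lt(abs(or2$oddsratio - 1.210), 5e-3)
  expect_lt(abs(or2$ci_high - 19.497), 5e-3)

  sym <- odds_ratio_woolf(c(1, 1, 1, 1))
  expect_equal(sym$oddsratio, 1)
  expect_equal(log(sym$ci_low), -log(sym$ci_high))
})

test_that("transposed comparisons invert the OR and swap the CI", {
  set.seed(7)
  for (i in 1:25) {
    tb <- sample(1:200, 4)
    a <- odds_ratio_woolf(tb)
    b <- odds_ratio_woolf(tb[c(3, 4, 1, 2)])
    expect_equal(b$oddsratio, 1 / a$oddsratio)
    expect_equal(b$ci_low, 1 / a$ci_high)
    expect_equal(b$ci_high, 1 / a$ci_low)
  }
})

test_that("zero cells trigger Haldane correction; zero margins give NA", {
  z <- odds_ratio_woolf(c(6, 114, 0, 87))
  expect_true(z$corrected)
  expect_true(is.finite(z$oddsratio))
  m <- odds_ratio_woolf(c(0, 10, 0, 12))
  expect_true(is.na(m$oddsratio))
})

test_that("Pearson chi-square matches the closed form and stats::chisq.test", {
  t1 <- pearson_chi2_2x2(c(138, 30, 168, 46))
  expect_equal(t1$statistic, 0.7817, tolerance = 1e-4)
  expect_equal(t1$p, 0.3766, tolerance = 1e-4)
  expect_equal(pearson_chi2_2x2(c(10, 10, 10, 10))$statistic, 0)
  expect_equal(pearson_chi2_2x2(c(20, 10, 5, 25))$statistic * 2,
               pearson_chi2_2x2(2 * c(20, 10, 5, 25))$statistic)
  set.seed(8)
  for (i in 1:25) {
    tb <- sample(1:80, 4)
    oracle <- suppressWarnings(
      stats::chisq.test(matrix(tb, 2, byrow = TRUE), correct = FALSE))
    expect_equal(pearson_chi2_2x2(tb)$statistic, unname(oracle$statistic))
    expect_equal(pearson_chi2_2x2(tb)$p, oracle$p.value)
  }
  expect_warning(res <- pearson_chi2_2x2(c(0, 0, 5, 5)), "margin")
  expect_equal(res$p, 1)
})

# independent enumeration oracle: direct combinatorial probability of every
# table with the observed margins
fisher_enum_oracle <- function(tb) {
  a <- tb[1]; b <- tb[2]; c_ <- tb[3]; d <- tb[4]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- sum(tb)
  avals <- max(0, c1 - r2):min(r1, c1)
  logp <- vapply(avals, function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }, 0)
  p <- exp(logp)
  sum(p[p <= p[match(a, avals)] * (1 + 1e-7)])
}

test_that("Fisher exact matches exhaustive enumeration and stats::fisher.test", {
  expect_lt(fisher_exact_2x2(c(6, 114, 0, 87))$p, 0.05)
  expect_equal(fisher_exact_2x2(c(0, 0, 12, 9))$p, 1)
  set.seed(9)
  for (i in 1:40) {
    n <- sample(8:40, 1)
    tb <- as.vector(stats::rmultinom(1, n, c(0.3, 0.2, 0.3, 0.2)))
    got <- fisher_exact_2x2(tb)$p
    expect_equal(got, fisher_enum_oracle(tb), tolerance = 1e-12)
    expect_equal(got,
                 stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Pearson and Fisher converge on large well-filled tables", {
  # agreement is asserted where it matters for decisions (p <= 0.5); in the
  # far-null region the min-likelihood two-sided exact p can sit a few
  # percent above the chi-square approximation even in large tables
  set.seed(10)
  checked <- 0L
  for (i in 1:40) {
    tb <- as.vector(stats::rmultinom(1, 6400, c(0.3, 0.2, 0.3, 0.2)))
    pp <- pearson_chi2_2x2(tb)$p
    if (pp > 0.5) next
    checked <- checked + 1L
    expect_lt(abs(pp - fisher_exact_2x2(tb)$p), 0.02)
  }
  expect_gte(checked, 10L)
})

test_that("genotypic models build the documented 2x2 comparisons", {
  ref <- reference_counts()
  p <- panel_from_marginal_counts(ref$genotype_counts, ref$n_cases,
                                  ref$n_controls, snps = ref$snps, seed = 2)
  dom <- genotypic_association(p, "dominant")
  row <- dom[dom$snp_id == "rs2922126", ]
  expect_equal(row$oddsratio, 1.292, tolerance = 5e-3)

  mono <- genotypic_association(p, "pairwise")
  expect_match(mono$comparison[mono$snp_id == "rs34911341"], "monomorphic")

  # identical case/control distributions -> all ORs 1
  g <- rbind(matrix(rep(c(0L, 1L, 2L), 10), ncol = 1),
             matrix(rep(c(0L, 1L, 2L), 10), ncol = 1))
  eq <- make_panel(g, rep(c("case", "control"), each = 30))
  res <- genotypic_association(eq, "pairwise")
  expect_true(all(res$oddsratio == 1))
})

test_that("proportion-test power is calibrated and monotone", {
  expect_equal(power_two_proportions(0.2, 0, 100, 100), 0.05, tolerance = 1e-9)
  p_small <- power_two_proportions(0.2, 0.1, 80, 80)
  p_bign <- power_two_proportions(0.2, 0.1, 300, 300)
  p_bigd <- power_two_proportions(0.2, 0.2, 80, 80)
  expect_gt(p_bign, p_small)
  expect_gt(p_bigd, p_small)
  expect_error(power_two_proportions(0.9, 0.2, 50, 50), "\\(0, 1\\)")

  # Monte-Carlo oracle at the design's allele-scale sizes
  set.seed(11)
  rej <- mean(replicate(4000, {
    x1 <- stats::rbinom(1, 190, 0.2)
    x2 <- stats::rbinom(1, 240, 0.4)
    suppressWarnings(stats::prop.test(c(x1, x2), c(190, 240),
                                      correct = FALSE)$p.value) < 0.05
  }))
  expect_lt(abs(power_two_proportions(0.2, 0.2, 240, 190) - rej), 0.02)
})
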