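test_that("EM equals direct counting when phase is unambiguous", {
  g <- cbind(c(0L, 0L, 2L, 2L, 0L), c(0L, 2L, 0L, 2L, 0L))
  p <- make_panel(g, c("case", "case", "control", "control", "case"))
  em <- em_haplotype_freqs(p, c("s1", "s2"))
  got <- setNames(em$frequencies, em$haplotypes)
  expect_equal(unname(got["AA"]), 4 / 10, tolerance = 1e-8)
  expect_equal(unname(got["AB"]), 2 / 10, tolerance = 1e-8)
  expect_equal(unname(got["BA"]), 2 / 10, tolerance = 1e-8)
  expect_equal(unname(got["BB"]), 2 / 10, tolerance = 1e-8)
})

test_that("all-double-heterozygote panels yield the symmetric solution", {
  g <- matrix(1L, 8, 2)
  p <- make_panel(g, rep(c("case", "control"), 4))
  em <- em_haplotype_freqs(p, c("s1", "s2"))
  f <- setNames(em$frequencies, em$haplotypes)
  expect_equal(unname(f["AA"]), unname(f["BB"]), tolerance = 1e-8)
  expect_equal(unname(f["AB"]), unname(f["BA"]), tolerance = 1e-8)
  expect_equal(sum(f), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood never decreases", {
  set.seed(21)
  for (i in 1:5) {
    g <- matrix(sample(0:2, 40, replace = TRUE), 20, 2)
    g[sample(40, 4)] <- NA
    p <- make_panel(g, rep(c("case", "control"), 10))
    em <- suppressWarnings(em_haplotype_freqs(p, c("s1", "s2")))
    expect_true(all(diff(em$loglik_trace) > -1e-8))
  }
})

test_that("EM matches the exhaustive grid-search ML oracle", {
  set.seed(22)
  for (i in 1:4) {
    n <- sample(8:20, 1)
    g <- matrix(sample(0:2, 2 * n, replace = TRUE, prob = c(.5, .35, .15)),
                n, 2)
    p <- make_panel(g, rep_len(c("case", "control"), n))
    em <- suppressWarnings(em_haplotype_freqs(p, c("s1", "s2")))
    oracle <- grid_ml_oracle(g)
    # oracle order AB, Ab, aB, ab refers to minor dosage (0,0),(0,1),(1,0),(1,1)
    em_f <- em$frequencies[order(em$hap_minor[, 1], em$hap_minor[, 2])]
    expect_true(all(abs(em_f - oracle$freqs) < 0.02))
  }
})

test_that("EM recovers a 3-SNP generating pool and handles missingness", {
  blk <- ghsr_pool_block()
  cfg <- cohort_config(blocks = list(blk), n_cases = 500, n_controls = 500,
                       missing_rate = 0.05, seed = 23)
  p <- simulate_cohort(cfg)
  em <- suppressWarnings(em_haplotype_freqs(p, c("h1", "h2", "h3")))
  truth <- setNames(blk$freqs, blk$haplotypes)
  est <- setNames(em$frequencies, em$haplotypes)
  expect_lt(mean(abs(est[names(truth)] - truth)), 0.02)
  # individuals missing >2 of the block SNPs are not usable
  expect_lte(em$n_used, n_samples(p))
})

test_that("haplotype association is null on identical groups, powered on shifts", {
  g <- matrix(sample(0:2, 200, replace = TRUE, prob = c(.49, .42, .09)), 100, 2)
  p <- make_panel(rbind(g, g), rep(c("case", "control"), each = 100))
  res <- haplotype_association(p, c("s1", "s2"))
  expect_true(all(res$chi2 < 1e-6))
  expect_true(all(res$p > 0.999))
  expect_true(!is.unsorted(rev(res$freq_pooled)))

  # haplotype AB enriched in cases: 0.30 vs 0.15
  blk_case <- list(snps = default_meta(c("s1", "s2")),
                   haplotypes = c("AA", "AB", "BA", "BB"),
                   freqs = c(0.40, 0.30, 0.20, 0.10))
  blk_ctrl <- list(snps = default_meta(c("s1", "s2")),
                   haplotypes = c("AA", "AB", "BA", "BB"),
                   freqs = c(0.55, 0.15, 0.20, 0.10))
  pc <- simulate_genotypes(cohort_config(blocks = list(blk_case),
                                         n_cases = 500, n_controls = 0,
                                         missing_rate = 0, seed = 24),
                           n = 500)
  pk <- simulate_genotypes(cohort_config(blocks = list(blk_ctrl),
                                         n_cases = 0, n_controls = 500,
                                         missing_rate = 0, seed = 25),
                           n = 500)
  pk$phenotype <- factor(rep("control", 500), levels = c("control", "case"))
  both <- make_panel(rbind(pc$genotypes, pk$genotypes),
                     c(rep("case", 500), rep("control", 500)),
                     snps = pc$snps, sample_id = sprintf("i%04d", 1:1000))
  res2 <- haplotype_association(both, c("s1", "s2"))
  expect_lt(res2$p[res2$haplotype == "AB"], 0.001)
})

test_that("pairwise LD covers complete, absent and intermediate regimes", {
  # complete LD
  blk <- list(list(snps = default_meta(c("a", "b")),
                   haplotypes = c("AA", "BB"), freqs = c(0.6, 0.4)))
  p <- simulate_genotypes(cohort_config(blocks = blk, n_cases = 200,
                                        n_controls = 200, missing_rate = 0,
                                        seed = 26))
  ld <- pairwise_ld(p, "a", "b")
  expect_equal(ld$d_prime, 1, tolerance = 1e-6)

  # multiplicative pool -> D = 0
  expect_equal(ld_from_pool(c(0.35, 0.35, 0.15, 0.15))$d, 0)
  expect_equal(ld_from_pool(c(0.35, 0.35, 0.15, 0.15))$d_prime, 0)

  # hand computation: symmetric coupling pool
  hand <- ld_from_pool(c(0.40, 0.10, 0.10, 0.40))
  expect_equal(hand$d, 0.15)
  expect_equal(hand$d_prime, 0.600)
  expect_equal(hand$r2, 0.36)

  mono <- make_panel(cbind(rep(0L, 10), sample(0:2, 10, replace = TRUE)),
                     rep(c("case", "control"), 5))
  expect_error(pairwise_ld(mono, "s1", "s2"), "monomorphic")
})

test_that("LD matrices are symmetric, complete and block-structured", {
  cfg <- cohort_config(seed = 27, missing_rate = 0)
  p <- simulate_cohort(cfg)
  snps3 <- c("rs2948694", "rs572169", "rs2922126")
  m <- ld_matrix(p, snps3)
  expect_equal(nrow(m), 3L)
  ab <- pairwise_ld(p, "rs572169", "rs2922126")
  ba <- pairwise_ld(p, "rs2922126", "rs572169")
  expect_equal(ab$d_prime, ba$d_prime, tolerance = 1e-9)
  expect_equal(ab$r2, ba$r2, tolerance = 1e-9)

  full <- ld_matrix(p)
  expect_equal(nrow(full), 15L)
  # the monomorphic SNP is flagged, not dropped
  expect_true(any(grepl("monomorphic", full$note)))
  # estimated pairs satisfy 0 <= r2 <= D' <= 1
  est <- full[full$note == "", ]
  expect_true(all(est$r2 >= 0 & est$r2 <= est$d_prime + 1e-9 &
                    est$d_prime <= 1 + 1e-9))

  # two coupled 2-SNP blocks at common frequencies: within-block D' is
  # high, between-block D' hovers near zero
  mk_block <- function(ids) list(snps = default_meta(ids),
                                 haplotypes = c("AA", "AB", "BA", "BB"),
                                 freqs = c(0.40, 0.10, 0.10, 0.40))
  cfg2 <- cohort_config(blocks = list(mk_block(c("a1", "a2")),
                                      mk_block(c("b1", "b2"))),
                        n_cases = 500, n_controls = 500,
                        missing_rate = 0, seed = 28)
  p2 <- simulate_genotypes(cfg2)
  full2 <- ld_matrix(p2)
  within <- full2$d_prime[(full2$snp_a == "a1" & full2$snp_b == "a2") |
                            (full2$snp_a == "b1" & full2$snp_b == "b2")]
  between <- full2$d_prime[substr(full2$snp_a, 1, 1) !=
                             substr(full2$snp_b, 1, 1)]
  expect_gt(min(within), 0.4)
  expect_lt(max(between), 0.2)
})
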