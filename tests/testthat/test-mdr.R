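# independent slow-path oracle for one fold: build the cell table with
# string keys and explicit loops, label, and score both parts
naive_fold_ba <- function(panel, combo, train, test) {
  g <- panel$genotypes[, combo, drop = FALSE]
  key <- apply(g, 1, function(r) if (anyNA(r)) NA else paste(r, collapse = "/"))
  y <- panel$phenotype == "case"
  tr <- train & !is.na(key); te <- test & !is.na(key)
  ca <- tapply(y[tr], key[tr], sum)
  tot <- tapply(y[tr], key[tr], length)
  co <- tot - ca
  thr <- sum(ca) / sum(co)
  high_cells <- names(ca)[ifelse(co > 0, ca / co >= thr, ca > 0)]
  ba <- function(idx) {
    pred_case <- key[idx] %in% high_cells
    sens <- mean(pred_case[y[idx]])
    spec <- mean(!pred_case[!y[idx]])
    (sens + spec) / 2
  }
  c(train = ba(which(tr)), test = ba(which(te)))
}

test_that("cell tables count complete-data individuals per genotype cell", {
  g <- matrix(c(0L, 0L, 1L, 0L, 1L, 1L), ncol = 1)
  p <- make_panel(g, c("case", "case", "case", "control", "control", "control"))
  ct <- cell_counts(p, "s1")
  expect_equal(ct$cases[1:2], c(2L, 1L))
  expect_equal(ct$controls[1:2], c(1L, 2L))
  expect_equal(ct$threshold, 1.0)

  g2 <- cbind(sample(0:2, 30, TRUE), sample(0:2, 30, TRUE))
  p2 <- make_panel(g2, rep(c("case", "control"), 15))
  ct2 <- cell_counts(p2, c("s1", "s2"))
  expect_equal(length(ct2$cases), 9L)

  # an individual missing one combo SNP leaves only its own cell
  g3 <- g2; g3[1, 1] <- NA
  p3 <- make_panel(g3, rep(c("case", "control"), 15))
  ct3 <- cell_counts(p3, c("s1", "s2"))
  expect_equal(sum(ct2$cases) - sum(ct3$cases), 1L)
  expect_error(cell_counts(make_panel(matrix(NA_integer_, 4, 1),
                                      rep(c("case", "control"), 2)), "s1"),
               "empty-table")
})

test_that("cell classification follows the threshold and empty-cell policy", {
  ct <- list(combo = "s1", tuples = cell_tuples <- matrix(0:2, 3, 1),
             cases = c(10L, 0L, 3L), controls = c(2L, 0L, 7L),
             threshold = 1.26, n_case = 13L, n_control = 9L)
  class(ct) <- "cell_table"
  m <- classify_cells(ct)
  expect_true(m$high[1])             # 10/2 = 5 >= 1.26
  expect_false(m$high[2])            # unseen -> low by default
  expect_false(m$high[3])            # 3/7 < 1.26
  ct$controls[1] <- 0L
  expect_true(classify_cells(ct)$high[1])   # cases with zero controls -> high

  # tie exactly at threshold goes high
  ct2 <- ct; ct2$cases <- c(5L, 1L, 1L); ct2$controls <- c(4L, 1L, 1L)
  ct2$threshold <- 1.25
  expect_true(classify_cells(ct2)$high[1])
})

test_that("balanced accuracy matches the hand-worked confusion matrix", {
  # single SNP, cells 0 (high) and 1 (low): sens 0.8, spec 0.6 -> BA 0.7
  g <- matrix(c(rep(0L, 8), rep(1L, 2),        # cases: 8 in high, 2 in low
                rep(0L, 4), rep(1L, 6)), ncol = 1)
  p <- make_panel(g, c(rep("case", 10), rep("control", 10)))
  model <- structure(list(combo = "s1", high = c(TRUE, FALSE, FALSE),
                          seen = c(TRUE, TRUE, FALSE), unseen = "low",
                          threshold = 1, cases = c(8L, 2L, 0L),
                          controls = c(4L, 6L, 0L)),
                     class = "mdr_risk_model")
  expect_equal(balanced_accuracy(model, p), 0.7)
  only_cases <- subset_samples(p, p$phenotype == "case")
  expect_warning(ba <- balanced_accuracy(model, only_cases), "undefined")
  expect_true(is.na(ba))

  perfect <- structure(list(combo = "s1", high = c(TRUE, FALSE, FALSE),
                            seen = c(TRUE, TRUE, FALSE), unseen = "low",
                            threshold = 1, cases = c(10L, 0L, 0L),
                            controls = c(0L, 10L, 0L)),
                       class = "mdr_risk_model")
  psep <- make_panel(matrix(c(rep(0L, 10), rep(1L, 10)), ncol = 1),
                     c(rep("case", 10), rep("control", 10)))
  expect_equal(balanced_accuracy(perfect, psep), 1.0)
})

test_that("cross-validation matches an independent slow implementation", {
  set.seed(31)
  for (rep in 1:3) {
    g <- cbind(sample(0:2, 80, TRUE), sample(0:2, 80, TRUE),
               sample(0:2, 80, TRUE))
    g[sample(length(g), 6)] <- NA
    p <- make_panel(g, sample(rep(c("case", "control"), 40)))
    cv <- cross_validate(p, c("s1", "s3"), folds = 5, seed = rep)
    folds <- snpcc:::stratified_folds(p$phenotype == "case", 5, seed = rep)
    for (f in 1:5) {
      oracle <- naive_fold_ba(p, c("s1", "s3"), folds != f, folds == f)
      expect_equal(cv$folds$training_ba[f], unname(oracle["train"]),
                   tolerance = 1e-12)
      expect_equal(cv$folds$testing_ba[f], unname(oracle["test"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("fold assignment is stratified, seeded, and shared", {
  p <- null_panel(32)
  f1 <- snpcc:::stratified_folds(p$phenotype == "case", 10, seed = 5)
  f2 <- snpcc:::stratified_folds(p$phenotype == "case", 10, seed = 5)
  expect_identical(f1, f2)
  per_fold_cases <- table(f1[p$phenotype == "case"])
  expect_true(max(per_fold_cases) - min(per_fold_cases) <= 1)
  cv1 <- cross_validate(p, c("s1", "s2"), seed = 5)
  cv2 <- cross_validate(p, c("s1", "s2"), seed = 5)
  expect_identical(cv1$folds, cv2$folds)
})

test_that("training BA is >= 0.5 by construction; testing BA is not", {
  set.seed(33)
  tested_below <- FALSE
  for (rep in 1:10) {
    g <- cbind(sample(0:2, 60, TRUE), sample(0:2, 60, TRUE))
    p <- make_panel(g, sample(rep(c("case", "control"), 30)))
    cv <- cross_validate(p, c("s1", "s2"), folds = 5, seed = rep)
    expect_true(all(cv$folds$training_ba >= 0.5 - 1e-12))
    if (any(cv$folds$testing_ba < 0.5)) tested_below <- TRUE
  }
  expect_true(tested_below)
})

test_that("exhaustive search enumerates combos and finds planted signals", {
  p <- xor_panel(34)
  s <- mdr_search(p, k_range = 1:2, seed = 34)
  expect_equal(nrow(s$models[[1]]), 6L)
  expect_equal(nrow(s$models[[2]]), 15L)
  expect_setequal(s$best$combo, c("s1", "s2"))
  expect_gte(s$best$cvc, 8L)
  expect_gt(s$best$testing_ba, 0.6)

  # a fully penetrant single SNP gives a perfect k=1 model
  g <- matrix(c(rep(2L, 30), rep(0L, 30)), ncol = 1)
  g <- cbind(g, sample(0:2, 60, TRUE))
  pp <- make_panel(g, c(rep("case", 30), rep("control", 30)))
  sp <- mdr_search(pp, k_range = 1, seed = 1)
  expect_equal(sp$best$combo, "s1")
  expect_equal(sp$best$testing_ba, 1.0)
  expect_equal(sp$best$cvc, 10L)
})

test_that("permutation p-values are bounded, seeded and sane under signal", {
  p <- xor_panel(35)
  pv <- permutation_pvalue(p, n_perm = 99, seed = 35, k_range = 1:2)
  expect_equal(pv, 1 / 100)          # planted signal beats all permutations
  pv2 <- permutation_pvalue(p, n_perm = 99, seed = 35, k_range = 1:2)
  expect_identical(pv, pv2)
  expect_gte(pv, 1 / 100)

  # fixed-combo statistic on an unassociated combo is clearly null
  pnull <- null_panel(36)
  pv3 <- permutation_pvalue(pnull, combo = c("s3", "s4"), n_perm = 99,
                            seed = 36, statistic = "combo")
  expect_gt(pv3, 0.05)
})

test_that("classification metrics cover perfect and degenerate models", {
  psep <- make_panel(matrix(c(rep(2L, 20), rep(0L, 20)), ncol = 1),
                     c(rep("case", 20), rep("control", 20)))
  m <- classify_cells(cell_counts(psep, "s1"))
  cm <- class_metrics(m, psep)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$precision, 1)
  expect_equal(cm$f1, 1)
  expect_equal(cm$mcc, 1)
  expect_equal(cm$pr_auc, 1)

  # F1 from the formula: precision 0.5, sensitivity 0.5 -> 0.5
  g <- matrix(c(rep(0L, 10), rep(1L, 10), rep(0L, 10), rep(1L, 10)), ncol = 1)
  phalf <- make_panel(g, c(rep("case", 20), rep("control", 20)))
  mh <- classify_cells(cell_counts(phalf, "s1"))
  # cells are exactly at threshold -> both high; force one low for the check
  mh$high <- c(TRUE, FALSE, FALSE)
  cmh <- class_metrics(mh, phalf)
  expect_equal(cmh$precision, 0.5)
  expect_equal(cmh$sensitivity, 0.5)
  expect_equal(cmh$f1, 0.5)

  # MCC stays in [-1, 1] across random models
  set.seed(37)
  for (i in 1:10) {
    g <- matrix(sample(0:2, 50, TRUE), ncol = 1)
    pr <- make_panel(g, sample(rep_len(c("case", "control"), 50)))
    cmr <- class_metrics(classify_cells(cell_counts(pr, "s1")), pr)
    expect_true(is.na(cmr$mcc) || (cmr$mcc >= -1 && cmr$mcc <= 1))
  }
})

test_that("average precision of uninformative scores equals prevalence", {
  set.seed(38)
  ap <- replicate(200, {
    score <- rep(stats::runif(10), each = 10)   # 10 distinct score levels
    y <- sample(c(rep(TRUE, 30), rep(FALSE, 70)))
    snpcc:::average_precision(score, y)
  })
  expect_lt(abs(mean(ap) - 0.3), 0.02)
})

test_that("entropy analysis separates synergy from redundancy", {
  # noiseless XOR: strong pairwise synergy, near-zero main effects
  set.seed(39)
  n <- 800
  g1 <- sample(0:2, n, TRUE, prob = c(.25, .5, .25))
  g2 <- sample(0:2, n, TRUE, prob = c(.25, .5, .25))
  y <- ifelse((g1 + g2) %% 2 == 1, "case", "control")
  p <- make_panel(cbind(g1, g2), y)
  rep <- entropy_analysis(p)
  expect_gt(rep$pair_ig$ig_pct[rep$pair_ig$snp_a == "s1" &
                                 rep$pair_ig$snp_b == "s2"], 50)
  expect_lt(rep$main_ig[["s1"]], 2)
  expect_lt(rep$main_ig[["s2"]], 2)

  # duplicating a SNP with a real marginal effect is pure redundancy:
  # the pair adds nothing beyond either copy, interaction IG = -I(A;C)/H(C)
  yd <- ifelse(g1 >= 1, "case", "control")
  pd <- make_panel(cbind(g1, g2, g1), yd)  # s3 duplicates s1
  rd <- entropy_analysis(pd)
  expect_lt(rd$pair_ig$ig_pct[rd$pair_ig$snp_a == "s1" &
                                rd$pair_ig$snp_b == "s3"],
            -0.9 * rd$main_ig[["s1"]])
  expect_gt(rd$main_ig[["s1"]], 10)
  expect_match(rd$newick, "^\\(")

  # class independent of the SNPs: all IG near zero (plug-in bias bound)
  pn <- make_panel(cbind(sample(0:2, 400, TRUE), sample(0:2, 400, TRUE)),
                   sample(rep(c("case", "control"), 200)))
  rn <- entropy_analysis(pn)
  expect_true(all(abs(rn$main_ig) < 2))
  expect_true(all(abs(rn$pair_ig$ig_pct) < 3))

  # constant SNP is excluded from clustering with a note
  pc <- make_panel(cbind(rep(0L, 100), sample(0:2, 100, TRUE),
                         sample(0:2, 100, TRUE)),
                   rep(c("case", "control"), 50))
  rc <- entropy_analysis(pc)
  expect_equal(rc$main_ig[["s1"]], 0)
  expect_match(paste(rc$notes, collapse = " "), "constant")
})
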