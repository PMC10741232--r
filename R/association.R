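#' Hardy-Weinberg equilibrium chi-square test
#'
#' Goodness-of-fit of observed genotype counts against the Hardy-Weinberg
#' proportions (p^2, 2pq, q^2) implied by the observed allele frequencies,
#' on 1 degree of freedom. A monomorphic SNP is in trivial equilibrium
#' (chi-square 0, p = 1).
#'
#' @param counts genotype counts: numeric vector
#'   `c(n_hom_major, n_het, n_hom_minor)` (names optional, order fixed).
#' @param alpha significance level used for the `in_hwe` flag.
#' @return A list of class `hwe_result`: `chi2`, `df` (= 1), `p`, `maf`,
#'   `in_hwe` (`p >= alpha`), `n`.
#' @export
#' @examples
#' hwe_chi_square(c(61, 46, 0))   # heterozygote excess, chi2 ~ 8.02
hwe_chi_square <- function(counts, alpha = 0.05) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L) stop("counts must be (n_hom_major, n_het, n_hom_minor)")
  if (any(counts < 0)) stop("negative genotype counts")
  n <- sum(counts)
  if (n == 0) stop("empty genotype counts")
  q <- (2 * counts[3L] + counts[2L]) / (2 * n)   # minor allele frequency
  p <- 1 - q
  if (q == 0 || q == 1) {
    res <- list(chi2 = 0, df = 1L, p = 1, maf = min(p, q), in_hwe = TRUE, n = n)
    class(res) <- "hwe_result"
    return(res)
  }
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  pval <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = 1L, p = pval, maf = min(p, q),
                 in_hwe = pval >= alpha, n = n),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square: chi2 = %.3f (df 1), p = %.3g, MAF = %.3f, %s\n",
              x$chi2, x$p, x$maf,
              if (x$in_hwe) "in HWE" else "NOT in HWE"))
  invisible(x)
}

#' Exact Hardy-Weinberg test
#'
#' Conditional exact test: the probability of each possible heterozygote
#' count given the observed minor-allele count, summing the probabilities of
#' configurations no more likely than the observed one. Preferable to the
#' chi-square when genotype classes are sparse.
#'
#' @inheritParams hwe_chi_square
#' @return Two-sided exact p-value.
#' @export
hwe_exact <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  n_minor <- 2 * counts[3L] + counts[2L]
  if (n == 0) stop("empty genotype counts")
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # log-probability of each heterozygote count given allele counts
  lp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(hom_maj + 1) - lgamma(h + 1) - lgamma(hom_min + 1) +
      h * log(2)
  }, 0)
  prob <- exp(lp - max(lp)); prob <- prob / sum(prob)
  obs <- prob[match(counts[2L], hets)]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

#' Pooled minor-allele frequency from group allele counts
#'
#' @param cases,controls allele counts `c(n_major, n_minor)` for each group.
#' @return Pooled minor-allele frequency.
#' @export
#' @examples
#' pooled_maf(c(168, 46), c(138, 30))  # ~0.199
pooled_maf <- function(cases, controls) {
  tot <- sum(cases) + sum(controls)
  if (tot == 0) stop("zero pooled allele total")
  (cases[2L] + controls[2L]) / tot
}

as_2x2 <- function(table) {
  tb <- as.numeric(table)
  if (length(tb) != 4L) stop("a 2x2 table requires exactly 4 cells")
  if (any(tb < 0)) stop("negative cell counts")
  # row-major: (a, b) = numerator group exposed/unexposed, (c, d) = reference
  tb
}

#' Odds ratio with Woolf (log-method) confidence interval
#'
#' OR = (a d) / (b c) for the 2x2 table `[a b; c d]`, where row 1 is the
#' numerator group and column 1 the exposure of interest, with the 95% CI
#' `exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and flagged;
#' when an entire margin is zero the estimate is undefined and `NA` is
#' returned.
#'
#' @param table 2x2 counts, row-major `c(a, b, c, d)` or a 2x2 matrix
#'   (rows = groups, columns = exposure yes/no).
#' @param orientation free-text description of the numerator odds, carried
#'   through to reports.
#' @param conf_level confidence level (default 0.95, z = 1.96).
#' @return A list of class `or_estimate`: `oddsratio`, `ci_low`, `ci_high`,
#'   `orientation`, `corrected` (Haldane flag).
#' @export
#' @examples
#' odds_ratio_woolf(c(168, 46, 138, 30))  # 0.794 (0.476-1.325)
odds_ratio_woolf <- function(table, orientation = "group1 exposure odds vs group2",
                             conf_level = 0.95) {
  tb <- as_2x2(table)
  corrected <- FALSE
  margin_zero <- (tb[1] + tb[2] == 0) || (tb[3] + tb[4] == 0) ||
    (tb[1] + tb[3] == 0) || (tb[2] + tb[4] == 0)
  if (margin_zero) {
    return(structure(list(oddsratio = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, orientation = orientation,
                          corrected = FALSE),
                     class = "or_estimate"))
  }
  if (any(tb == 0)) {
    tb <- tb + 0.5
    corrected <- TRUE
  }
  or <- (tb[1] * tb[4]) / (tb[2] * tb[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / tb))
  structure(list(oddsratio = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 orientation = orientation, corrected = corrected),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f)%s [%s]\n", x$oddsratio,
              x$ci_low, x$ci_high,
              if (isTRUE(x$corrected)) " [Haldane +0.5]" else "",
              x$orientation))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' `chi2 = N (ad - bc)^2 / (r1 r2 c1 c2)` on 1 df, without continuity
#' correction. A zero margin makes the statistic undefined; p = 1 is
#' returned with a warning.
#'
#' @inheritParams odds_ratio_woolf
#' @return A list of class `assoc_test`: `statistic`, `p`, `method`.
#' @export
pearson_chi2_2x2 <- function(table) {
  tb <- as_2x2(table)
  n <- sum(tb)
  if (n == 0) stop("empty table")
  r1 <- tb[1] + tb[2]; r2 <- tb[3] + tb[4]
  c1 <- tb[1] + tb[3]; c2 <- tb[2] + tb[4]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("zero margin in 2x2 table; chi-square undefined, returning p = 1")
    return(structure(list(statistic = NA_real_, p = 1, method = "pearson_chi2"),
                     class = "assoc_test"))
  }
  chi2 <- n * (tb[1] * tb[4] - tb[2] * tb[3])^2 / (r1 * r2 * c1 * c2)
  structure(list(statistic = chi2,
                 p = stats::pchisq(chi2, 1L, lower.tail = FALSE),
                 method = "pearson_chi2"),
            class = "assoc_test")
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by summing, over all tables with the observed margins,
#' the hypergeometric probabilities no larger than that of the observed
#' table.
#'
#' @inheritParams odds_ratio_woolf
#' @return A list of class `assoc_test`: `statistic` (`NA`), `p`, `method`.
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as_2x2(table)
  if (any(tb != round(tb))) stop("Fisher exact test requires integer counts")
  a <- tb[1]; b <- tb[2]; c_ <- tb[3]; d <- tb[4]
  r1 <- a + b; c1 <- a + c_; n <- sum(tb)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[match(a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  structure(list(statistic = NA_real_, p = min(p, 1), method = "fisher_exact"),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  if (is.na(x$statistic))
    cat(sprintf("%s: p = %.4g\n", x$method, x$p))
  else
    cat(sprintf("%s: statistic = %.3f, p = %.4g\n", x$method, x$statistic, x$p))
  invisible(x)
}

expected_2x2 <- function(tb) {
  tb <- as_2x2(tb)
  r <- c(tb[1] + tb[2], tb[3] + tb[4])
  cl <- c(tb[1] + tb[3], tb[2] + tb[4])
  outer(r, cl) / sum(tb)
}

# Pearson unless any expected cell is small, then Fisher.
select_test <- function(table, fisher_threshold = 5) {
  if (any(expected_2x2(table) < fisher_threshold)) fisher_exact_2x2(table)
  else pearson_chi2_2x2(table)
}

#' Per-SNP Hardy-Weinberg screen
#'
#' Runs [hwe_chi_square()] for every SNP in one group of a panel.
#'
#' @param panel a [genotype_panel].
#' @param group `"case"`, `"control"` or `"pooled"`.
#' @param alpha flag threshold.
#' @return Data frame: `snp_id`, `group`, `n`, `chi2`, `p`, `maf`, `in_hwe`.
#'   Monomorphic SNPs report `chi2`/`p` as `NA` (no test is meaningful).
#' @export
hwe_screen <- function(panel, group = "pooled", alpha = 0.05) {
  res <- lapply(panel$snps$snp_id, function(s) {
    gc <- genotype_counts(panel, s, group)
    if (sum(gc) == 0)
      return(data.frame(snp_id = s, group = group, n = 0L, chi2 = NA_real_,
                        p = NA_real_, maf = NA_real_, in_hwe = NA))
    h <- hwe_chi_square(gc, alpha)
    mono <- h$maf == 0
    data.frame(snp_id = s, group = group, n = h$n,
               chi2 = if (mono) NA_real_ else h$chi2,
               p = if (mono) NA_real_ else h$p,
               maf = h$maf, in_hwe = h$in_hwe)
  })
  do.call(rbind, res)
}

#' Allelic case-control association for every SNP
#'
#' Builds the per-SNP 2x2 allele table (major/minor by case/control) and
#' reports the odds ratio with Woolf CI plus a Pearson chi-square p-value
#' (Fisher exact when any expected cell falls below `fisher_threshold`).
#' The default orientation reports the odds of carrying the major allele in
#' cases relative to controls.
#'
#' @param panel a [genotype_panel].
#' @param fisher_threshold expected-count threshold that triggers the Fisher
#'   exact test (default 5).
#' @return Data frame with one row per polymorphic SNP: group allele counts,
#'   `oddsratio`, `ci_low`, `ci_high`, `method`, `p`. Monomorphic SNPs are
#'   retained with `NA` statistics.
#' @export
allelic_association <- function(panel, fisher_threshold = 5) {
  res <- lapply(panel$snps$snp_id, function(s) {
    ca <- allele_counts(panel, s, "case")
    co <- allele_counts(panel, s, "control")
    base <- data.frame(snp_id = s,
                       case_major = ca[1L], case_minor = ca[2L],
                       control_major = co[1L], control_minor = co[2L],
                       row.names = NULL)
    if (ca[2L] + co[2L] == 0 || ca[1L] + co[1L] == 0)   # monomorphic
      return(cbind(base, oddsratio = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, method = NA_character_, p = NA_real_))
    tb <- c(ca[1L], ca[2L], co[1L], co[2L])
    or <- odds_ratio_woolf(tb, "odds of major allele, cases vs controls")
    tst <- select_test(tb, fisher_threshold)
    cbind(base, oddsratio = or$oddsratio, ci_low = or$ci_low,
          ci_high = or$ci_high, method = tst$method, p = tst$p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Genotypic case-control association
#'
#' Per-SNP 2x2 comparisons under a chosen genetic model:
#' * `"pairwise"` — each non-reference genotype against the major-allele
#'   homozygote;
#' * `"dominant"` — minor-allele carriers (het + hom minor) vs non-carriers;
#' * `"recessive"` — minor-allele homozygotes vs the rest.
#'
#' The test-selection rule applies Fisher's exact test when any expected
#' cell of the 2x2 is below `fisher_threshold`, Pearson's chi-square
#' otherwise. Monomorphic SNPs are skipped with a note (`NA` statistics).
#'
#' @param panel a [genotype_panel].
#' @param model genetic model, see above.
#' @param fisher_threshold Fisher trigger on expected counts.
#' @return Data frame: `snp_id`, `model`, `comparison`, per-group counts,
#'   `oddsratio`, `ci_low`, `ci_high`, `method`, `p`.
#' @export
genotypic_association <- function(panel,
                                  model = c("pairwise", "dominant", "recessive"),
                                  fisher_threshold = 5) {
  model <- match.arg(model)
  res <- lapply(panel$snps$snp_id, function(s) {
    ca <- genotype_counts(panel, s, "case")
    co <- genotype_counts(panel, s, "control")
    mono <- (ca[2L] + ca[3L] + co[2L] + co[3L]) == 0
    comparisons <- switch(model,
      pairwise = {
        out <- list()
        if (ca[2L] + co[2L] > 0)
          out$het <- list(label = "het vs hom_major",
                          tb = c(ca[2L], ca[1L], co[2L], co[1L]))
        if (ca[3L] + co[3L] > 0)
          out$hom <- list(label = "hom_minor vs hom_major",
                          tb = c(ca[3L], ca[1L], co[3L], co[1L]))
        out
      },
      dominant = list(dom = list(
        label = "carrier vs non-carrier",
        tb = c(ca[2L] + ca[3L], ca[1L], co[2L] + co[3L], co[1L]))),
      recessive = list(rec = list(
        label = "hom_minor vs rest",
        tb = c(ca[3L], ca[1L] + ca[2L], co[3L], co[1L] + co[2L]))))
    if (mono || !length(comparisons))
      return(data.frame(snp_id = s, model = model,
                        comparison = "monomorphic (skipped)",
                        case_n1 = NA_integer_, case_n0 = NA_integer_,
                        control_n1 = NA_integer_, control_n0 = NA_integer_,
                        oddsratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, method = NA_character_,
                        p = NA_real_))
    rows <- lapply(comparisons, function(cmp) {
      tb <- cmp$tb
      or <- odds_ratio_woolf(tb, paste0("odds of ", cmp$label,
                                        ", cases vs controls"))
      tst <- select_test(tb, fisher_threshold)
      data.frame(snp_id = s, model = model, comparison = cmp$label,
                 case_n1 = tb[1L], case_n0 = tb[2L],
                 control_n1 = tb[3L], control_n0 = tb[4L],
                 oddsratio = or$oddsratio, ci_low = or$ci_low,
                 ci_high = or$ci_high, method = tst$method, p = tst$p)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Power of the two-sample proportion test (normal approximation)
#'
#' Two-sided power to detect a difference `delta` between a control
#' proportion `p_control` and a case proportion `p_control + delta`, with
#' `n1` and `n2` observations per group at level `alpha`. Used to check a
#' case-control design's ability to detect a given allele-frequency
#' difference (counts are then alleles, i.e. 2x the sample sizes).
#'
#' @param p_control control-group proportion.
#' @param delta difference in proportions (case minus control).
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level.
#' @return Approximate power in `[0, 1]`; equals `alpha` at `delta = 0`.
#' @export
#' @examples
#' power_two_proportions(0.2, 0.2, 190, 240)  # ~0.99 at allele scale
power_two_proportions <- function(p_control, delta, n1, n2, alpha = 0.05) {
  p1 <- p_control + delta
  p2 <- p_control
  if (p2 <= 0 || p2 >= 1 || p1 <= 0 || p1 >= 1)
    stop("proportions must lie strictly in (0, 1)")
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- stats::qnorm(1 - alpha / 2)
  d <- p1 - p2
  stats::pnorm((d - z * se0) / se1) + stats::pnorm((-d - z * se0) / se1)
}
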