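#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Classical expectation-maximization over latent phase for a block of 2-4
#' SNPs. The E-step assigns each individual's compatible (unordered)
#' haplotype pairs probability proportional to `f_h1 * f_h2` (doubled for
#' heterozygous pairs), summing over all completions of missing genotypes;
#' the M-step sets each frequency to its expected haplotype count divided by
#' twice the number of usable individuals. Frequencies are initialized at
#' the product of single-SNP allele frequencies and iterated until the
#' largest frequency change drops below `tol`. The log-likelihood is
#' non-decreasing across iterations (returned as a trace).
#'
#' Individuals missing more than two of the block's SNPs are excluded;
#' remaining missing genotypes are summed over, not deleted.
#'
#' @param panel a [genotype_panel].
#' @param block character vector of 2-4 SNP ids (ordered as desired for the
#'   haplotype labels).
#' @param group `"pooled"`, `"case"` or `"control"`.
#' @param tol convergence threshold on the max absolute frequency change.
#' @param max_iter iteration cap; non-convergence warns but still returns.
#' @return A list of class `em_result`: `block`, `haplotypes` (allele
#'   strings), `frequencies`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `n_used`.
#' @export
#' @examples
#' p <- simulate_cohort(cohort_config(seed = 7, missing_rate = 0))
#' em_haplotype_freqs(p, c("rs2948694", "rs572169", "rs2922126"))
em_haplotype_freqs <- function(panel, block, group = "pooled",
                               tol = 1e-10, max_iter = 1000L) {
  if (length(block) < 2L || length(block) > 4L)
    stop("block size must be 2-4 SNPs")
  p <- filter_group(panel, group)
  jj <- vapply(block, function(s) match_snp(p, s), 0L)
  g <- p$genotypes[, jj, drop = FALSE]
  g <- g[rowSums(is.na(g)) <= 2L & rowSums(is.na(g)) < length(block), ,
         drop = FALSE]
  if (nrow(g) == 0L)
    stop("estimation error: no usable individuals in group '", group, "'")
  m <- length(block)
  H <- 2L^m
  # haplotype h (1..H) carries minor allele at SNP k iff bit k of h-1 is set
  hap_minor <- t(vapply(seq_len(H) - 1L,
                        function(h) as.integer(bitwAnd(h, 2L^(seq_len(m) - 1L)) > 0L),
                        integer(m)))

  # unordered pairs and their per-SNP dosages
  pair_idx <- which(upper.tri(diag(H), diag = TRUE), arr.ind = TRUE)
  pair_dose <- hap_minor[pair_idx[, 1L], , drop = FALSE] +
               hap_minor[pair_idx[, 2L], , drop = FALSE]
  mult <- ifelse(pair_idx[, 1L] == pair_idx[, 2L], 1, 2)

  # collapse individuals into distinct genotype patterns
  key <- apply(g, 1L, paste, collapse = "/")
  pat <- !duplicated(key)
  pat_g <- g[pat, , drop = FALSE]
  pat_n <- as.numeric(table(key)[key[pat]])
  compat <- lapply(seq_len(nrow(pat_g)), function(i) {
    d <- pat_g[i, ]
    ok <- rep(TRUE, nrow(pair_dose))
    for (k in seq_len(m))
      if (!is.na(d[k])) ok <- ok & pair_dose[, k] == d[k]
    which(ok)
  })

  # init: product of observed allele frequencies, floored to keep the
  # likelihood finite when a completion needs an unobserved allele
  qk <- vapply(seq_len(m), function(k) {
    x <- g[, k]
    called <- sum(!is.na(x))
    if (called == 0) 0 else sum(x, na.rm = TRUE) / (2 * called)
  }, 0)
  f <- apply(hap_minor, 1L, function(h) prod(ifelse(h == 1L, qk, 1 - qk)))
  f <- pmax(f, 1e-9); f <- f / sum(f)

  n_used <- sum(pat_n)
  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pair_p <- mult * f[pair_idx[, 1L]] * f[pair_idx[, 2L]]
    # plain accumulation: fast enough at <=16 haplotypes / <=136 pairs
    counts <- numeric(H)
    ll <- 0
    for (i in seq_along(compat)) {
      idx <- compat[[i]]
      w <- pair_p[idx]
      tot <- sum(w)
      ll <- ll + pat_n[i] * log(tot)
      w <- w / tot * pat_n[i]
      for (r in seq_along(idx)) {
        counts[pair_idx[idx[r], 1L]] <- counts[pair_idx[idx[r], 1L]] + w[r]
        counts[pair_idx[idx[r], 2L]] <- counts[pair_idx[idx[r], 2L]] + w[r]
      }
    }
    loglik_trace <- c(loglik_trace, ll)
    f_new <- counts / (2 * n_used)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations")

  snps <- p$snps[jj, , drop = FALSE]
  labels <- apply(hap_minor, 1L, function(h)
    paste(ifelse(h == 1L, snps$allele_minor, snps$allele_major), collapse = ""))
  structure(list(block = block, haplotypes = labels, frequencies = f,
                 hap_minor = hap_minor, loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace, n_iter = iter,
                 converged = converged, n_used = n_used),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat("<em_result> block ", paste(x$block, collapse = "-"), ": ",
      x$n_used, " individuals, ", x$n_iter, " iterations",
      if (x$converged) " (converged)\n" else " (NOT converged)\n", sep = "")
  ord <- order(-x$frequencies)
  shown <- ord[x$frequencies[ord] > 1e-4]
  for (i in shown)
    cat(sprintf("  %s  %.4f\n", x$haplotypes[i], x$frequencies[i]))
  invisible(x)
}

#' Haplotype case-control association
#'
#' Estimates block haplotype frequencies by EM separately in the pooled
#' sample, cases and controls, and tests each haplotype (this-haplotype vs
#' all others) with a Pearson chi-square on expected chromosome counts
#' (group frequency times 2n usable individuals). Haplotypes below the
#' reporting threshold are omitted; rows are ordered by descending pooled
#' frequency.
#'
#' @param panel a [genotype_panel].
#' @param block character vector of 2-4 SNP ids.
#' @param threshold minimum pooled frequency reported (default 0.001).
#' @return Data frame: `haplotype`, `freq_pooled`, `freq_case`,
#'   `freq_control`, `chi2`, `p`.
#' @export
haplotype_association <- function(panel, block, threshold = 0.001) {
  em_all <- em_haplotype_freqs(panel, block, "pooled")
  em_ca <- em_haplotype_freqs(panel, block, "case")
  em_co <- em_haplotype_freqs(panel, block, "control")
  keep <- which(em_all$frequencies >= threshold)
  keep <- keep[order(-em_all$frequencies[keep])]
  rows <- lapply(keep, function(i) {
    fca <- em_ca$frequencies[i]; fco <- em_co$frequencies[i]
    tb <- c(2 * em_ca$n_used * fca, 2 * em_ca$n_used * (1 - fca),
            2 * em_co$n_used * fco, 2 * em_co$n_used * (1 - fco))
    tst <- if (all(tb > 0) || any(tb[c(1, 3)] > 0)) pearson_chi2_2x2(tb)
           else list(statistic = NA_real_, p = NA_real_)
    data.frame(haplotype = em_all$haplotypes[i],
               freq_pooled = em_all$frequencies[i],
               freq_case = fca, freq_control = fco,
               chi2 = tst$statistic, p = tst$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ld_from_two_locus <- function(p11, q1, q2) {
  # q1, q2: allele-1 frequencies at the two loci; p11 their joint frequency
  d <- p11 - q1 * q2
  if (q1 <= 0 || q1 >= 1 || q2 <= 0 || q2 >= 1)
    stop("LD undefined error: monomorphic locus")
  d_max <- if (d > 0) min(q1 * (1 - q2), (1 - q1) * q2)
           else if (d < 0) min(q1 * q2, (1 - q1) * (1 - q2))
           else 1
  list(d = d,
       d_prime = abs(d) / d_max,
       r2 = d^2 / (q1 * (1 - q1) * q2 * (1 - q2)))
}

#' Linkage disequilibrium implied by a two-locus haplotype pool
#'
#' Closed-form D, D' and r-squared for a haplotype frequency vector given
#' in the order (AB, Ab, aB, ab), where A/B are the allele-1 labels at the
#' two loci.
#'
#' @param freqs numeric vector of length 4 summing to 1, order
#'   `c(AB, Ab, aB, ab)`.
#' @return List with `d`, `d_prime`, `r2`.
#' @export
#' @examples
#' ld_from_pool(c(0.40, 0.10, 0.10, 0.40))  # D' = 0.6, r2 = 0.36
ld_from_pool <- function(freqs) {
  if (length(freqs) != 4L || abs(sum(freqs) - 1) > 1e-9)
    stop("freqs must be 4 haplotype frequencies summing to 1")
  ld_from_two_locus(freqs[1L], freqs[1L] + freqs[2L], freqs[1L] + freqs[3L])
}

#' Pairwise linkage disequilibrium between two panel SNPs
#'
#' Two-locus haplotype frequencies are estimated by [em_haplotype_freqs()]
#' and converted to `D = p_AB - p_A p_B`, the range-normalized `|D'|`, and
#' `r2`. Alleles are oriented to the minor allele at each locus (D's sign
#' refers to minor-minor coupling; `d_prime` is reported as an absolute
#' value, as in conventional LD plots).
#'
#' @param panel a [genotype_panel].
#' @param snp_a,snp_b SNP ids.
#' @param group `"pooled"` (default), `"case"` or `"control"`.
#' @return A list of class `ld_result`: `snp_a`, `snp_b`, `d`, `d_prime`,
#'   `r2`.
#' @export
pairwise_ld <- function(panel, snp_a, snp_b, group = "pooled") {
  em <- em_haplotype_freqs(panel, c(snp_a, snp_b), group)
  # hap_minor rows: (0,0), (1,0), (0,1), (1,1) over (snp_a, snp_b)
  p11 <- em$frequencies[em$hap_minor[, 1L] == 1L & em$hap_minor[, 2L] == 1L]
  q1 <- sum(em$frequencies[em$hap_minor[, 1L] == 1L])
  q2 <- sum(em$frequencies[em$hap_minor[, 2L] == 1L])
  ld <- ld_from_two_locus(p11, q1, q2)
  structure(c(list(snp_a = snp_a, snp_b = snp_b), ld), class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD %s ~ %s: D = %.4f, D' = %.3f, r2 = %.3f\n",
              x$snp_a, x$snp_b, x$d, x$d_prime, x$r2))
  invisible(x)
}

#' Pairwise LD over a set of SNPs
#'
#' Upper-triangle report of [pairwise_ld()] for every SNP pair. Pairs for
#' which LD is undefined (a monomorphic locus) are flagged in the `note`
#' column rather than dropped; the relation is symmetric, so each unordered
#' pair appears once.
#'
#' @param panel a [genotype_panel].
#' @param snps SNP ids (default: all panel SNPs).
#' @param group `"pooled"`, `"case"` or `"control"`.
#' @return Data frame: `snp_a`, `snp_b`, `d`, `d_prime`, `r2`, `note`.
#' @export
ld_matrix <- function(panel, snps = panel$snps$snp_id, group = "pooled") {
  if (length(snps) < 2L) stop("need at least 2 SNPs")
  pairs <- utils::combn(snps, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    res <- tryCatch(pairwise_ld(panel, a, b, group), error = function(e) e)
    if (inherits(res, "error"))
      data.frame(snp_a = a, snp_b = b, d = NA_real_, d_prime = NA_real_,
                 r2 = NA_real_, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      data.frame(snp_a = a, snp_b = b, d = res$d, d_prime = res$d_prime,
                 r2 = res$r2, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
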