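#' Reference cohort summary counts (GHRL/GHSR prostate-cancer panel)
#'
#' Marginal genotype counts for a published-style candidate-gene panel:
#' 120 sporadic prostate-cancer cases and 95 healthy controls typed at six
#' SNPs in the ghrelin gene *GHRL* (rs34911341, rs696217, rs4684677;
#' 3p25.3) and the ghrelin-receptor gene *GHSR* (rs2922126, rs572169,
#' rs2948694; 3q26.31). Only marginal per-SNP counts are available (the
#' individual-level joint genotypes are not), so per-SNP statistics — MAF,
#' HWE, allelic and genotypic odds ratios — are exactly determined while
#' haplotype/LD/MDR quantities are not. Per-SNP totals differ because
#' genotyping success varied by assay (call rates roughly 0.88-0.97).
#'
#' @return A list: `snps` (metadata data frame), `genotype_counts` (data
#'   frame `snp_id`, `group`, `n_hom_major`, `n_het`, `n_hom_minor`),
#'   `n_cases`, `n_controls`.
#' @export
reference_counts <- function() {
  snps <- data.frame(
    snp_id = c("rs34911341", "rs696217", "rs4684677",
               "rs2922126", "rs572169", "rs2948694"),
    chrom = "3",
    pos = c(10289835L, 10289773L, 10286769L,
            172449471L, 172447937L, 172447373L),
    allele_major = c("C", "G", "A", "A", "C", "A"),
    allele_minor = c("T", "T", "G", "T", "T", "G"),
    stringsAsFactors = FALSE)
  gc <- rbind(
    data.frame(snp_id = "rs34911341", group = "control",
               n_hom_major = 85L, n_het = 0L, n_hom_minor = 0L),
    data.frame(snp_id = "rs34911341", group = "case",
               n_hom_major = 100L, n_het = 0L, n_hom_minor = 0L),
    data.frame(snp_id = "rs696217", group = "control",
               n_hom_major = 54L, n_het = 30L, n_hom_minor = 0L),
    data.frame(snp_id = "rs696217", group = "case",
               n_hom_major = 61L, n_het = 46L, n_hom_minor = 0L),
    data.frame(snp_id = "rs4684677", group = "control",
               n_hom_major = 85L, n_het = 1L, n_hom_minor = 0L),
    data.frame(snp_id = "rs4684677", group = "case",
               n_hom_major = 103L, n_het = 1L, n_hom_minor = 0L),
    data.frame(snp_id = "rs2922126", group = "control",
               n_hom_major = 31L, n_het = 56L, n_hom_minor = 0L),
    data.frame(snp_id = "rs2922126", group = "case",
               n_hom_major = 36L, n_het = 78L, n_hom_minor = 6L),
    data.frame(snp_id = "rs572169", group = "control",
               n_hom_major = 38L, n_het = 42L, n_hom_minor = 0L),
    data.frame(snp_id = "rs572169", group = "case",
               n_hom_major = 45L, n_het = 57L, n_hom_minor = 0L),
    data.frame(snp_id = "rs2948694", group = "control",
               n_hom_major = 82L, n_het = 3L, n_hom_minor = 0L),
    data.frame(snp_id = "rs2948694", group = "case",
               n_hom_major = 110L, n_het = 9L, n_hom_minor = 0L))
  list(snps = snps, genotype_counts = gc, n_cases = 120L, n_controls = 95L)
}

#' Reconstruct an individual-level panel from marginal genotype counts
#'
#' Builds a [genotype_panel] whose per-SNP, per-group genotype counts
#' exactly equal the input. The joint assignment of genotypes across SNPs
#' is arbitrary (each SNP's codes are independently permuted across the
#' group's samples) but fully determined by `seed`. Samples beyond a SNP's
#' per-group total are set missing at that SNP, which reproduces per-SNP
#' call-rate differences.
#'
#' @param counts data frame with columns `snp_id`, `group` (`"case"` /
#'   `"control"`), `n_hom_major`, `n_het`, `n_hom_minor`.
#' @param n_cases,n_controls group sizes.
#' @param snps optional SNP metadata (as in [genotype_panel]); default
#'   metadata is fabricated from the SNP ids.
#' @param seed integer seed controlling the within-group assignment.
#' @return A [genotype_panel].
#' @export
#' @examples
#' ref <- reference_counts()
#' p <- panel_from_marginal_counts(ref$genotype_counts, ref$n_cases,
#'                                 ref$n_controls, snps = ref$snps, seed = 1)
#' summarize_panel(p)
panel_from_marginal_counts <- function(counts, n_cases, n_controls,
                                       snps = NULL, seed = 1L) {
  counts <- as.data.frame(counts)
  snp_ids <- unique(counts$snp_id)
  if (is.null(snps))
    snps <- data.frame(snp_id = snp_ids, chrom = ".",
                       pos = seq_along(snp_ids),
                       allele_major = "A", allele_minor = "B",
                       stringsAsFactors = FALSE)
  snps <- snps[match(snp_ids, snps$snp_id), , drop = FALSE]
  sizes <- c(control = n_controls, case = n_cases)
  with_seed(seed, {
    cols <- lapply(c("control", "case"), function(grp) {
      size <- sizes[[grp]]
      mat <- matrix(NA_integer_, size, length(snp_ids))
      for (j in seq_along(snp_ids)) {
        row <- counts[counts$snp_id == snp_ids[j] & counts$group == grp, ]
        if (nrow(row) > 1L)
          stop("need at most one count row per SNP and group (",
               snp_ids[j], ", ", grp, ")")
        # absent row = nobody typed in this group at this SNP
        triple <- if (nrow(row) == 0L) c(0L, 0L, 0L)
                  else c(row$n_hom_major, row$n_het, row$n_hom_minor)
        if (any(triple < 0)) stop("negative genotype counts")
        tot <- sum(triple)
        if (tot > size)
          stop("consistency error: ", snp_ids[j], " has ", tot, " ", grp,
               " genotypes but the group size is ", size)
        codes <- c(rep(0L, triple[1L]), rep(1L, triple[2L]),
                   rep(2L, triple[3L]), rep(NA_integer_, size - tot))
        mat[, j] <- codes[sample.int(size)]
      }
      mat
    })
    genotypes <- rbind(cols[[1L]], cols[[2L]])
    genotype_panel(genotypes, snps,
                   c(rep("control", n_controls), rep("case", n_cases)))
  })
}

#' Recompute the per-SNP association tables from the reference counts
#'
#' Reconstructs an individual-level panel from the bundled reference
#' marginal counts ([reference_counts()]) and recomputes every per-SNP
#' quantity the marginals determine: Hardy-Weinberg chi-square per group,
#' pooled MAF, allelic odds ratios with Woolf CIs and Pearson/Fisher
#' p-values, and the genotypic 2x2 comparisons. Rows for monomorphic
#' genotype classes carry `NA` statistics.
#'
#' Note the allelic odds ratios are oriented as the odds of the *major*
#' allele in cases relative to controls, and the genotypic table reports
#' both pairwise comparisons and the dominant (carrier) model.
#'
#' @param seed seed for the (statistically irrelevant) joint genotype
#'   assignment.
#' @return A list of data frames: `hwe`, `maf`, `allelic`, `genotypic`,
#'   `dominant`.
#' @export
reproduce_reference_tables <- function(seed = 1L) {
  ref <- reference_counts()
  panel <- panel_from_marginal_counts(ref$genotype_counts, ref$n_cases,
                                      ref$n_controls, snps = ref$snps,
                                      seed = seed)
  hwe <- rbind(hwe_screen(panel, "control"), hwe_screen(panel, "case"))
  smry <- summarize_panel(panel)
  maf <- data.frame(snp_id = smry$snps$snp_id,
                    call_rate = smry$snps$call_rate,
                    maf = smry$snps$maf)
  list(hwe = hwe,
       maf = maf,
       allelic = allelic_association(panel),
       genotypic = genotypic_association(panel, "pairwise"),
       dominant = genotypic_association(panel, "dominant"),
       genotypic_reference = genotypic_reference_table(panel))
}

# Genotypic comparisons in the reference layout. Orientation varies by row
# (as in the source tables): homozygote-reference rows report the odds of
# the major-allele homozygote against the heterozygote class in cases vs
# controls; the rs2922126 A/A row reports the dominant T-carriage odds and
# its T/T row the Fisher exact test of the rare homozygote.
genotypic_reference_table <- function(panel) {
  cnt <- function(grp, s) genotype_counts(panel, s, grp)
  rows <- list()
  add <- function(snp, label, tb, test = NULL) {
    or <- odds_ratio_woolf(tb, label)
    tst <- if (is.null(test)) select_test(tb) else test
    rows[[length(rows) + 1L]] <<- data.frame(
      snp_id = snp, comparison = label,
      case_n1 = tb[1L], case_n0 = tb[2L],
      control_n1 = tb[3L], control_n0 = tb[4L],
      oddsratio = or$oddsratio, ci_low = or$ci_low, ci_high = or$ci_high,
      method = tst$method, p = tst$p, stringsAsFactors = FALSE)
  }
  ca <- cnt("case", "rs696217"); co <- cnt("control", "rs696217")
  add("rs696217", "hom_major vs het, cases vs controls",
      c(ca[1L], ca[2L], co[1L], co[2L]))
  ca <- cnt("case", "rs4684677"); co <- cnt("control", "rs4684677")
  add("rs4684677", "hom_major vs het, cases vs controls",
      c(ca[1L], ca[2L], co[1L], co[2L]))
  ca <- cnt("case", "rs2922126"); co <- cnt("control", "rs2922126")
  add("rs2922126", "T carrier vs non-carrier, cases vs controls",
      c(ca[2L] + ca[3L], ca[1L], co[2L] + co[3L], co[1L]))
  add("rs2922126", "het vs non-het, controls vs cases",
      c(co[2L], co[1L] + co[3L], ca[2L], ca[1L] + ca[3L]))
  add("rs2922126", "hom_minor vs rest (Fisher)",
      c(ca[3L], ca[1L] + ca[2L], co[3L], co[1L] + co[2L]),
      test = fisher_exact_2x2(c(ca[3L], ca[1L] + ca[2L],
                                co[3L], co[1L] + co[2L])))
  ca <- cnt("case", "rs572169"); co <- cnt("control", "rs572169")
  add("rs572169", "hom_major vs het, cases vs controls",
      c(ca[1L], ca[2L], co[1L], co[2L]))
  ca <- cnt("case", "rs2948694"); co <- cnt("control", "rs2948694")
  add("rs2948694", "hom_major vs het, cases vs controls",
      c(ca[1L], ca[2L], co[1L], co[2L]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
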