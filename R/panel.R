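#' Genotype panel objects
#'
#' A `genotype_panel` holds individual-level biallelic genotypes for a small
#' SNP panel together with case/control labels and (optionally) right-censored
#' survival follow-up. Genotypes are stored as minor-allele dosage codes
#' (0 = homozygous major, 1 = heterozygous, 2 = homozygous minor), with `NA`
#' marking a failed genotyping call. Missing calls are never imputed at
#' construction time; every downstream statistic defines its own handling, so
#' per-SNP denominators may legitimately differ.
#'
#' @param genotypes integer matrix, samples in rows and SNPs in columns, with
#'   values in `{0, 1, 2, NA}`.
#' @param snps data frame of SNP metadata with columns `snp_id`, `chrom`,
#'   `pos` (1-based base-pair coordinate), `allele_major`, `allele_minor`.
#' @param phenotype character or factor of `"control"`/`"case"`, one per sample.
#' @param sample_id optional character vector of sample identifiers.
#' @param time optional numeric follow-up time in months (cases only, or all
#'   samples; never partially within a sample that has an `event` flag).
#' @param event optional integer/logical event indicator (1/TRUE = death,
#'   0/FALSE = censored alive).
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `snps`, `phenotype`, `sample_id`, `time`, `event`.
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2)
#' snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "3", pos = c(100L, 200L),
#'                    allele_major = "G", allele_minor = "T")
#' genotype_panel(g, snps, c("case", "control"))
genotype_panel <- function(genotypes, snps, phenotype, sample_id = NULL,
                           time = NULL, event = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  needed <- c("snp_id", "chrom", "pos", "allele_major", "allele_minor")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols))
    stop("snps metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop("duplicated snp_id in panel metadata")
  if (any(snps$allele_major == snps$allele_minor))
    stop("allele_major must differ from allele_minor")
  if (any(snps$pos <= 0))
    stop("SNP positions must be positive 1-based coordinates")
  if (ncol(genotypes) != nrow(snps))
    stop("genotype matrix has ", ncol(genotypes), " columns but ",
         nrow(snps), " SNPs are described")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype must be defined for every sample")
  if (!all(phenotype %in% c("case", "control")))
    stop("phenotype labels must be 'case' or 'control'")
  phenotype <- factor(phenotype, levels = c("control", "case"))
  if (is.null(sample_id)) {
    sample_id <- if (!is.null(rownames(genotypes))) rownames(genotypes)
                 else sprintf("S%04d", seq_len(nrow(genotypes)))
  }
  if (anyDuplicated(sample_id)) stop("duplicated sample ids")
  if (xor(is.null(time), is.null(event)))
    stop("survival fields must be given together (time and event) or not at all")
  if (!is.null(time)) {
    if (length(time) != nrow(genotypes) || length(event) != nrow(genotypes))
      stop("time/event must have one entry per sample (NA where not followed)")
    if (any(stats::na.omit(time) < 0)) stop("negative survival time")
    # a sample has either both fields or neither
    if (any(is.na(time) != is.na(event)))
      stop("time and event must be NA for exactly the same samples")
    event <- as.integer(event)
  }
  dimnames(genotypes) <- list(sample_id, snps$snp_id)
  structure(list(genotypes = genotypes, snps = snps, phenotype = phenotype,
                 sample_id = sample_id, time = time, event = event),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", n_samples(x), " samples (",
      n_cases(x), " cases / ", n_controls(x), " controls), ",
      n_snps(x), " SNPs\n", sep = "")
  cat("  SNPs: ", paste(x$snps$snp_id, collapse = ", "), "\n", sep = "")
  if (!is.null(x$time))
    cat("  survival follow-up on ", sum(!is.na(x$time)), " samples\n", sep = "")
  invisible(x)
}

#' @rdname genotype_panel
#' @param panel a `genotype_panel`.
#' @export
n_samples <- function(panel) nrow(panel$genotypes)

#' @rdname genotype_panel
#' @export
n_snps <- function(panel) nrow(panel$snps)

#' @rdname genotype_panel
#' @export
n_cases <- function(panel) sum(panel$phenotype == "case")

#' @rdname genotype_panel
#' @export
n_controls <- function(panel) sum(panel$phenotype == "control")

#' Subset a panel by sample
#'
#' @param panel a `genotype_panel`.
#' @param i logical or integer sample index.
#' @return A `genotype_panel` restricted to the selected samples.
#' @export
subset_samples <- function(panel, i) {
  genotype_panel(panel$genotypes[i, , drop = FALSE], panel$snps,
                 as.character(panel$phenotype)[i], panel$sample_id[i],
                 time = panel$time[i], event = panel$event[i])
}

#' Select samples belonging to one phenotype group
#'
#' @param panel a `genotype_panel`.
#' @param group `"case"`, `"control"` or `"pooled"`.
#' @return A `genotype_panel` (unchanged for `"pooled"`).
#' @export
filter_group <- function(panel, group = c("pooled", "case", "control")) {
  group <- match.arg(group)
  if (group == "pooled") return(panel)
  subset_samples(panel, panel$phenotype == group)
}

#' Per-SNP genotype counts for one group
#'
#' Counts of the three dosage classes among non-missing calls.
#'
#' @param panel a `genotype_panel`.
#' @param snp a SNP id present in the panel.
#' @param group `"case"`, `"control"` or `"pooled"`.
#' @return Named integer vector `c(n_hom_major, n_het, n_hom_minor)`.
#' @export
genotype_counts <- function(panel, snp, group = "pooled") {
  p <- filter_group(panel, group)
  g <- p$genotypes[, match_snp(p, snp)]
  c(n_hom_major = sum(g == 0L, na.rm = TRUE),
    n_het       = sum(g == 1L, na.rm = TRUE),
    n_hom_minor = sum(g == 2L, na.rm = TRUE))
}

#' Per-SNP allele counts for one group
#'
#' Major/minor allele counts derived from non-missing genotypes (two alleles
#' per called genotype).
#'
#' @inheritParams genotype_counts
#' @return Named integer vector `c(n_major, n_minor)`.
#' @export
allele_counts <- function(panel, snp, group = "pooled") {
  gc <- genotype_counts(panel, snp, group)
  c(n_major = unname(2L * gc[1L] + gc[2L]),
    n_minor = unname(2L * gc[3L] + gc[2L]))
}

match_snp <- function(panel, snp) {
  j <- match(snp, panel$snps$snp_id)
  if (is.na(j)) stop("SNP '", snp, "' not present in panel")
  j
}

#' Summarize a genotype panel
#'
#' Cohort-level summary: group sizes plus per-SNP call rate and pooled
#' minor-allele frequency. The MAF is computed over the pooled non-missing
#' alleles of both groups; a SNP that is monomorphic simply reports MAF 0.
#'
#' @param panel a `genotype_panel`.
#' @return A `cohort_summary`: list with `n_cases`, `n_controls` and a data
#'   frame `snps` holding `snp_id`, `call_rate`, `maf`.
#' @export
#' @examples
#' p <- simulate_cohort(cohort_config(seed = 1))
#' summarize_panel(p)
summarize_panel <- function(panel) {
  if (n_samples(panel) == 0L || n_snps(panel) == 0L)
    stop("cannot summarize an empty panel")
  g <- panel$genotypes
  called <- colSums(!is.na(g))
  call_rate <- called / nrow(g)
  minor <- colSums(g, na.rm = TRUE)          # dosage sum = minor allele count
  maf <- ifelse(called > 0, minor / (2 * called), NA_real_)
  structure(list(
    n_cases = n_cases(panel), n_controls = n_controls(panel),
    snps = data.frame(snp_id = panel$snps$snp_id,
                      call_rate = unname(call_rate), maf = unname(maf),
                      stringsAsFactors = FALSE)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n_cases, " cases / ", x$n_controls,
      " controls\n", sep = "")
  print(transform(x$snps, call_rate = round(call_rate, 3), maf = round(maf, 3)))
  invisible(x)
}

# evaluate code under a fixed RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
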