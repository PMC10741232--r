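# shared fixture builders (all data generated in code)

default_meta <- function(ids, major = "A", minor = "B") {
  data.frame(snp_id = ids, chrom = "1", pos = seq_along(ids) * 1000L,
             allele_major = rep_len(major, length(ids)),
             allele_minor = rep_len(minor, length(ids)),
             stringsAsFactors = FALSE)
}

make_panel <- function(genotypes, phenotype, snps = NULL, ...) {
  genotypes <- as.matrix(genotypes)
  if (is.null(snps))
    snps <- default_meta(paste0("s", seq_len(ncol(genotypes))))
  genotype_panel(genotypes, snps, phenotype, ...)
}

# one independent biallelic SNP per block at the given MAFs
single_snp_blocks <- function(ids, mafs, major = "A", minor = "B") {
  lapply(seq_along(ids), function(i) {
    list(snps = default_meta(ids[i], major, minor),
         haplotypes = c(major, minor),
         freqs = c(1 - mafs[i], mafs[i]))
  })
}

# 6-SNP panel: loci s1/s2 at MAF 0.5 (XOR pair), 4 noise SNPs at MAF 0.3
xor_study_blocks <- function() {
  single_snp_blocks(paste0("s", 1:6), c(0.5, 0.5, 0.3, 0.3, 0.3, 0.3))
}

xor_panel <- function(seed, n_cases = 200, n_controls = 200,
                      baseline = 0.05, effect = 0.25) {
  cfg <- cohort_config(blocks = xor_study_blocks(),
                       n_cases = n_cases, n_controls = n_controls,
                       penetrance = make_xor_penetrance(c("s1", "s2"),
                                                        baseline, effect),
                       missing_rate = 0, seed = seed)
  simulate_case_control(cfg)
}

null_panel <- function(seed, n_cases = 200, n_controls = 200) {
  cfg <- cohort_config(blocks = xor_study_blocks(), n_cases = n_cases,
                       n_controls = n_controls, missing_rate = 0,
                       seed = seed)
  simulate_genotypes(cfg)
}

# GHSR-like 3-SNP haplotype pool used for recovery checks
ghsr_pool_block <- function() {
  list(snps = data.frame(snp_id = c("h1", "h2", "h3"), chrom = "3",
                         pos = c(100L, 200L, 300L),
                         allele_major = c("A", "C", "A"),
                         allele_minor = c("G", "T", "T"),
                         stringsAsFactors = FALSE),
       haplotypes = c("ACA", "ATT", "ACT", "ATA", "GTA", "GCT"),
       freqs = c(0.587, 0.211, 0.121, 0.048, 0.018, 0.015))
}
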