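#' Synthetic cohort configuration
#'
#' Describes the generating process for a synthetic case-control genotype
#' panel: mutually independent haplotype blocks (within-block LD fully
#' specified by each block's haplotype pool), cohort sizes, an optional
#' penetrance-table disease model, per-genotype missingness, and
#' right-censored survival for cases. The defaults emulate the reference
#' cohort: 120 cases / 95 controls typed at six SNPs in two 3-SNP blocks
#' (*GHRL*: rs34911341/rs696217/rs4684677; *GHSR*:
#' rs2948694/rs572169/rs2922126) whose pools reproduce the reference
#' marginal minor-allele frequencies (0.000, 0.199, 0.005, 0.032, 0.275,
#' 0.353), a 5% genotype failure rate, no disease model (the reference
#' study's single-SNP findings are null), and a case hazard sized to yield
#' about 19 deaths among 120 cases over a 60-month window.
#'
#' @param blocks list of blocks; each block is a list with `snps` (metadata
#'   data frame as in [genotype_panel]), `haplotypes` (allele strings, one
#'   character per block SNP) and `freqs` (probabilities summing to 1).
#' @param n_cases,n_controls cohort sizes.
#' @param penetrance optional penetrance model (see [make_xor_penetrance()]).
#' @param missing_rate per-genotype missingness probability in `[0, 1)`.
#' @param censor_time administrative censoring horizon in months.
#' @param hazard per-month event rate(s) for cases: a single baseline rate,
#'   or a list `list(snp =, rates = c(\code{"0"}=, \code{"1"}=, \code{"2"}=),
#'   baseline =)` for genotype-dependent hazards.
#' @param seed integer seed; mandatory for any stochastic stage.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(blocks = default_blocks(),
                          n_cases = 120L, n_controls = 95L,
                          penetrance = NULL, missing_rate = 0.05,
                          censor_time = 60, hazard = 0.00287,
                          seed = NULL) {
  for (b in blocks) {
    if (abs(sum(b$freqs) - 1) > 1e-12)
      stop("config error: block haplotype frequencies must sum to 1 (got ",
           format(sum(b$freqs), digits = 15), ")")
    if (any(nchar(b$haplotypes) != nrow(b$snps)))
      stop("config error: haplotype strings must have one allele per block SNP")
    if (length(b$haplotypes) != length(b$freqs))
      stop("config error: one frequency per haplotype required")
  }
  if (missing_rate < 0 || missing_rate >= 1)
    stop("config error: missing_rate must lie in [0, 1)")
  structure(list(blocks = blocks, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 penetrance = penetrance, missing_rate = missing_rate,
                 censor_time = censor_time, hazard = hazard, seed = seed),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_blocks <- function() {
  ghrl_snps <- data.frame(
    snp_id = c("rs34911341", "rs696217", "rs4684677"),
    chrom = "3", pos = c(10289835L, 10289773L, 10286769L),
    allele_major = c("C", "G", "A"), allele_minor = c("T", "T", "G"),
    stringsAsFactors = FALSE)
  ghsr_snps <- data.frame(
    snp_id = c("rs2948694", "rs572169", "rs2922126"),
    chrom = "3", pos = c(172447373L, 172447937L, 172449471L),
    allele_major = c("A", "C", "A"), allele_minor = c("G", "T", "T"),
    stringsAsFactors = FALSE)
  list(
    list(snps = ghrl_snps,
         haplotypes = c("CGA", "CTA", "CGG"),
         freqs = c(0.798, 0.197, 0.005)),
    list(snps = ghsr_snps,
         haplotypes = c("ACA", "ATT", "ACT", "ATA", "GTA", "GCT"),
         freqs = c(0.587, 0.211, 0.121, 0.048, 0.018, 0.015)))
}

block_minor_matrix <- function(block) {
  # haplotype x snp indicator of carrying the minor allele
  chars <- do.call(rbind, strsplit(block$haplotypes, ""))
  ok <- t(t(chars) == block$snps$allele_major) |
        t(t(chars) == block$snps$allele_minor)
  if (!all(ok))
    stop("config error: haplotype allele not among the SNP's two alleles")
  t(t(chars) == block$snps$allele_minor) * 1L
}

draw_block_dosages <- function(block, n) {
  ind <- block_minor_matrix(block)
  h1 <- sample.int(length(block$freqs), n, replace = TRUE, prob = block$freqs)
  h2 <- sample.int(length(block$freqs), n, replace = TRUE, prob = block$freqs)
  ind[h1, , drop = FALSE] + ind[h2, , drop = FALSE]
}

#' Simulate genotypes for a cohort
#'
#' Each individual draws two haplotypes per block, independently from the
#' block's pool, blocks being mutually independent; genotypes are
#' minor-allele dosage codes. Without a disease model the case/control
#' labels are exchangeable, so the first `n_controls` individuals are
#' labelled controls and the rest cases.
#'
#' @param config a [cohort_config()].
#' @param n number of individuals (default `n_cases + n_controls`).
#' @param seed overrides `config$seed`.
#' @return A [genotype_panel] (no missingness or survival; see
#'   [simulate_cohort()] for the full generator).
#' @export
simulate_genotypes <- function(config, n = NULL, seed = config$seed) {
  if (is.null(seed)) stop("config error: a seed is required for simulation")
  if (is.null(n)) n <- config$n_cases + config$n_controls
  with_seed(seed, simulate_genotypes_impl(config, n,
                                          c(rep("control", min(config$n_controls, n)),
                                            rep("case", max(0L, n - config$n_controls)))))
}

simulate_genotypes_impl <- function(config, n, phenotype) {
  mats <- lapply(config$blocks, draw_block_dosages, n = n)
  genotypes <- do.call(cbind, mats)
  snps <- do.call(rbind, lapply(config$blocks, `[[`, "snps"))
  genotype_panel(genotypes, snps, phenotype,
                 sample_id = sprintf("S%05d", seq_len(n)))
}

#' Pure-epistasis (XOR-parity) two-locus penetrance model
#'
#' Builds a 3x3 penetrance table over the dosage codes of two loci in which
#' cells whose two dosages have opposite parity carry `baseline + effect`
#' and all other cells `baseline`. When both loci have allele frequency
#' 0.5 (Hardy-Weinberg genotype weights 1/4, 1/2, 1/4) the per-locus
#' marginal penetrance is `baseline + effect/2` for every single-locus
#' genotype — a pure interaction with no marginal single-locus effect.
#'
#' @param loci character vector of two distinct SNP ids.
#' @param baseline disease probability of the low-risk cells.
#' @param effect increment carried by the high-risk cells;
#'   `baseline + effect` must lie in `[0, 1]`.
#' @return A list of class `penetrance_model`: `loci`, `table` (3x3 matrix,
#'   rows = dosage at locus 1, cols = locus 2), `baseline`.
#' @export
#' @examples
#' make_xor_penetrance(c("rs1", "rs2"), baseline = 0.05, effect = 0.25)
make_xor_penetrance <- function(loci, baseline, effect) {
  if (length(loci) != 2L || loci[1L] == loci[2L])
    stop("config error: two distinct loci required")
  if (baseline < 0 || baseline > 1 || baseline + effect < 0 ||
      baseline + effect > 1)
    stop("config error: penetrances must lie in [0, 1]")
  d <- 0:2
  tab <- outer(d, d, function(a, b) baseline + effect * ((a + b) %% 2))
  dimnames(tab) <- list(locus1 = d, locus2 = d)
  structure(list(loci = loci, table = tab, baseline = baseline),
            class = "penetrance_model")
}

# disease probability per individual; any missing dosage -> baseline
penetrance_of <- function(model, panel) {
  d1 <- panel$genotypes[, match_snp(panel, model$loci[1L])]
  d2 <- panel$genotypes[, match_snp(panel, model$loci[2L])]
  p <- rep(model$baseline, n_samples(panel))
  ok <- !is.na(d1) & !is.na(d2)
  p[ok] <- model$table[cbind(d1[ok] + 1L, d2[ok] + 1L)]
  p
}

#' Label a simulated panel by a penetrance model (retrospective sampling)
#'
#' Each individual becomes a case with probability equal to the penetrance
#' of their multi-locus genotype; the labelled pool is then sampled down to
#' exactly `n_cases` cases and `n_controls` controls (retrospective
#' case-control design). Individuals beyond the quotas are dropped. If the
#' pool cannot satisfy a quota an error is raised — pass a generously sized
#' panel (see [simulate_case_control()] for the batch-until-quota driver).
#'
#' @param panel a [genotype_panel] serving as the population pool.
#' @param model a `penetrance_model`.
#' @param n_cases,n_controls required group sizes.
#' @param seed integer seed.
#' @return A [genotype_panel] with exactly `n_cases + n_controls` samples.
#' @export
assign_phenotype <- function(panel, model, n_cases, n_controls, seed) {
  with_seed(seed, {
    p <- penetrance_of(model, panel)
    is_case <- stats::runif(length(p)) < p
    ci <- which(is_case); ki <- which(!is_case)
    if (length(ci) < n_cases || length(ki) < n_controls)
      stop("unsatisfiable error: pool yielded ", length(ci), " cases / ",
           length(ki), " controls; need ", n_cases, " / ", n_controls)
    keep <- c(ki[seq_len(n_controls)], ci[seq_len(n_cases)])
    out <- subset_samples(panel, keep)
    out$phenotype <- factor(c(rep("control", n_controls),
                              rep("case", n_cases)),
                            levels = c("control", "case"))
    out
  })
}

#' Simulate a case-control cohort under a penetrance model
#'
#' Batch rejection sampler: population individuals are generated from the
#' config's haplotype pools, labelled by Bernoulli(penetrance), and
#' accumulated until both group quotas are met. Exact by construction; the
#' number of attempts is bounded.
#'
#' @param config a [cohort_config()] whose `penetrance` is non-`NULL`.
#' @param seed overrides `config$seed`.
#' @param batch population batch size per attempt.
#' @param max_batches bound on attempts before declaring the model
#'   unsatisfiable.
#' @return A [genotype_panel] with `config$n_cases` cases and
#'   `config$n_controls` controls (controls first).
#' @export
simulate_case_control <- function(config, seed = config$seed,
                                  batch = 1000L, max_batches = 1000L) {
  if (is.null(config$penetrance))
    stop("config error: simulate_case_control requires a penetrance model")
  if (is.null(seed)) stop("config error: a seed is required for simulation")
  with_seed(seed, {
    case_rows <- list(); ctrl_rows <- list()
    n_case <- 0L; n_ctrl <- 0L
    snps <- do.call(rbind, lapply(config$blocks, `[[`, "snps"))
    for (i in seq_len(max_batches)) {
      g <- do.call(cbind, lapply(config$blocks, draw_block_dosages, n = batch))
      pnl <- genotype_panel(g, snps, rep("control", batch),
                            sample_id = sprintf("B%dI%05d", i, seq_len(batch)))
      p <- penetrance_of(config$penetrance, pnl)
      is_case <- stats::runif(batch) < p
      if (n_case < config$n_cases && any(is_case))
        case_rows <- c(case_rows, list(g[is_case, , drop = FALSE]))
      if (n_ctrl < config$n_controls && any(!is_case))
        ctrl_rows <- c(ctrl_rows, list(g[!is_case, , drop = FALSE]))
      n_case <- sum(vapply(case_rows, nrow, 0L))
      n_ctrl <- sum(vapply(ctrl_rows, nrow, 0L))
      if (n_case >= config$n_cases && n_ctrl >= config$n_controls) break
    }
    if (n_case < config$n_cases || n_ctrl < config$n_controls)
      stop("unsatisfiable error: quotas not met after ", max_batches,
           " batches (", n_case, " cases / ", n_ctrl, " controls)")
    g <- rbind(do.call(rbind, ctrl_rows)[seq_len(config$n_controls), , drop = FALSE],
               do.call(rbind, case_rows)[seq_len(config$n_cases), , drop = FALSE])
    genotype_panel(g, snps,
                   c(rep("control", config$n_controls),
                     rep("case", config$n_cases)),
                   sample_id = sprintf("S%05d", seq_len(nrow(g))))
  })
}

#' Attach exponential survival times to the cases of a panel
#'
#' Event times are exponential with a per-individual monthly rate looked up
#' from the genotype at one SNP (or a single shared rate); times beyond
#' `censor_time` are administratively censored at `censor_time`. Controls
#' receive no follow-up (`NA`). An individual missing the hazard genotype
#' gets the baseline rate rather than being dropped.
#'
#' @param panel a [genotype_panel].
#' @param hazard a single positive rate per month, or a list
#'   `list(snp =, rates = c("0" =, "1" =, "2" =), baseline =)`.
#' @param censor_time administrative censoring horizon in months.
#' @param seed integer seed.
#' @return The panel with `time`/`event` filled in for cases.
#' @export
simulate_survival <- function(panel, hazard, censor_time = 60, seed) {
  with_seed(seed, {
    idx <- which(panel$phenotype == "case")
    rate <- rep(NA_real_, n_samples(panel))
    if (is.list(hazard)) {
      g <- panel$genotypes[, match_snp(panel, hazard$snp)]
      r <- hazard$rates[as.character(g[idx])]
      r[is.na(r)] <- hazard$baseline
      rate[idx] <- r
    } else rate[idx] <- hazard
    if (any(rate[idx] <= 0)) stop("hazard rates must be positive")
    time <- rep(NA_real_, n_samples(panel))
    event <- rep(NA_integer_, n_samples(panel))
    t_raw <- stats::rexp(length(idx), rate[idx])
    event[idx] <- as.integer(t_raw <= censor_time)
    time[idx] <- pmin(t_raw, censor_time)
    panel$time <- time
    panel$event <- event
    panel
  })
}

#' Randomly mask genotypes as missing
#'
#' Each genotype call is independently set missing with probability `rate`;
#' labels and survival fields are untouched.
#'
#' @param panel a [genotype_panel].
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The masked panel.
#' @export
inject_missingness <- function(panel, rate, seed) {
  if (rate < 0 || rate >= 1) stop("missingness rate must lie in [0, 1)")
  if (rate == 0) return(panel)
  with_seed(seed, {
    mask <- matrix(stats::runif(length(panel$genotypes)) < rate,
                   nrow(panel$genotypes))
    panel$genotypes[mask] <- NA_integer_
    panel
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generator: block-LD genotypes (with retrospective
#' case-control sampling when a penetrance model is configured), genotype
#' missingness, and censored survival for cases. All randomness flows from
#' the single config seed, so identical configs give identical panels.
#'
#' @param config a [cohort_config()].
#' @param seed overrides `config$seed`.
#' @return A [genotype_panel].
#' @export
#' @examples
#' p <- simulate_cohort(cohort_config(seed = 42))
#' summarize_panel(p)
simulate_cohort <- function(config, seed = config$seed) {
  if (is.null(seed)) stop("config error: a seed is required for simulation")
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max, 3L)
    panel <- if (is.null(config$penetrance))
      simulate_genotypes(config, seed = s[1L])
    else simulate_case_control(config, seed = s[1L])
    if (config$missing_rate > 0)
      panel <- inject_missingness(panel, config$missing_rate, seed = s[2L])
    simulate_survival(panel, config$hazard, config$censor_time, seed = s[3L])
  })
}

#' Read / write a cohort config as YAML
#'
#' The YAML file doubles as the simulation truth record: haplotype pools,
#' penetrance model, hazards, cohort sizes and seed.
#'
#' @param path file path.
#' @param config a [cohort_config()].
#' @return `read_cohort_config()` returns a [cohort_config()];
#'   `write_cohort_config()` invisibly returns the path.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  blocks <- lapply(y$blocks, function(b)
    list(snps = as.data.frame(b$snps, stringsAsFactors = FALSE),
         haplotypes = unlist(b$haplotypes),
         freqs = as.numeric(unlist(b$freqs))))
  pen <- NULL
  if (!is.null(y$penetrance)) {
    pen <- make_xor_penetrance(unlist(y$penetrance$loci),
                               y$penetrance$baseline, 0)
    pen$table <- matrix(as.numeric(unlist(y$penetrance$table)), 3L, 3L,
                        dimnames = list(locus1 = 0:2, locus2 = 0:2))
  }
  hazard <- if (is.list(y$hazard))
    list(snp = y$hazard$snp,
         rates = stats::setNames(as.numeric(unlist(y$hazard$rates)),
                                 names(y$hazard$rates)),
         baseline = y$hazard$baseline)
  else y$hazard
  cohort_config(blocks = blocks, n_cases = y$n_cases,
                n_controls = y$n_controls, penetrance = pen,
                missing_rate = y$missing_rate, censor_time = y$censor_time,
                hazard = hazard, seed = y$seed)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  y <- list(
    blocks = lapply(config$blocks, function(b)
      list(snps = as.list(b$snps), haplotypes = as.list(b$haplotypes),
           freqs = as.list(b$freqs))),
    n_cases = config$n_cases, n_controls = config$n_controls,
    missing_rate = config$missing_rate, censor_time = config$censor_time,
    hazard = config$hazard, seed = config$seed)
  if (!is.null(config$penetrance))
    y$penetrance <- list(loci = as.list(config$penetrance$loci),
                         baseline = config$penetrance$baseline,
                         table = as.numeric(config$penetrance$table))
  yaml::write_yaml(y, path)
  invisible(path)
}
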