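---
title: "Candidate-gene case-control analysis with snpcc: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene case-control analysis with snpcc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcc)
```

# Scope

`snpcc` implements the complete statistical pipeline used in small
candidate-gene case-control studies of a handful of SNPs — the setting of a
ghrelin-system (*GHRL*/*GHSR*) prostate-cancer panel with 120 cases, 95
controls and six markers, which the package's bundled reference counts and
generator defaults emulate. The stages are:

1. single-SNP statistics: Hardy-Weinberg equilibrium (HWE), minor-allele
   frequencies, allelic and genotypic odds ratios with Woolf confidence
   intervals, Pearson chi-square or Fisher exact tests;
2. haplotype-frequency estimation by EM from unphased genotypes, haplotype
   case-control tests, and pairwise linkage disequilibrium (D, D', r²);
3. multifactor dimensionality reduction (MDR) for gene-gene interaction,
   with cross-validation consistency, permutation significance,
   classification metrics and entropy-based interaction maps;
4. Kaplan-Meier survival by genotype with log-rank comparison;
5. a synthetic-cohort generator that gives every stage a ground-truth test
   bed.

The statistical core (HWE, odds ratios, exact test, EM, LD, MDR, entropy,
KM/log-rank) is implemented in the package rather than delegated, so each
formula is visible, testable against independent oracles, and exactly the
one described here.

# Single-SNP association

Genotypes are coded as minor-allele dosage 0/1/2, the minor allele being
the rarer allele in the pooled sample (ties broken lexicographically). One
coding convention serves MAF computation, dominant/recessive models and
MDR cells alike. Missing calls are a distinct state and are never imputed:
each statistic defines its own denominator, which is why per-SNP sample
sizes differ in real panels with variable assay success.

*HWE.* `hwe_chi_square()` compares observed genotype counts with
$n(p^2, 2pq, q^2)$ on 1 df. A monomorphic SNP is reported as trivially in
equilibrium. `hwe_exact()` offers the conditional exact test for sparse
genotype classes.

*Odds ratios.* `odds_ratio_woolf()` uses the log (Woolf) interval
$\exp(\ln \widehat{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$. This choice
is validated in the test suite by exact reproduction of reference
confidence bounds (e.g. 1.325 and 19.497) from the bundled counts. A zero
cell triggers the Haldane-Anscombe +0.5 correction with a flag; a zero
margin yields `NA`. Orientation is always carried as text because
published tables are not consistent about which odds sit in the numerator;
`reproduce_reference_tables()` encodes per-row orientations explicitly.

*Test selection.* Pearson's chi-square (no continuity correction) is the
default; Fisher's exact test replaces it when any expected cell falls
below 5. The threshold is an argument (`fisher_threshold`) because the
trigger convention varies between software packages; 5 is the classical
rule. The exact p-value is the min-likelihood two-sided sum. Note a
discreteness fact checked in the tests: exact and chi-square p-values
track each other closely in the rejection region, but in the far-null
region the exact p can sit above the asymptotic one by roughly the size of
a hypergeometric atom, so "agreement" is only asserted where decisions are
made (p ≤ 0.5) and at large counts.

*Power.* `power_two_proportions()` is the standard two-sided normal
approximation with null-pooled variance, reducing exactly to α at zero
difference. For allelic designs the inputs are chromosome counts (2n).

# Haplotypes and LD

`em_haplotype_freqs()` is a plain EM over latent phase for blocks of 2-4
SNPs (at most 16 haplotypes). Partition-ligation staging, multi-restart
schemes and individual-level phasing are deliberately out of scope: at
this block size the likelihood surface is small enough that the standard
EM initialized at allele-frequency products is reliable, and the test
suite compares it against an exhaustive grid-search maximizer. Convergence
is declared when the largest frequency change drops below `tol = 1e-10`
(default cap 1000 iterations) — a deliberately strict setting chosen so
results are bit-reproducible across platforms; occasional non-convergence
warnings at this tolerance are benign (frequency changes are then at the
1e-9 scale). The log-likelihood trace is returned and asserted
non-decreasing in tests.

Missing genotypes are summed over all compatible completions in the
E-step rather than deleted listwise, matching panels whose call rates
differ by SNP; individuals missing more than two block SNPs carry
essentially no phase information and are excluded.

Haplotype association uses expected chromosome counts (group EM frequency
× 2n usable individuals) in a per-haplotype 2×2 chi-square, reported in
descending pooled frequency with a 0.001 reporting floor — low enough to
expose rare haplotypes (reference tables list down to 0.015) without
noise. LD statistics follow the conventional definitions
$D = p_{AB} - p_A p_B$, $D' = |D|/D_{max}$, $r^2 = D^2/(p_A p_a p_B p_b)$,
computed from the EM two-locus frequencies on the pooled sample by default
(a group filter is available; published LD figures rarely state which
sample they use). $D'$ is reported as an absolute value, with the sign
available in `d`.

# MDR

`mdr_search()` enumerates every k-locus combination, pools each
combination's 3^k genotype cells into high/low risk by comparing the cell
case:control ratio with the ratio among individuals entering the table
(the canonical threshold for unbalanced designs — about 120:95 here, not
1:1), and scores models by balanced accuracy under stratified 10-fold
cross-validation. Deterministic conventions, each of which some MDR
implementations vary, are fixed and documented: ties at the threshold are
high risk; cells unseen in training default to low risk at test time (an
`"exclude"` policy is available); folds are fixed by one seed and shared
across all combinations so model comparisons are paired; CVC counts the
folds in which a combination is its size's best by training balanced
accuracy; the overall winner maximizes testing balanced accuracy with ties
broken by higher CVC, then fewer loci. Reported testing accuracy is the
across-fold average.

The permutation p-value attached to the best model re-runs the entire
search on every permuted label vector and compares the observed best
testing accuracy with the permutation distribution of the *maximum*
testing accuracy. This choice matters: permuting labels for a single,
already-selected combination ignores the selection over all C(6,k) models
and is anti-conservative — under the null it would flag a "best" model far
more often than the nominal rate, while the search-wide statistic is
calibrated (the acceptance checks measure both the false-positive rate and
the near-uniformity of the null p). The fixed-combo statistic remains
available via `permutation_pvalue(statistic = "combo")` for assessing one
pre-specified combination. The default `n_perm = 1000` resolves p-values
to 0.001 at desk runtime; claims at the 1e-4 scale need 9999 or more.

Classification metrics (`class_metrics()`) use standard definitions on
whole-data predictions; PR-AUC is average precision with step
interpolation over the distinct values of the cell case-proportion score,
avoiding both optimistic linear interpolation and within-tie ordering
artifacts. MCC is the standard matthews coefficient and is bounded by
[-1, 1] — a reported value outside that range in any source is
definitionally impossible and not a reproduction target.

Entropy analysis uses plug-in entropies (log base 2) on complete-data
individuals, expressed as percent of the class entropy H(C): main effect
$I(A;C)/H(C)$ and pairwise interaction information
$[I(A,B;C) - I(A;C) - I(B;C)]/H(C)$, positive for synergy and negative for
redundancy. Plug-in estimates are biased upward at small n (a few tenths
of a percent at n ≈ 400); no bias correction is applied, matching the
convention of the MDR ecosystem, and tests allow for the bias bound. The
dendrogram applies average-linkage clustering to
$1 - |II|/\max|II|$ and is serialized as Newick.

# Survival

`km_estimate()` and `log_rank()` are the textbook product-limit estimator
(deaths processed before censorings at tied times; Greenwood standard
errors) and the unweighted Mantel-Cox statistic. `survival_by_genotype()`
partitions cases by genotype, applies administrative censoring at 60
months (the design's follow-up window), reports monomorphic partitions
without a test, and notes empty genotype groups instead of failing. Both
functions are cross-checked against the `survival` package in the test
suite, and the log-rank null distribution is additionally checked against
a permutation reference.

# The synthetic cohort generator

`simulate_cohort()` draws, for each individual, two haplotypes per block
from configured pools (blocks mutually independent — matching a two-gene
panel on separate chromosome arms), then applies optional missingness and
exponential survival with administrative censoring. All randomness flows
from a single integer seed.

Defaults are the reference study conditions: 120 cases / 95 controls; two
3-SNP blocks whose pools are the published block haplotype tables
completed to sum to one (*GHRL*: CGA 0.798, CTA 0.197, CGG 0.005 over
rs34911341/rs696217/rs4684677; *GHSR*: ACA 0.587, ATT 0.211, ACT 0.121,
ATA 0.048, GTA 0.018, GCT 0.015 over rs2948694/rs572169/rs2922126), which
reproduce the published marginal MAFs (0.000, 0.199, 0.005, 0.032, 0.275,
0.353); a 5% genotype failure rate (assay success "over 90%", observed
call rates roughly 0.88-0.97); no disease model, since the reference
single-SNP findings are null; and a case hazard of 0.00287 per month,
sized so that a 60-month window yields about 19 deaths among 120 cases,
the reference cohort's death count (its printed percentage, 15.43%, is
inconsistent with that count; the generator targets the count).

Disease models are penetrance tables. `make_xor_penetrance()` builds the
canonical pure-epistasis table: cells whose two dosages have opposite
parity carry `baseline + effect`. At MAF 0.5 each locus's marginal
penetrance is `baseline + effect/2` for every genotype, so single-locus
tests see nothing while the two-locus MDR model sees everything — the
ground truth used for the package's power checks. Case-control sampling
is retrospective by batch rejection (exact group quotas, bounded
attempts), preferring exactness over speed at desk scale.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: population structure and covariates,
genotyping error (as opposed to missingness), linkage *between* blocks,
recombination within blocks, and informative censoring. The published
between-SNP D' values (0.190 / 0.600 / 0.08) come from individual-level
data that are not deposited, so synthetic LD targets bracket those regimes
rather than match them.

# Problem sizes used in validation

The package's acceptance checks (see `scripts/acceptance.R`) use problem
sizes chosen to make simulation error small relative to each assertion
band while staying desk-fast: EM recovery at n = 1000 individuals × 50
seeds (mean absolute frequency error, band < 0.02); empirical LD at 2000
individuals against the closed form; MDR power over 20 replicates of the
200/200 XOR design; MDR calibration over 100 null replicates at the same
scale with 99 permutations each (99 suffices to decide p > 0.05; the
reported rate band is ≥ 90%); and 2000 null replicates each for the
allelic-test and log-rank type-I error (band [0.035, 0.065] at α = 0.05,
i.e. ±3 binomial SEs around 0.05 plus discreteness slack). The null
calibration runs at 200/200 rather than 120/95 to share the power study's
scale; selection over 21 models inflates the best model's mean testing
balanced accuracy to about 0.56 under the null, which is the expected
order for the maximum of ~21 correlated centered statistics and well
inside the [0.42, 0.58] acceptance band.

# Known limitations

* Blocks are capped at 4 SNPs for EM; larger blocks need partition-ligation
  or sampling approaches out of scope here.
* No covariate adjustment anywhere (the reference design reports
  unadjusted 2×2 measures); no Cox regression; no trend tests.
* MDR is the classical balanced-accuracy variant; model-based extensions
  (GMDR, MB-MDR) are not implemented.
* Multiple-testing correction is off by default (matching the reference
  analysis); `stats::p.adjust` can be applied to any reported p column.
* The exact per-SNP denominators of the bundled reference counts were
  reconstructed from published marginal tables whose layout is partly
  garbled for one SNP; the reconstruction is the one consistent with the
  published allele counts and odds ratio.
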