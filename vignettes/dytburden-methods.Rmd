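---
title: "Methods: rare-variant prioritization and burden testing of dystonia-related genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant prioritization and burden testing of dystonia-related genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dytburden)
```

## The analysis this package implements

Parkinson's disease (PD) and dystonia overlap clinically and genetically:
dystonia is a common feature of young-onset PD, and parkinsonism appears in
several monogenic dystonias. This package implements a candidate-gene
analysis of rare coding variants in dystonia-related ("DYT") genes within a
PD case-control cohort, built from two complementary strands:

1. **Candidate prioritization** — identify individual patients carrying
   potentially pathogenic variants under the gene's inheritance mode,
   screen them against in-house controls, and grade them with a reduced
   ACMG evidence engine; supported by runs-of-homozygosity (ROH) detection
   for consanguineous probands.
2. **Burden testing** — per-gene SKAT-O association tests between rare
   variant subgroups and case status, adjusted for age, sex, and five
   genetic principal components.

Individual-level genotypes for such studies are typically not deposited, so
the package ships a synthetic cohort generator that emits the exact
interchange formats the analysis consumes (VCF, annotation TSV, sample
TSV), plus small deterministic fixtures that encode the package's worked
examples with decoy variants.

## The gene panel

The shipped panel (`dyt_panel()`) holds 47 autosomal DYT genes: 19 with
autosomal recessive (AR) inheritance, 25 autosomal dominant (AD), and 3
(VPS16, SPR, ADCY5) with both patterns reported. Genes flagged `BOTH`
participate in both prioritization passes, each under its own criteria.
GCH1 is deliberately absent — its variants are conventionally analyzed
separately in these cohorts — but `extra_genes` can append any gene.
Symbols are opaque, case-sensitive join keys; no identifier mapping is
attempted, because silent case-folding or aliasing hides annotation
mismatches rather than fixing them.

Two member genes (CACNA1B, CIZ1) have contested disease associations. The
panel carries no per-gene confidence field; findings in these genes should
be interpreted cautiously downstream, and the panel TSV format makes it
trivial to drop them.

## Variant classification

All definitions operate on an ANNOVAR-style annotation table:

* **Effective MAF** — the maximum of the two gnomAD East-Asian frequency
  fields (exome and genome). Taking the maximum is conservative for
  rarity: a variant common in either source is not rare. When both fields
  are missing the variant is treated as gnomAD-absent (frequency 0), which
  retains novel variants — gnomAD-absent variants are common among real
  candidates, including several in the worked examples.
  The two fields are labelled exome/genome but treated symmetrically; no
  claim is made about which source is which.
* **Loss-of-function (LoF)** — stopgain, stoploss, frameshift, or a
  splicing variant within 2 bp of an exon-intron junction (inclusive).
  A splicing variant without a recorded junction distance is an error, not
  a silent non-LoF. Frameshift status is taken from the annotation's
  consequence token, not re-derived from indel lengths.
* **Damaging missense (Dmis)** — missense with ReVe ≥ 0.7 (inclusive at
  0.7). A missense variant without a ReVe score is not Dmis.
* **Deleterious** — Dmis or LoF.
* **Rarity** — strict `<` comparisons at 0.01 and 0.001 on the effective
  MAF.

The burden scan's variant subgroups are the cells of
{missense, Dmis, LoF, deleterious} × {MAF < 0.01, MAF < 0.001}. The
missense subgroup deliberately ignores pathogenicity scores.

## Candidate prioritization

For each case sample:

* **Recessive model** (AR and BOTH genes): deleterious homozygous variants
  with effective MAF < 0.01, and every unordered pair of distinct
  deleterious heterozygous variants in the same gene, both with
  MAF < 0.01. Phase is not required — compound-heterozygous states are
  putative, matching what short-read data can support without parental
  genotypes. A sample with three qualifying heterozygotes in one gene
  yields three pair findings; pairs are never merged with homozygous
  findings in the same gene.
* **Dominant model** (AD and BOTH genes): deleterious heterozygous
  variants with effective MAF < 0.001. Homozygous states do not qualify.

Sporadic cases enter both models; familial probands enter only the model
matching their family's inheritance (subgroup `FPD_AR` → recessive,
`FPD_AD` → dominant). Missing genotypes are treated as non-carrier —
conservative for candidate calling.

**Control screening.** A dominant finding is excluded if any control
carries the variant at all. A recessive finding is excluded only if a
control is *biallelic*: homozygous for the candidate, or (for a pair)
carrying both members or homozygous for either. Heterozygous-only control
carriage never screens a recessive finding, since healthy heterozygous
carriers of recessive alleles are expected. Screening is monotone: adding
control carriers can only screen more findings.

## The ACMG evidence engine

In practice, variant grades arise from expert judgement; a code path can only
approximate them. The engine is therefore deliberately small and
config-driven (`default_acmg_config()`), with three operationalized
criteria:

| code | weight | default predicate |
|------|--------|-------------------|
| PVS1 | very strong | LoF variant, optionally gated by a per-gene allowlist of genes with an established LoF mechanism |
| PM2 | moderate | effective MAF ≤ 0 and no control carrier |
| PP3 | supporting | ≥ 4 of 7 computational predictors damaging |

The seven predictors are CADD, SIFT, LRT, MutationAssessor,
PolyPhen2-HVAR, PolyPhen2-HDIV, and MutationTaster. The six categorical
tools contribute a damaging call as `D`; CADD contributes when its
phred-scaled score reaches the configurable cutoff (default 20, below
every worked-example candidate's score), so the annotation table needs no
categorical CADD column.

Combining rules: pathogenic (P) requires very-strong plus one moderate;
likely pathogenic (LP) requires very-strong plus one supporting, or one
moderate plus a *context-dependent* number of supporting criteria — one
under the dominant model, two under the recessive model. Everything else
is uncertain significance (US). The context dependence is the engine's one
substantive design choice: a novel, well-supported damaging missense
variant is a credible dominant heterozygous candidate (LP) but the same
evidence in a biallelic recessive context, where carrier frequency
arguments are weaker, stays US. This single rule reproduces every worked
example grade (eight US recessive classifications; one P stopgain and
three LP missense dominant classifications), and it is a config entry, not
a constant, because the underlying expert reasoning is not recoverable
from a set of final grades alone.

The LoF allowlist defaults to "all genes" (PVS1 for any panel LoF
variant); restricting it per gene is how a user expresses "LoF is not an
established mechanism for this gene".

## Runs of homozygosity

`detect_roh()` is a PLINK-style sliding-window scan. Defaults: 50-SNP
windows, at most 1 heterozygous and 5 missing calls per compatible window,
a SNP is marked when ≥ 5% of its overlapping windows are compatible, and
maximal marked runs are reported when they span ≥ 1 Mb and ≥ 50 SNPs.
These are the tool's conventional defaults, declared rather than inferred
— all are config keys. Interval length is end − start of the printed endpoints, which
reproduces the worked example's 5.36 Mb tract arithmetic on chr2 exactly. Chromosomes with fewer SNPs than one window
yield no calls. The scan runs on whatever variant set it is given —
panel-region exome variants in the shipped fixtures, genome-wide input
through the same reader.

## The burden scan

### Null model

Case status is regressed on age, sex (0 = male, 1 = female), and the first
five principal components by logistic IRLS (tolerance 1e-8, 25 iterations).
Samples with missing covariates are dropped with a logged count — no
imputation, because covariate imputation in a case-control design risks
differential bias. Fitted probabilities within 1e-8 of the boundary abort
with a separation error instead of producing a spuriously confident null.

### Statistics

With per-variant scores $S_j = \sum_i G_{ij}(y_i - \hat\mu_i)$ and weights
$w_j$, the family of statistics is

$$Q(\rho) = (1-\rho)\sum_j (w_j S_j)^2 + \rho\Big(\sum_j w_j S_j\Big)^2,
\qquad \rho \in [0,1],$$

the variance-component (SKAT) kernel at $\rho = 0$ and the squared
weighted burden score at $\rho = 1$. Under the null, $Q(\rho)$ is a
weighted sum of 1-df chi-squares whose weights are the eigenvalues of
$R_\rho^{1/2} Z'PZ R_\rho^{1/2}$, with $Z$ the weighted genotypes, $P$ the
projection induced by the null model, and
$R_\rho = (1-\rho)I + \rho\mathbf{1}\mathbf{1}'$.

Tail probabilities use Ruben's expansion: the quadratic form's law is
written as a mixture of central chi-squares with positive weights summing
to one, so truncation error is bounded by the unaccumulated mass
(tolerance 1e-10, at most 5,000 terms). Single or equal eigenvalues are
scaled chi-squares, computed exactly. If the series has not converged
within the term cap — which requires an extreme eigenvalue spread — the
Liu-Tang-Zhang moment-matched noncentral chi-square approximation is the
fallback.

SKAT-O minimizes the per-$\rho$ p-value over the grid
$\{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ (the method's conventional
default, config-overridable) and evaluates the null distribution of the
minimum by one-dimensional integration over the grid's joint
representation: the common chi-square(1) component along the burden
direction plus a moment-matched residual mixture. For the integration
terms $\rho$ is capped at 0.999 to keep the representation non-degenerate;
per-$\rho$ p-values themselves use the exact $\rho$. The combined p-value
is clamped to its Bonferroni bracket
$[\min_\rho p_\rho,\ K\min_\rho p_\rho]$, which the exact min-p
combination must satisfy; `rho_opt` is the grid argmin (first index wins
ties). Single-variant genes collapse: every $\rho$ gives the same
statistic, and the single score-test p is returned directly.

A label-permutation mode (`method = "permutation"`) re-evaluates the
min-p combination against its own permutation distribution. It assumes
exchangeability, i.e. an intercept-only null, and exists as an independent
oracle for testing, not as a production path.

### Scan conventions

* **Rarity** for subgroup cells is evaluated on the *annotation's*
  gnomAD-EAS effective MAF, not the cohort frequency — rarity is defined
  against the reference population. Cohort alt-allele frequency is used
  only for the weights.
* **Weights** default to the Beta(1, 25) density evaluated at the cohort
  MAF (the SKAT convention, emphasizing rarer variants); flat weights are
  a config option.
* **Missing dosages** are mean-imputed per variant within the analyzed
  samples, keeping the score statistic well-defined without dropping
  samples. (Prioritization, by contrast, treats missing as non-carrier —
  the two modules record their policies separately because their error
  trade-offs differ.)
* **Carrier counts** are samples with observed dosage ≥ 1 over the cell's
  variants, invariant to variant order.
* **Cells with zero qualifying variants** are reported untested
  (`p = NA`), which is distinct from `p = 1`.
* **Multiple testing**: the significance threshold divides 0.05 by the
  number of panel genes only (0.05/47 ≈ 0.00106, printed as 0.001), not by
  genes × subgroups. This mirrors the conventional reporting for this
  design and is *anti-conservative* across the eight correlated subgroup
  cells per gene; `suggestive` flags uncorrected p < 0.05.
* The scan requires exactly one case subgroup with its matched control
  group; the pipeline stage runs it separately for each matched sporadic
  pair present (sEOPD vs control group 1, sLOPD vs control group 2).
  Familial probands enter prioritization but not the burden scan.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes: independent biallelic variants in Hardy-Weinberg equilibrium at
rare population frequencies; case status assigned by a logistic model
combining a baseline prevalence, optional covariate effects, and per-gene
log-odds for carriers of deleterious variants; case-control sampling from
the resulting population; annotations drawn consistently (ReVe uniform on
[0.7, 1] for the damaging-missense class and on [0, 0.7) otherwise, so the
configured class mix is the expected Dmis fraction; gnomAD frequency equal
to the simulated population frequency, with a small missingness rate
standing in for novel variants).

Defaults are desk-scale and chosen once: 200 cases / 200 controls, 10
panel genes, 30 variants per gene (comparable to the per-gene rare-variant
loads seen in exome panels of this kind), population frequencies
log-uniform on [1e-4, 5e-3], class mix 45% non-damaging missense / 20%
Dmis / 10% LoF / 25% synonymous, ages normal with mean 43 (early-onset
cohorts; 62 is the late-onset analogue) and SD 8, sex balanced, PCs
standard normal, no confounding, baseline prevalence 0.35 (a case-control
sampling device, not an epidemiological claim). The study-scale subgroup
sizes (1,508 + 1,962 sporadic cases, 153 + 336 familial probands, 1,652 +
1,279 controls) are available from `study_cohort_profile()` for scaled-up
runs.

What the generator does **not** model: linkage disequilibrium, haplotype
phase, sequencing or genotyping error, relatedness, population
substructure beyond the covariate PCs, and divergence between database and
cohort frequencies (the simulated gnomAD frequency *is* the sampling
frequency). Passing tests therefore demonstrate correctness of the
implemented statistics under idealized sampling — not robustness to the
artefacts of real sequencing data.

The worked-example fixtures are single-fault by construction: each decoy
variant violates exactly one filter (common frequency, sub-threshold ReVe,
synonymous consequence, unpaired heterozygote, control biallelic carriage,
3 bp splice distance, off-panel gene, mismatched inheritance mode, missing
ReVe), so a filtering bug surfaces as one localized failure rather than a
diffuse count mismatch.

## Validation design and problem sizes

The shipped tests validate the statistical core at sizes chosen to give
sharp checks at interactive runtimes:

* **Type-I error**: 2,000 null cohorts of n = 500 with 5 rare variants
  (MAF 0.001–0.01) and age/sex/PC covariates; the empirical rejection rate
  at α = 0.05 is required to fall in [0.03, 0.07]. The observed rate sits
  slightly below 0.05, the familiar mild conservatism of kernel score
  tests with very rare variants.
* **Exactness of the tail computation**: chi-square analytic limits and a
  200,000-draw Monte-Carlo oracle for random eigenvalue mixtures.
* **Permutation oracle**: five cohorts of 200 samples × 10 variants,
  10,000 label permutations, agreement required within three Monte-Carlo
  standard errors. The comparison is made in the tail regime (association
  signal present, p ≲ 0.1) — where the test's calls are actually made.
  At central p-values (0.2–0.8) the asymptotic null departs from the
  exact permutation null by up to ~0.02 at this sample size, an expected
  finite-sample gap that small-sample moment adjustments would close;
  implementing those adjustments is out of scope and flagged as a known
  limitation.
* **Power**: the spiked-gene study uses 500 cases / 500 controls, 10
  genes, frequencies log-uniform on [5e-4, 8e-3], and a per-gene carrier
  log-odds of log 8. The spike strength was fixed by a pilot expected-count
  calculation (≈ 35–40 case vs ≈ 6 control carriers of the spiked gene's
  deleterious variants) so that detection power is essentially 1 and the
  check exercises implementation correctness — the spiked gene must attain
  the scan-wide minimum p in ≥ 90% of 50 seeded replicates — rather than
  sitting on a marginal power curve.

## Known limitations

* No small-sample moment adjustment for the SKAT-O null (see above);
  cohort sizes in the intended application are in the hundreds to
  thousands, where the asymptotic null is adequate.
* The Bonferroni divisor ignores the eight subgroup cells per gene
  (anti-conservative), matching the conventional reporting.
* ACMG grading uses three criteria only; segregation, de-novo status, and
  functional evidence are outside the computational pipeline.
* Hemizygous or haploid genotypes are rejected — the panel is autosomal.
* ROH parameters are declared defaults, not values recovered from any
  specific external run.
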