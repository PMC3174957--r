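---
title: "Two-stage integration of cis-eQTL mapping with case-control GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage integration of cis-eQTL mapping with case-control GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlpipe)
```

## The analysis this package implements

`eqtlpipe` implements a two-stage strategy for prioritizing disease
variants with expression data from a modest, case-only cohort:

1. **Stage 1 — cis-eQTL scan.** In a cohort of patients with both
   genome-wide genotypes and probe-level expression from a disease tissue,
   every SNP within a fixed window of a gene's transcription start site
   (TSS) is tested for association with that gene's expression by a
   general linear model

   \[
   y_{ip} = \mu_p + \beta \, g_{is} + \mathbf{c}_i^\top
   \boldsymbol{\alpha} + \varepsilon_{ip},
   \]

   where \(y_{ip}\) is normalized log-scale expression of probe \(p\) in
   sample \(i\), \(g_{is} \in \{0,1,2\}\) the additive dosage at SNP
   \(s\), and \(\mathbf{c}_i\) the covariates (age, sex, and the first
   six genotype ancestry principal components). Raw p-values are adjusted
   once, jointly over all SNP–probe tests, by Benjamini–Hochberg, and
   FDR-adjusted \(p < 0.05\) defines a significant eQTL.

2. **Stage 2 — disease lookup under a reduced multiple-testing burden.**
   Only the unique SNPs among the significant eQTL pairs are tested for
   disease association (logistic regression on additive dosage, adjusted
   for age, pack-years of smoking and ancestry PCs). The Bonferroni
   threshold is \(\alpha / m_{\text{eQTL}}\) — typically three to five
   orders of magnitude more permissive than a genome-wide correction
   over a 550k-SNP chip — which is the entire point of the design: a
   SNP with measurable effects on transcript levels in disease tissue is
   a priori more plausible as a disease variant, so the lookup spends
   its error budget on far fewer tests. Disease evidence comes from two
   parallel routes: a pooled *mega-analysis* (one logistic regression on
   individual-level data across the discovery studies, with
   study-indicator covariates) and a fixed-effects *meta-analysis* of
   per-study fits combined by inverse-variance weighting. SNPs reaching
   nominal \(p < 0.01\) in either route form the candidate set.

3. **Replication.** Candidates are screened sequentially in two
   independent cohorts: pass 1 requires \(p < 0.1\) in the first
   (larger) cohort; pass 2 requires \(p < 0.1\) in the second with
   effect direction consistent across both screens and the discovery
   analysis. Candidates missing from a screen panel are reported as
   untested, never as failures.

4. **Locus dissection.** For a candidate locus, pairwise genotype
   (composite) \(r^2\) is computed among the locus SNPs; SNPs are
   assigned to tag-SNP LD bins (maximal-\(r^2\) tag, core membership at
   \(r^2 \ge 0.80\), moderate-LD sub-bins in \([0.50, 0.80)\)), and a
   per-SNP table joins per-gene eQTL p-values, bin assignments and
   disease p-values. This table supports the key inference pattern:
   when two genes' eQTL SNPs occupy bins that are not in LD with each
   other, the locus plausibly harbours two distinct susceptibility
   genes.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cis_window_bp` | 50,000 | bp | cis definition around the TSS; most regulatory eQTLs fall well inside this; keeps the test count manageable at n≈131 |
| `expanded_window_bp` | 200,000 | bp | rescan window for candidate loci that show nothing at 50 kb |
| `maf_min` | 0.05 | frequency | below this, a 131-sample cohort carries too few minor alleles for a stable linear fit |
| `fdr_alpha` | 0.05 | — | eQTL significance (BH, joint over all pairs) |
| `fwer_alpha` | 0.05 | — | Bonferroni numerator for the reduced-set lookup |
| `nominal_p` | 0.01 | — | candidate threshold in either disease analysis |
| `replication_p` | 0.1 | — | per-cohort screen threshold (liberal by design; the two-cohort-plus-direction conjunction provides the control) |
| `n_pcs` | 6 | — | genotype ancestry adjustment in both stages |
| `ld_bin_r2_min` | 0.80 | \(r^2\) | core bin membership; literature bins built with looser historical thresholds can be supplied externally |
| `moderate_ld_range` | (0.50, 0.80) | \(r^2\) | sub-bins of SNPs related to, but not proxies of, a tag |

## Conventions and numerical choices

- **Coordinates** are 1-based inclusive everywhere (VCF convention).
- **Cis-window boundary** is inclusive (`|pos − tss| ≤ window`), so pair
  counts are well defined; distance is signed and strand-oriented
  (minus-strand genes measure from their transcript's 3'-most genomic
  coordinate).
- **Genotype coding** is additive dosage of the ALT allele at parse time;
  the minor-allele orientation that reported effects use is applied at
  the association layer (`run_gwas()` flips columns whose ALT frequency
  exceeds 0.5 in the analyzed cohort and records the counted allele).
  Doing the flip at analysis rather than parse time keeps file round
  trips exact.
- **Missing data** are handled pairwise-complete per test; the only
  imputation anywhere is per-SNP mean imputation inside the PCA.
- **Logistic fits** use IRLS with deviance tolerance 1e-8 and at most 50
  iterations; the Wald covariance is evaluated at the *converged*
  coefficients (not the one-step-stale QR some implementations reuse),
  so a binary-predictor fit reproduces the closed-form 2×2 log-OR and
  its SE to ~1e-6. Non-convergence or \(|\hat\beta| > 15\) is flagged as
  separation with a missing p-value.
- **Degenerate tests** (zero-variance genotype, rank-deficient design,
  single outcome class) are flagged and carried through output tables;
  they are excluded from the FDR input rather than silently dropped.
- **P-value underflow** is floored at the smallest positive double and
  flagged; the pipeline never reports an exact zero.
- **Meta-analysis**: the default combination is inverse-variance
  weighting on the effect scale; a weighted-Z (Stouffer) alternative is
  exposed via `pipeline_config(meta_method = "stouffer")`. The two agree
  exactly when study SEs are equal and differ only mildly otherwise; IVW
  is the default because it yields a pooled effect estimate, not just a
  z-score.
- **LD** is genotype (composite) \(r^2\) — the squared Pearson
  correlation of dosages — because phase is not part of the data model;
  EM-based haplotype \(r^2\) is out of scope.
- **Bin ties** (a SNP equally correlated with two tags) break toward the
  tag at the smaller genomic position; core and sub-bin membership are
  mutually exclusive by construction.
- **Established hits** (Bonferroni-significant SNPs) are excluded from
  the replication candidate set by default — they are considered already
  established and not retested — with a config switch
  (`exclude_bonferroni_from_replication`) for designs, such as the
  simulation studies below, where no prior reports exist.

## What the synthetic-data generator emulates

`sim_config()` / `generate_study_bundle()` produce, from one master
seed, a shared SNP panel and haplotype pool plus every cohort of the
two-stage design: an expression cohort (default n = 131), discovery
case-control studies (defaults: three studies of 434/44, 210/198 and
92/104 cases/controls — one quarter of the motivating design, so the
combined discovery set is 736 cases and 346 controls) and two
replication studies (246/469 and 124/125). Covariates follow the
clinical moments of a severe-COPD cohort: age ~ N(65, 5.5) years, 66%
male, pack-years ~ N(47, 28) truncated at zero.

Haplotypes come from a *haplotype ladder*: within each block every
haplotype draws one latent founder coordinate \(u \sim U(0,1)\) and
carries the alternate allele at SNP \(j\) iff \(u < p_j\), followed by
an independent per-site mutation (default probability 0.02; frequencies
are mutation-corrected so the realized expectation matches the drawn
target). The ladder gives monotone, controllable LD: SNPs in one block
with equal target frequencies are near-perfect proxies (tag bins), SNPs
with different frequencies sit in moderate LD, and SNPs in different
blocks are independent. This is deliberately simpler than a coalescent:
it is desk-scale, deterministic given the seed, and produces exactly the
tag-bin geometry the locus-dissection stage needs to be tested against.
An optional two-subpopulation mixture (`ancestry_divergence`) creates
the frequency divergence that makes the PC adjustment exercisable;
it is off by default.

Expression is generated as intercept + planted cis effects + covariate
effects + homoscedastic Gaussian noise on a log2-like scale. The noise
model is a stated stand-in, not an inference about real microarray
data: real probe intensities show heteroscedasticity, batch structure
and probe-level artifacts that the generator does not attempt (no RMA
inputs, no batch effects). Passing tests therefore demonstrate that the
*statistics* are implemented correctly and calibrated under the stated
model, not that the pipeline is robust to microarray artifacts.
Disease status follows a logistic liability on dosages and covariates,
with each study's intercept calibrated on its realized cohort so the
expected case fraction matches the design.

Seeding is hierarchical: every component derives a fixed child stream
from the master seed, so adding a stage never perturbs the draws of
earlier stages, and identical configurations give byte-identical
bundles on disk.

## Validation design and problem sizes

The test suite validates each primitive against an independent
brute-force oracle (normal-equations OLS, closed-form 2×2 log-OR,
exhaustive BH step-up, longhand IVW plus a `metafor` fixed-effects
cross-check, brute-force correlation, full eigendecomposition for the
PCs) on hundreds of random fixtures, and validates the pipeline against
planted truth:

- **Null calibration**: a no-effect bundle with ~5,400 cis pairs at
  n = 131 (340 independent SNPs × 20 genes) gives a raw \(p < 0.05\)
  fraction within 3 binomial SEs of 0.05 and passes a KS uniformity
  test; across 100 null bundles the two-stage prioritization passes zero
  SNPs in ≥ 95 runs.
- **Parameter recovery**: a planted cis effect of 0.8 (log2 units per
  allele, n = 131) and a disease log-odds of 0.5 (n = 4,000) are
  recovered without bias over 50 seeds (pooled estimate within two
  pooled SEs; per-seed 2-SE coverage near nominal).
- **End to end**: a single strong planted variant (common SNP, cis
  \(\beta = 1.2\), disease log-odds 0.8 ≈ OR 2.2, in its own haplotype
  block) is the *unique* replicated hit through the complete pipeline in
  ≥ 90% of 50 seeds. The effect sizes define what "strong" means in the
  simulated conditions: a variant worth replicating should survive a
  124-case second screen at \(p < 0.1\).
- **Locus dissection**: on an engineered three-tag locus (three 5-SNP
  blocks, equal within-block frequencies, n = 2,000), bin assignment
  recovers the generating blocks exactly, and two eQTLs planted for
  different genes in different blocks land in different bins with
  cross-bin \(r^2\) well under 0.5.

These problem sizes were chosen so the whole suite runs in a few
minutes on one CPU while keeping every statistical check adequately
powered.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_snps = 60, n_genes = 6, maf_range = c(0.2, 0.5),
  cis_effects = data.frame(snp = 30, probe = NA, beta = 1.2),
  disease_log_odds = c("30" = 0.8),
  master_seed = 1)
bundle <- generate_study_bundle(cfg)
res <- run_pipeline(
  bundle,
  pipeline_config(exclude_bonferroni_from_replication = FALSE),
  out_dir = "pipeline_out")
print(res)
res$replication[res$replication$replicated, ]
```

## Limitations

- No trans-eQTL scanning: at around a hundred expression samples, a
  genome-wide trans search is underpowered and explodes the test count.
- No per-gene permutation p-values, mixed models, kinship correction,
  haplotype phasing, conditional fine-mapping or colocalization
  statistics.
- Family-based replication cohorts are supported only through
  externally supplied per-SNP summary records
  (`read_replication_summaries()`); the package does not implement a
  pedigree association engine.
- The generator does not simulate probe-level intensities, batch
  effects, or recombination within blocks; its LD is blockwise by
  construction.
- On desk-scale panels of a few dozen SNPs, the genotype PCs partially
  absorb individual haplotype-block axes — including a planted
  variant's own block — which mildly inflates association SEs. This is
  a small-panel artifact: on a genome-wide panel each PC reflects
  ancestry, not any single locus. The end-to-end simulations accept
  this power cost rather than dropping the PC adjustment, since the
  adjustment is part of the analysis being validated.
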