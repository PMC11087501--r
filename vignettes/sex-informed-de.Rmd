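---
title: "Sex-informed differential expression and X-dosage analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-informed differential expression and X-dosage analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexdimorph)
```

# Scope

`sexdimorph` implements a sex-informed analysis of bulk RNA-seq count data
from case/control brain cohorts: normalization into TPM and TMM-scaled
log-CPM with voom-style precision weights; differential expression under
four linear designs (sex; sex-by-region; sex-by-diagnosis;
diagnosis-within-sex) with empirical-Bayes moderated statistics and BH FDR;
relative X-chromosome expression (RXE) as a per-sample dosage statistic;
enrichment of sex-biased genes in X-inactivation (XCI) status classes; a
stringent filter isolating sex-specific schizophrenia genes; a
male-subsampling permutation null for DEG counts; and replication statistics
($\pi_1$, effect-size concordance, overlap enrichment) between analyses.

Because cohort data of this kind are access-controlled, the package ships a
synthetic-data generator that emulates the statistical structure these
methods assume. Every procedure is exercised end-to-end against it, with
known ground truth.

# The generator

`simulate_dataset()` draws gamma-Poisson (negative-binomial) counts:
$\mathrm{Var}(y) = \mu + \phi\mu^2$ with dispersion $\phi$ (default 0.1, a
typical bulk-tissue value). On the log2 scale of the NB mean, a gene--sample
entry is

$$\log_2 \mu_{gs} = b_g + \ell_s + \lambda_g h_s + \Delta_{gs},$$

with per-gene baselines $b_g \sim N(\log_2 50,\ 1.5^2)$, per-sample
library-size factors $\ell_s$ (log-normal, $\sigma_{\log} = 0.2$), a hidden
standard-normal batch factor $h_s$ with loadings
$\lambda_g \sim N(0, 0.2^2)$, and planted effects $\Delta_{gs}$:

* **Sex effects.** A fraction (default 2%) of autosomal genes carries a
  male-vs-female log2 fold change of magnitude 1 with random sign.
* **Allosome rules.** Chromosome-Y genes are silent in females. Male
  (non-PAR) X genes sit at the *female inactive-gene baseline* — the
  dosage-compensated state. XCI escape genes are shifted up in females by
  +0.4 log2 (variable-escape genes by a per-gene uniform amount in
  [0, 0.4]); pseudoautosomal (PAR) genes are annotated as escaping and
  expressed equally in both sexes. Non-PAR X genes are split into
  escape/variable/inactive classes at the published catalogue proportions
  (99 : 101 : 431).
* **Diagnosis effects.** A fraction of autosomal genes carries a
  schizophrenia log2FC restricted to configurable sexes and regions,
  emulating sex-specific disease signal.
* **X-dosage shift.** The expression means of all non-PAR X genes are
  multiplied by a factor (default 0.8) in one (sex, diagnosis, region)
  group — by default male schizophrenia cases in the last region —
  emulating a group-restricted loss of X dosage.

The cohort structure is three regions with repeated donors (one sample per
donor per region), unbalanced sexes, ages uniform on 17–80 (the analysis
inclusion window), quality covariates drawn independent standard normal by
default (with an optional confounding loading), and three donor-level
ancestry PCs.

What the generator does **not** emulate: transcript/exon/junction-level
features, correlated quality covariates and their dependence on batch, GC
and length biases, cell-type composition shifts, and outlier samples.
Passing tests therefore demonstrate internal correctness and statistical
calibration of the procedures under a clean NB world, not robustness to
every artefact of real cohort data.

# Normalization

* **Effective length**: gene length $-$ mean fragment length $+ 1$; genes at
  $\le 1$ are unquantifiable at that fragment length and are masked.
* **TPM**: per-sample length-normalized rates rescaled to $10^6$; column
  sums are conserved to within $10^{-9}$ relative error.
* **Low-expression filter**: a gene survives when its CPM reaches the
  threshold (default 10, with a nonzero count) in at least
  $\lceil 0.7 \times \text{smallest group size} \rceil$ samples, counting
  qualifying samples cohort-wide. The ceiling is the conservative reading of
  "70% of the smallest group"; presence additionally requires a nonzero
  count so a zero threshold degenerates to a presence filter rather than a
  no-op.
* **TMM** factors are computed by edgeR's implementation (30% trim on M,
  5% on A, reference = sample whose upper-quartile CPM is closest to the
  cohort mean) and rescaled to geometric mean 1. The test suite checks them
  against a brute-force implementation of the weighted trimmed-mean
  definition.
* **log-CPM** uses a fixed prior count (default 0.5) against the
  TMM-effective library size.
* **Precision weights** follow the voom construction: per-gene least
  squares on log-CPM, a lowess trend (span 0.5) of $\sqrt{\text{residual
  sd}}$ against mean log-CPM, and weight $= \widehat{\sqrt{sd}}^{-4}$ at
  each observation's fitted value. Predictions beyond the trend's range are
  clamped to its endpoints so extreme genes get finite positive weights.

# Designs and inference

Six designs are supported (`design_spec()`), treatment-coded with female and
CTL as references so positive sex coefficients mean male-biased and positive
diagnosis coefficients mean up in schizophrenia. The sex, sex-by-diagnosis,
diagnosis-within-sex, and minimal-null designs carry surrogate-variable
terms; the sex-by-region and diagnosis-only-null designs deliberately do
not, mirroring the modelling choices the designs encode.

**Hidden factors** are principal components of the per-gene residual matrix
after regressing out the full (SV-free) design — estimating them from a
design that omits the contrast would let the first component absorb the
effect under test. The number of factors is chosen by Buja–Eyuboglu
permutation: each gene's residuals are permuted independently (19
permutations) and leading PCs are kept while their add-one permutation
p-value is $\le 0.05$. This residual-PCA construction approximates surrogate
variable analysis without its iterative reweighting; a known consequence,
visible in our own calibration runs, is a slight type-I inflation when weak
latent structure leads the rule to keep noise PCs.

**Covariate screening** correlates each candidate with the top 10 expression
PCs within each sex and keeps candidates with a Bonferroni-significant
correlation (over all candidate × PC × sex tests) in either sex, after
pruning candidates pairwise correlated above $r = 0.95$ (keeping the first).

**Moderated fits** (`fit_moderated()`) are per-gene weighted least squares
with residual variances shrunk toward a common prior:
$\tilde{s}^2_g = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$, with $(s_0^2, d_0)$
estimated by moment-matching a scaled-F distribution across genes (limma's
`squeezeVar`). The moderated t uses $\tilde s^2_g$ with $d + d_0$ degrees of
freedom; multi-column contrasts (sex-by-region across three regions) use a
joint moderated F. The $d_0$ override is part of the contract: $d_0 = 0$
reproduces the ordinary WLS t exactly, $d_0 \to \infty$ pins every variance
at $s_0^2$ — both are asserted in the tests, along with exact agreement with
limma's `lmFit`/`eBayes` route on shared inputs.

**Repeated donors.** The sex-by-region design spans regions with the same
donors. Rather than a random-effects likelihood fit, the package uses
donor-clustered robust (CR1 sandwich) standard errors per gene, with
$n_{\text{clusters}} - 1$ degrees of freedom and no variance moderation in
that path. This targets the same inference at closed form; it is the one
deliberate methodological substitution in the package and is flagged here
for users.

**Residualization** regresses a null design out of each gene and z-scores
the residuals; the two nulls differ in whether diagnosis is retained, so
diagnosis signal survives residualization under the minimal null — the
property the sex-specific filter depends on.

# Dosage statistics

**RXE** is $\log_2(\text{mean TPM over X genes}) - \log_2(\text{mean TPM
over autosomal genes})$ per sample, after dropping genes expressed (TPM $>$
0 — presence is not otherwise defined, so a nonzero reading is used) in
fewer than 20% of samples. The equation form (log of means) is the default;
a mean-of-log variant (`method = "mean_of_log"`, using $\log_2(\text{TPM} +
1)$) is available for comparison since prose descriptions of this statistic
sometimes transform first. PAR genes are excluded from the X set and
chromosome Y from both sets — neither is X-dosage informative — with flags
to change both choices, and `restrict_xci_class` limits the X set to, e.g.,
inactive genes when asking which class drives a dosage difference. RXE
filtering and computation are done per region by the pipeline, treating
regions as separate expression contexts.

**Mann-Whitney** comparisons use exact enumeration when both groups have
$\le 8$ observations without ties, otherwise the tie-corrected normal
approximation with continuity correction.

**XCI enrichment** builds, for each XCI class × direction stratum
(female-bias / male-bias / all), the 2×2 table of DEG membership against
class membership over the universe of tested X-annotated genes, applies the
two-sided Fisher exact test (minimum-likelihood two-siding), and
Bonferroni-corrects over all tables computed. Reported odds ratios are
sample cross-product ratios, so single-zero-cell tables report infinite OR
rather than a shrunk estimate.

# Sex-specific schizophrenia signal

The **stringent filter** starts from one sex's FDR < 0.05 diagnosis DEGs,
removes genes significant in the opposite sex, then removes genes whose
residualized expression (minimal null, diagnosis left in) differs between
diagnoses in the *opposite* sex by Mann-Whitney at p < 0.05. Stages are
strictly nested and each removal is recorded with its reason. On data where
the diagnosis effect is truly shared between sexes the filter removes most
of the set — its purpose — which the tests assert on planted simulations.

The **subsampling null** asks whether one sex's DEG count is explained by
its smaller sample size: draw the male samples down to the female n (simple
random sampling by default; the draw can optionally be stratified by
diagnosis, since unstratified draws can unbalance CTL/SZ), rerun the full
diagnosis DE pipeline per draw, and locate the observed female count in the
B-draw distribution with an add-one empirical p-value, reported one- and
two-sided (two-sided = twice the smaller tail, capped at 1; the add-one form
never returns 0). Hidden factors are re-estimated within each draw when the
DE configuration requests them — the faithful but expensive choice;
`de_args` can disable SVs and weights when the null is run at scale.

# $\pi_1$ and concordance

$\pi_0(\lambda) = \#\{p > \lambda\}/(n(1-\lambda))$ on the grid
$0.05, 0.10, \ldots, 0.95$, smoothed by a cubic smoothing spline (df = 3)
and evaluated at the largest $\lambda$, clamped to $[0,1]$;
$\pi_1 = 1 - \pi_0$ estimates the fraction of one analysis's (nominally
significant, p < 0.05) findings that are true signals in another. Below 20
p-values the smoother is unstable and a fixed $\lambda = 0.5$ estimate is
used. Spearman correlation of log2FCs (average ranks under ties), sign
concordance, and Fisher overlap enrichment complete the replication view.

# Numerical and design choices

* Classed errors (`sexdimorph_validation_error`) for every contract
  violation; errors name the offending sample/gene/column.
* All-zero TPM columns, zero X-gene means, empty groups, rank-deficient
  designs (naming aliased columns), and residual df shortfalls are signaled,
  never propagated as NaN/-Inf.
* Moderation with zero-variance genes: `squeezeVar` handles them; genes
  with zero *residual* variance are excluded from residualization with a
  warning.
* Determinism: the generator and every random stage take explicit seeds and
  restore the caller's RNG state; the pipeline derives and records stage
  seeds from one master seed in `resolved_config.yaml`.
* Problem sizes in the test suite are chosen for a desk-scale laptop run:
  calibration checks use 2000 genes × 120 samples over ten seeds, recovery
  checks 2000 genes × 200 samples, the RXE recovery 25 replicates of 2000 ×
  200, and the subsampling calibration 200 repetitions at B = 99 on a
  200-gene cohort with the unweighted, SV-free DE configuration (the
  exchangeability being tested does not depend on those components, and the
  dataset plants many weak diagnosis effects so the DEG count has enough
  spread for a distributional comparison against the uniform).

# Known limitations

* The residual-PCA surrogate construction can mildly inflate type-I error
  in the presence of weak latent structure (see above); the calibration
  acceptance checks therefore characterize the pipeline without a hidden
  batch factor.
* Cluster-robust inference replaces, not reproduces, a mixed-model fit;
  with few donors its t approximation is crude.
* The empirical p of the subsampling null is discrete; with B = 99 its
  resolution is 0.02.
* Gene-level only; no transcript/exon/junction features.

# A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(n_genes = 2000, seed = 7),
  out_dir = "sexdim_demo", covariates = "auto", n_sv = "auto",
  subsample_B = 100, seed = 7
)
res <- run_pipeline(cfg)
res$rxe_tests
autoplot(res$rxe, by = "sex")
```
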