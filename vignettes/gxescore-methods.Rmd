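---
title: "Molecular gene-environment scores for brain endophenotypes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular gene-environment scores for brain endophenotypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxescore)
```

## The scientific problem

Family history and retrospective trauma scales are noisy proxies for the
genetic and environmental liabilities that shape psychiatric risk:
familiality confounds shared genes with shared environment, and recall-based
trauma scores are subjective. `gxescore` implements a molecular alternative
for bipolar-spectrum (BDS) cohorts: a **polygenic risk score** (PRS) as the
genetic measure, a **methylation profile score** (MPS) as the environmental
measure, and a regression stage that relates both scores, their product, and
the clinical proxies to structural brain measures (an endophenotype panel of
tissue fractions, cortical thicknesses and subcortical/thalamic volumes).

The pipeline has four analysis stages plus a synthetic-cohort generator.
Because cohort genotype, methylation and MRI data of this kind are protected
and undeposited, the generator is a first-class module: it plants known
genetic, epigenetic and interaction effects so every downstream stage can be
validated against ground truth.

## Genotype stage

**QC.** Variants are filtered by per-call quality (GenCall-like score < 0.2
masked, when a quality matrix is available), call rate (>= 0.95),
minor-allele frequency (>= 0.01) and an exact Hardy-Weinberg test
(p >= 1e-6); subjects need a call rate >= 0.95. The HWE test conditions on
the observed allele counts and sums the probabilities of all heterozygote
counts whose conditional probability does not exceed the observed one.
Probabilities are computed by the ratio recurrence
$P(h+2)/P(h) = 4\,n_{AA}(h)\,n_{aa}(h) / ((h+1)(h+2))$ and normalized, which
is exact to floating precision and avoids factorial overflow; the suite
verifies agreement with a direct enumeration oracle to $10^{-12}$ for every
table with up to 50 subjects.

**Relatedness.** Pairwise identity-by-descent is estimated by the
method-of-moments from identity-by-state counts and allele frequencies on an
LD-pruned marker set (greedy window pruning, $r^2 \ge 0.2$, window 50,
step 5), with $\hat\pi = P(\text{IBD}=1)/2 + P(\text{IBD}=2)$ clipped to
$[0,1]$ and state probabilities renormalized. We deliberately omit the
finite-sample bias-correction factors used by some tools: at the marker and
sample scales this package targets the correction is negligible, and the
uncorrected estimator keeps the algebra transparent. Pairs with
$\hat\pi \ge 0.14$ are reported as potentially related.

**PRS.** GWAS weights are aligned to the counted allele (effect allele =
counted allele: weight applies to the dosage; effect allele = other allele:
the score uses $2-d$). Strand-ambiguous A/T and C/G variants are dropped by
default — without allele-frequency matching there is no safe way to orient
them. Clumping is greedy by ascending GWAS p-value (ties by chromosome and
position) with defaults $r^2 \ge 0.1$ within 250 kb — the conventional PRS
defaults, configurable — and is performed once on the full summary set so
that p-value-threshold subsets are nested. The score at threshold $p_T$ is
$\sum_j w_j d_j$ over clumped variants with GWAS $p \le p_T$; missing
dosages are mean-imputed at twice the effect-allele frequency. The threshold
is chosen by scanning $p_T \in \{0.01, 0.02, \dots, 0.50\}$ and fitting a
logistic regression of family-history status on each score; the smallest
two-sided Wald p-value wins, ties break toward the smaller threshold, and
thresholds with non-converged (e.g. separated) fits are excluded from
selection but retained in the scan table. Note that a flipped allele
labelling with a negated weight shifts each variant's contribution by a
constant $-2w$; between-subject contrasts (and hence all downstream
inference) are exactly invariant, which is what the tests assert on centered
scores.

## Methylation stage

**Probe QC** removes probes whose detection p-value is >= 0.01 in more than
1% of samples (the failure fraction is configurable; the underlying
detection rule is stated loosely in common protocols, so the operational
threshold is explicit here), whose bead count is < 3 in at least 5% of
samples, or which carry a SNP at the interrogation/extension site. The three
rules are independent, so their application order cannot change the survivor
set. **Sample QC** flags subjects beyond 4 SD on either of the first two
beta-value principal components.

**BMIQ.** Illumina type II probes have a compressed dynamic range relative
to type I probes. Per subject, a three-state (unmethylated / hemimethylated
/ methylated) beta mixture is fitted by EM separately to each design type;
type II probes assigned to the outer states are quantile-mapped onto the
matching type I state distribution
($\beta' = F^{-1}_{I,s}(F_{II,s}(\beta))$), and hemimethylated probes are
carried across by a dilation (linear) map that preserves the gaps to the
outer states. The EM uses deterministic quantile-based initialization, a
weighted method-of-moments M-step (stable for tight, well-separated
methylation states), a relative log-likelihood tolerance of $10^{-5}$ and at
most 200 iterations. Subjects whose fit fails to converge or produces a
state with fewer than 5 probes keep their unadjusted betas and are reported.
Type I probes are never modified, and the map is monotone within each state.

**MPS.** After BMIQ, betas are logit-transformed to M-values
($M = \log_2 \beta/(1-\beta)$, the field convention; base configurable). An
L1-penalized logistic regression of BDS status on all subjects' M-values
(glmnet path; probes standardized internally, weights reported on the
M-value scale) selects the score's probes. Lambda is chosen by stratified
5-fold cross-validated binomial deviance with the one-standard-error rule —
the conservative conventional default, chosen here because the downstream
use is a score, not a classifier, and sparser scores are more interpretable.
The MPS is the plain weighted sum $\sum_i w_i x_i$ of selected-probe
M-values, without the intercept. The number of selected probes is
data-dependent (LASSO under cross-validation is not support-stable at these
sample sizes), so it is reported, not asserted. A cis-meQTL scan
(probe M-value ~ dosage for variants within 500 kb) with Storey q-values
across all tested pairs screens selected probes for genetic confounding.

## Association stage

Analysis is restricted to BDS subjects with brain measures; all measures are
z-scored over the analysis subjects. For each factor (family history, CLES
trauma count, PRS, MPS) and each measure, the package reports the Spearman
correlation (Pearson correlation of mid-ranks) and the OLS fit

`measure ~ factor + age + age^2 + gender + race + smoking`

on complete cases, with the factor's coefficient, two-sided p, and partial
$R^2 = 1 - SSR_{full}/SSR_{cov}$ against the covariate-only model on the
same subjects (equal to $(R^2_{full} - R^2_{cov})/(1 - R^2_{cov})$, an
identity the suite checks to $10^{-10}$). Age enters with its square; the
"Unknown" smoking level is retained as a category. Factors enter on their
native scale by default. Interaction models add the factor pair and product
term (`G + E + G:E + covariates`), reporting the interaction coefficient and
the partial $R^2$ of the three-term block. Missing CLES values are handled
by complete cases per model — no imputation.

**FDR.** Storey q-values are computed within each factor across measures
(configurable to one pooled family): $\hat\pi_0(\lambda) =
\#\{p > \lambda\}/(m(1-\lambda))$ over $\lambda = 0.05, \dots, 0.95$,
extrapolated with a cubic smoothing spline, clipped to $(0,1]$, then the
step-up rule. With fewer than 10 p-values $\pi_0$ is fixed at 1 (the
Benjamini-Hochberg special case). A known limitation, quantified by the
suite's null simulations: at family sizes around 44 the smoother's $\pi_0$
is noisy and the procedure is somewhat anticonservative — the probability of
at least one false family discovery at q < 0.1 under a global null is about
0.15 rather than 0.10 (pure BH measures about 0.09 on the same replicates).
Users who need strict small-family control should pass `pi0 = 1`.

**Bootstrap comparison.** For each measure, subjects are resampled with
replacement (default 2000 runs; each refit uses a fast QR path on
pre-built design matrices, and rank-deficient resamples are redrawn and
counted) and $\Delta = R^2_{partial,molecular} - R^2_{partial,clinical}$ is
recorded. The default one-sided p is the share of resampled $\Delta$ below
zero, with exact zero ties given half weight so that the degenerate
self-comparison yields p = 0.5. Simulation shows this p is *conservative*
under an exchangeable null — it concentrates around 0.5 and its 5% tail is
not inflated — rather than uniform; treat it as a directional screen, not a
calibrated test. A two-sided option doubles the smaller tail.

## The synthetic-cohort generator

The generator emulates the data the analyses assume, at desk scale, with
defaults mirroring the target study design: 119 subjects (55 BDS), 44 brain
measures, 2000 SNPs, 1000 CpG probes.

* **Genotypes**: two haplotypes per subject; within an LD block each
  haplotype's latent liabilities share a Gaussian factor (correlation
  `ld_rho`, default 0.3, blocks of 10) and are thresholded at the quantile
  of the variant's MAF (uniform on 0.05-0.5). This yields dosages in exact
  HWE with LD controlled independently of MAF. Missingness is completely at
  random (default 0).
* **GWAS weights**: 20 causal SNPs with log-odds weights of magnitude
  0.2-0.5 and p-values $10^{-U(4,8)}$; null SNPs get weights near zero
  (SD 0.02) and uniform p-values; the reported effect allele is ALT or REF
  with equal probability.
* **Methylation**: three-state beta mixtures per probe; signal probes
  (default 20, shift 0.1) start in the hemimethylated band so the planted
  BDS shift is realized exactly rather than truncated at the beta
  boundaries; type II probes (80%) are compressed toward 0.5 by a factor
  0.8 to exercise BMIQ; detection-p and bead-count matrices are emitted.
* **Clinical proxies**: group assignment follows the true genetic score with
  logistic-scale noise at exact group sizes; family history is Bernoulli
  with log-odds increasing in the true genetic score (slope 1.5); CLES is a
  0-11 count mapped from a latent with correlation 0.3 to the true
  environmental score. These joint dependencies are configurable modelling
  assumptions, not published quantities.
* **Brain measures**: $y = \beta_G G + \beta_E E + \beta_{G\times E} GE +$
  covariate terms $+$ shared $+$ noise, with $G, E$ standardized true
  scores, defaults $\beta_G = 0.3$, $\beta_E = 0.4$, $\beta_{G\times E} =
  0.4$ on 4 of 44 measures, noise SD 1, and a per-subject global component
  (SD 0.6, about a quarter of the variance) shared by all measures to
  emulate the positive correlation that intracranial-volume scaling induces
  among real volumetric measures.

What the generator does **not** emulate: genome-wide marker density
(10.9 million imputed SNPs), array-level intensity data, cell-type
composition, population stratification beyond what `genotype_pca` tests
construct, and pedigree structure beyond single injected relative pairs.
Passing tests therefore demonstrate the correctness and calibration of the
algorithms under the stated generative assumptions — not that any particular
real-cohort finding replicates.

## Numerical choices and degenerate inputs

* HWE: ratio recurrence with rescaling above $10^{250}$; monomorphic tables
  return p = 1; all-zero tables error.
* LD $r^2$: pairwise-complete subjects; zero-variance vectors give 0.
* PRS: an empty variant set at a threshold yields all-zero scores with a
  warning; clump ties break by (chromosome, position).
* Beta-mixture EM: beta parameters floored at 0.05, component variances
  capped below the Bernoulli bound; any EM failure falls back to unadjusted
  betas for that subject, with a warning.
* Betas are clamped to $[10^{-6}, 1-10^{-6}]$ at container construction;
  the logit transform refuses values outside $(0,1)$.
* `partial_r2` clips to $[0,1]$ with a warning (possible only for non-nested
  fits); a saturated covariate model errors.
* Rank-deficient association fits error, naming the collinear columns;
  two-level non-numeric factors are coerced to 0/1.
* PCA signs are fixed by making each component's largest-magnitude loading
  positive, so results are deterministic.
* All simulation stages draw from seed-offset RNG streams and restore the
  caller's RNG state.

## Problem sizes used by the test suite

The suite validates calibration with simulations sized for tight unit
economics: interaction type-I error uses 1000 replicates at n = 300; LASSO
support recovery uses 50 seeds at n = 200 with 500 probes; the null FDR
simulation uses 500 replicates of one factor family by 44 measures at
n = 47 (the analysed-cohort scale); bootstrap calibration uses 200-run
bootstraps over dozens of null datasets. The acceptance script runs the full
file-based pipeline once at the default cohort scale with a 500-run
bootstrap.

## Known limitations

* The Storey smoother's small-family anticonservatism described above.
* The bootstrap comparison p is conservative, not uniform, under the null.
* LASSO probe selection is unstable at n ~ 100-200: the *score* is
  reproducible under a fixed seed, the *support* varies across folds and
  seeds.
* The PRS threshold scan's "most significant" criterion is itself a
  selection over 50 correlated tests; the scan table is retained so users
  can judge the profile rather than trust a point choice.
* IBD estimates from a few thousand markers are noisy for individual pairs
  (SDs of a few percent on $\hat\pi$); they are screening statistics.
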