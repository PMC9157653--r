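---
title: "Models and methods for genomic selection in Solanaceous panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for genomic selection in Solanaceous panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsolanum)
```

`gsolanum` packages the statistical machinery of a genomic-selection study
on fruit traits in tomato- and pepper-style diversity panels. This
vignette explains the models, the defaults and why they are set where they
are, the numerical choices, and what the synthetic-data generator does and
does not emulate.

## The data model

A panel is a set of accessions — a large cultivated core plus small groups
of divergent wild species — genotyped at tens of thousands of biallelic
SNPs (coded as alternate-allele dosages 0/1/2) and phenotyped in replicated
field trials. Continuous morphometric/colorimetric traits come from image
analysis with several fruits per accession and trial; ordinal
conventional-descriptor (CD) traits are manual scores on 3–10 point
scales.

## Trial-level mixed model and genetic values

Replicates are first averaged within each accession × trial cell
(`trial_means()`); the cell means then follow

$$y_{ij} = \mu + g_i + t_j + e_{ij},\qquad
  g_i \sim N(0, \sigma^2_g),\; t_j \sim N(0, \sigma^2_t),\;
  e_{ij} \sim N(0, \sigma^2_e),$$

with a fixed intercept and independent random genotype and trial effects.
`fit_trial_lmm()` estimates the variance components by EM-REML on
Henderson's mixed-model equations: each iteration solves the equations at
the current components and updates
$\sigma^2_u \leftarrow (\hat u'\hat u + \sigma^2_e\,\mathrm{tr}\,C^{uu})/q$
for each random term and
$\sigma^2_e \leftarrow (y'y - \hat s'W'y)/(n-1)$. The restricted
log-likelihood is recorded every iteration and is non-decreasing (a
property the test suite asserts); convergence is a relative change below
1e-8, at most 500 iterations, with components clamped at zero — components
pinned at the floor are excluded from the convergence criterion, because a
boundary component decays geometrically forever without ever "converging"
in relative terms. Unbalanced cells are simply missing rows of the
equations; nothing is dropped or zero-filled.

Heritability is the genotype share of the total fitted variance,
$H^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_t+\sigma^2_e)$. Whether "total"
should include the trial component is genuinely ambiguous; both
conventions are implemented (`h2_includes_trial`, default `TRUE`, reading
"total variance" literally as the sum of everything fitted). The
per-accession genetic value $\hat\mu + \mathrm{BLUP}(g_i)$ is the response
passed to all genomic-prediction models.

Ordinal CD traits bypass the Gaussian model: `modal_labels()` takes each
accession's modal score across trials and replicates (ties to the lower
category), since a linear mixed model on a 5-point scale is
inappropriate.

## Single-trait rrBLUP and its kernel dual

The core prediction model is ridge-regression BLUP,

$$y = 1b + Zu + e, \qquad u \sim N(0, \sigma^2_u I_m),\;
  e \sim N(0, \sigma^2_e I_n),$$

the "common marker variance" assumption: every marker effect is shrunk
equally. The fixed design is the intercept alone — the standard rrBLUP
usage. Markers are centred by training-set means and deliberately *not*
variance-scaled: scaling would contradict the equal-variance-per-effect
assumption by giving rare alleles larger implied effects.

`fit_rrblup()` eigendecomposes the kernel $K = Z_cZ_c'$ once and maximises
the profiled restricted likelihood over $\log\lambda$
($\lambda=\sigma^2_e/\sigma^2_u$) on $[10^{-6},10^{6}]$: a bounded Brent
search followed by bisection on the analytic derivative of the profiled
deviance (envelope theorem for the GLS intercept), so the optimum is
located to machine precision rather than Brent's ~1e-8 floor — this is
what lets the kernel-parameterised multivariate solver reduce *exactly*
(to 1e-8 and beyond) to the marker-parameterised solver on one trait.
Endpoint optima are flagged as boundary fits. Predictions are
$\hat b + (Z_{new}-\bar z)\hat u$; marker columns must match exactly, with
no silent reordering. The GBLUP form uses $K = Z_cZ_c'/m$
(`kinship()`, centring vector configurable so train/test blocks stay
consistent inside cross-validation) and is identical by duality — the
test suite checks both this duality and agreement with a dense
mixed-model-equation solve on every run.

## Multi-trait model

For a group of $t$ traits the model becomes
$\mathrm{vec}(Y) = (I_t \otimes 1)B + g + e$ with
$\mathrm{cov}(g) = \Sigma_g \otimes K$ and
$\mathrm{cov}(e) = \Sigma_e \otimes I$. In the eigenbasis of $K$ the rows
decouple into independent $t$-vectors with covariance
$d_i\Sigma_g+\Sigma_e$, so each EM-REML iteration costs $O(nt^3)$. The
E-step uses the REML projector (fixed-effect uncertainty included), which
keeps the restricted likelihood monotone; near-singular covariance
estimates are ridge-stabilised by $10^{-8}\,\mathrm{tr}(\Sigma)/t$ with a
warning. Prediction is the trait-wise conditional mean
$\hat G_{test} = K_{cross}K_{train}^{+}\hat G_{train}$ plus intercepts —
valid because the genetic covariance factorises. The kernel
parameterisation was chosen over explicit marker effects: predictions are
identical by duality and the parameter space is far smaller. With $t=1$
the profiled 1-D REML is used directly instead of EM; EM's linear
convergence would make the single-trait reduction a statement about
iteration counts instead of algebra.

Whole prediction matrices are scored by the Rv coefficient
$\mathrm{tr}(XX'YY')/\sqrt{\mathrm{tr}((XX')^2)\,\mathrm{tr}((YY')^2)}$ on
column-centred matrices. Seven conventional trait groupings are provided
as presets (`trait_group_presets()`); any trait list works.

## Classification of descriptor traits

CD traits are predicted by two families: bootstrap-aggregated decision
trees (1000 trees, $\lfloor\sqrt p\rfloor$ split candidates) and an
RBF-kernel maximum-margin classifier whose cost and kernel width are each
tuned over a 15-value grid by inner cross-validated accuracy. The grids
default to 15 log-spaced costs on $[10^{-2},10^{3}]$ and 15 widths over
four decades around the median heuristic
$1/\mathrm{median}(\lVert x_i-x_j\rVert^2)$ — the published description
fixes the grid sizes but not the values, so these are documented,
configurable defaults. Class imbalance is handled by SMOTE
(`smote()`): synthetic minority samples are convex combinations
$x + U(0,1)(z-x)$ of a minority point and one of its $k=5$ nearest
same-class neighbours, applied *inside training folds only* — applying it
before splitting would leak interpolated copies of test points into
training. Ordinal labels are treated as nominal; ordinality re-enters only
through the regression-comparison mapping below.

## Evaluation framework

`make_cv_folds()` builds the repeated random k-fold scheme (default
5 × 30 = 150 sets; fold sizes differ by at most one). Per set, *all*
data-dependent steps — marker centring, REML, SMOTE, hyperparameter
tuning — are recomputed inside the training folds. Regression models
report Pearson and Spearman correlations plus the matched rate of the
top 30%/15% accessions (the selection-relevant metric; the top set of
size $s=\lceil f n\rceil$ is taken by predicted and by observed value and
the overlap divided by $s$). Classifiers report accuracy and AUC (binary:
rank-based; multiclass: macro-averaged one-vs-rest, the published numbers
do not state a reduction so the symmetric choice is used). Folds where a
metric is undefined (constant predictions, single-class truth) record
`NA` and are excluded from summaries with a count — zero-filling would
bias means toward zero. Models are contrasted by two-sided paired t-tests
over the 150 per-set values; raw p-values are reported without
multiple-testing correction.

To compare regression and classification on one footing, predicted
continuous values are assigned to categories occupying the same quantiles
as the observed CD classes (`map_regression_to_categories()`, the same
floor/largest-remainder rank rule as the generator) and scored by accuracy
against the observed labels.

Transfer scenarios (`build_scenarios()`): `baseline_transfer` trains on
all cultivated and tests on all wild accessions; `wild_augment` adds
`n_wild` sampled wild accessions (at least one per species when
stratified) to the training set and tests on the rest, the study grids
being 7, 10, 15, 20, 25, 30; `wild_balanced` trains on equal numbers of
cultivated and wild. Draws are independent per scenario and seeded; the
published text is ambiguous about whether wild draws are reused across
folds, and independent redraws were chosen as the cleaner design.

## The synthetic-data generator

`simulate_genotypes()` emulates the tGBS character of real panels rather
than their genealogy: no coalescent, no recombination map, no
domestication sweeps — the analysis only needs realistic LD ranks and
population structure, not history.

* **Structure.** A shared ancestral frequency vector; the cultivated group
  uses it directly, each wild species draws around it by the
  Balding–Nichols construction (Beta with mean $p_0$ and dispersion set by
  `fst_wild`). This reproduces the "cultivated core plus scattered distant
  wild groups" PCA geometry with one parameter. Defaults: 146 cultivated
  + 34 wild in 7 species (sizes 12, 11, 3, 3, 2, 2, 1 — the per-species
  breakdown of a real 34-accession wild set is not published, so a
  plausibly skewed split was fixed once), 10,000 SNPs on 12 chromosomes,
  `fst_wild = 0.3`, 10% missing calls.
* **LD.** Haplotypes are a latent stationary AR(1) Gaussian thresholded at
  the group allele-frequency quantile, two haplotypes summing to a
  dosage. Thresholding shrinks correlations (arcsine law), so `ld_rho` is
  calibrated on the *dosage* scale: the latent coefficient is
  $\sin(\pi\rho/2)$, and ancestral frequencies follow a probit AR(1) —
  with wild-group Balding–Nichols draws passed through a Gaussian copula —
  with the same persistence, because neighbours in strong LD must have
  similar allele frequencies or the frequency mismatch alone caps
  attainable $r^2$. The default `ld_rho = 0.95` reproduces the observed
  character of tGBS panels, where roughly a fifth to a quarter of SNPs
  suffice to tag the rest at $r^2 \ge 0.8$; at `ld_rho` ≤ 0.9 no
  thresholded-Gaussian model can put many pairs above 0.8, and tag
  fractions climb toward 100%. Note also that single-SNP modal imputation
  (the package's stand-in for haplotype imputation) attenuates pairwise
  LD, so tagging statistics are best assessed on complete genotypes.
* **Traits.** `simulate_multitrait()` samples shared causal loci with
  effect rows drawn from the requested genetic correlation matrix,
  rescales each trait's breeding values to variance exactly $h^2$ and
  splits the remaining $1-h^2$ between trial effects and replicate
  residuals (`trial_var_frac`, default 0.3), giving unit
  single-observation variance. At $h^2=0$ the returned "true values" are
  the standardised genetic scores (which contribute nothing to the
  phenotype) so that null-recovery correlations remain well defined.
  Defaults are 4 trials × 8 replicates (the tomato-style design; use 3
  trials for pepper) and 100 causal loci — published sources discuss
  architecture only qualitatively ("few major genes" vs "a large number
  of genes"), so QTL number is a free parameter, not an estimate.
  Causal-locus identities are returned (`qtl_ids`) so experiments can
  exclude them from the predictor set.
* **CD traits.** `derive_categorical_trait()` discretises a value vector
  by rank quantiles with floor/largest-remainder class sizes. Tied values
  always share the lowest class any of them would receive, so a constant
  vector lands entirely in the first class and any strictly increasing
  transform leaves labels unchanged. Descriptor labels in the package's
  experiments are derived from the *genetic value*: categories score the
  trait itself, and scoring noise (the realistic error source) is not
  modelled — deriving them from a noisy phenotype would instead impose an
  arcsine-law ceiling on any classifier's accuracy.

### Study conditions used by the experiments

Two experiments need conditions away from the generator defaults, chosen
once and fixed:

* **Transfer.** Prediction uses markers *excluding* the causal loci —
  genomic prediction works through marker–QTL LD, and it is the
  population-specificity of LD phase that makes cultivated-trained models
  fail on wild material; with causal loci genotyped directly the baseline
  transfer is near-perfect by construction and there is no phenomenon to
  study. The transfer panels use `ld_rho = 0.8` (imperfect proxies),
  `fst_wild = 0.6` (wild tomato species sit near the species boundary)
  and a 30-locus architecture. Under these conditions the cultivated-only
  baseline predictability collapses, adding one accession per wild
  species recovers most of it, and the gain saturates between 7 and 30
  added accessions.
* **Classification.** The 5-class fruit-size-style trait uses 5 causal
  loci at $h^2 = 0.8$ — fruit size in tomato is classically governed by a
  handful of major QTLs — with class proportions
  (0.15, 0.2, 0.3, 0.2, 0.15). The tree ensemble then clearly beats the
  majority-class baseline, and quantile-mapped rrBLUP predictions of the
  same trait score higher still, reproducing the observation that
  continuous image-based phenotyping out-predicts manual categories.

## What passing tests do and do not show

The generator produces additive, Gaussian-latent panels with stationary
LD, no dominance or epistasis, no genotype × environment interaction, no
genotyping error beyond uniform missingness, and frequency spectra
smoother than real site-frequency spectra. Passing tests therefore
demonstrate that the estimators and the evaluation machinery are correct
and well-calibrated *under the model they assume*; they do not certify
predictability levels on any real panel, which depend on trait
architecture and population history that the generator deliberately does
not model.

## Problem sizes and other numerical choices

Test and acceptance runs use panels of 100–300 accessions and 200–2,000
SNPs — large enough for the asymptotics that the properties rely on
(eigen-spectra, REML consistency, fold sizes), small enough to keep a full
run in minutes. Windows of 100 SNPs bound the LD search in pruning and
tagging (full pairwise $r^2$ is quadratic and pointless under local LD);
the tagging threshold defaults to $r^2 = 0.8$ (the threshold inside the
published tagging software is not stated); greedy tagging ties break
toward the lower position; cross-chromosome tag ranks interleave so any
prefix of the genome-wide list is representative. All stochastic steps
take explicit integer seeds, and identical seeds give bit-identical
panels, folds, draws and fits.

## Known limitations

Beyond the generator's simplifications: the LD filter and tagger are
windowed and greedy (no exact multi-marker rule mining — a ranked tag list
is all downstream analysis consumes); modal imputation ignores haplotype
information and attenuates LD relative to phasing-based imputation;
heritability from the trial model is a line-mean repeatability, not a
narrow-sense estimate from a pedigree; and the multivariate solver fits
unstructured covariances only, which is why trait groups are limited to
two or three members in practice.
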