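# gsolanum

Genomic selection for fruit traits in Solanaceous diversity panels.

Breeding programmes for tomato and pepper increasingly select parents from
large diversity panels using genomic prediction: an accession's genomic
estimated breeding value (GEBV) is predicted from genome-wide SNP markers
instead of waiting for field phenotypes. `gsolanum` implements the full
analysis such a study needs, as composable tidyverse-style functions:

* **Genotype handling** — VCF / dosage-matrix I/O, missingness and MAF
  filters, modal imputation, LD (r²) computation, an LD filter for
  near-duplicate SNPs, greedy maximum-coverage **tag-SNP selection** with
  ranked, nested subsets, and PCA for population structure.
* **Trial-level phenotypes** — the linear mixed model
  `y_ij = μ + g_i + t_j + e_ij` with random genotype and trial effects,
  fitted by EM-REML; heritability `H² = σ²_g / (σ²_g + σ²_t + σ²_e)` and
  per-accession genetic values `μ̂ + BLUP(g_i)` used as the response of all
  prediction models.
* **Single-trait rrBLUP / GBLUP** — the ridge-regression mixed model
  `y = 1b + Zu + e`, `u ~ N(0, σ²_u I)`, with the variance ratio
  `λ = σ²_e / σ²_u` estimated by profiled spectral REML; the kinship
  (`K = Z_c Z_cᵀ / m`) form is provided and is numerically identical by
  duality.
* **Multi-trait prediction** — the multivariate kinship model
  `cov(g) = Σ_g ⊗ K`, `cov(e) = Σ_e ⊗ I`, fitted by EM-REML in the
  eigenbasis of `K`, with Rv-coefficient evaluation of whole prediction
  matrices.
* **Classification of ordinal descriptor traits** — random-forest and
  RBF-SVC models with SMOTE class balancing inside training folds, plus
  the quantile mapping that puts regression predictions on the same
  accuracy footing as classifiers.
* **Evaluation** — repeated k-fold cross-validation (default 5 folds × 30
  repetitions = 150 sets), Pearson/Spearman predictability, top-30%/15%
  matched rates, accuracy and macro one-vs-rest AUC, paired t-tests
  between models, and population-transfer scenarios (train on cultivated,
  test on wild; augment training with wild accessions under
  one-per-species stratification).
* **Synthetic panels** — a seedable generator for tGBS-like SNP matrices
  (Balding–Nichols cultivated/wild structure, autoregressive LD along 12
  chromosomes) and correlated polygenic traits with trial/replicate
  structure, so the whole pipeline is testable without access to real
  panels.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and report
objects plot with `autoplot()`.

## Worked example

```r
library(gsolanum)

# a tomato-style panel: 146 cultivated + 34 wild accessions in 7 species
G <- simulate_genotypes(population_spec(n_snps = 3000, seed = 42))
G
#> <geno_matrix> 180 accessions x 3000 SNPs on 12 chromosome(s); 10.03% missing
#>   146 cultivated / 34 wild accessions

# genotype QC: missingness, modal imputation, MAF, LD pruning
G <- G |> filter_missingness(0.5) |> impute_missing() |> filter_maf(0.05) |>
  prune_redundant(0.999)
G
#> <geno_matrix> 180 accessions x 2975 SNPs on 12 chromosome(s); 0.00% missing
#>   146 cultivated / 34 wild accessions

# a polygenic fruit trait measured in 4 trials x 8 replicates
st <- simulate_trait(G, trait_spec(n_qtl = 100, h2 = 0.6, seed = 42))
fit <- fit_trial_lmm(trial_means(st$phenotypes, "trait_1"), trait = "trait_1")
glance(fit)
#> # A tibble: 1 x 8
#>   trait   mu_hat var_g  var_t  var_e    h2 converged n_iter
#>   <chr>    <dbl> <dbl>  <dbl>  <dbl> <dbl> <lgl>      <int>
#> 1 trait_1 -0.208 0.601 0.0401 0.0323 0.893 TRUE          18

# genomic prediction of the trial-BLUP genetic values, 5-fold x 10 reps
y <- setNames(fit$genetic_values$genetic_value,
              fit$genetic_values$accession_id)
sch <- make_cv_folds(G$meta$accession_id, n_folds = 5, n_repetitions = 10,
                     seed = 42)
cv <- run_cv(G, y, model = "rrblup", scheme = sch)
glance(cv)
#> # A tibble: 4 x 6
#>   trait metric       mean     sd n_sets n_missing
#>   <chr> <chr>       <dbl>  <dbl>  <int>     <int>
#> 1 trait pearson     0.789 0.0506     50         0
#> 2 trait spearman    0.767 0.0619     50         0
#> 3 trait top15_match 0.567 0.151      50         0
#> 4 trait top30_match 0.665 0.0962     50         0

# how well does a model trained on cultivated accessions transfer to wild?
base <- run_scenarios(G, y, build_scenarios(G$meta, "baseline_transfer"))
aug  <- run_scenarios(G, y, build_scenarios(G$meta, "wild_augment",
                                            n_wild = 7, n_draws = 30,
                                            seed = 42))
c(cultivated_only = base$pearson, plus_7_wild = mean(aug$pearson))
#> cultivated_only     plus_7_wild
#>       0.8453896       0.8530107
```

The trial LMM attributes 89% of the cell-mean variance to genotype
(`h2 = 0.893` — cell means average 8 replicates, so the residual is
small), cross-validated predictability of the genetic values is 0.79, and
in this gentle scenario (trait heritability 0.6, causal SNPs genotyped)
the cultivated-only model already transfers to wild accessions; the
transfer experiments in the test suite and acceptance script use harder,
more realistic conditions (stronger wild divergence, causal loci hidden
behind LD proxies) under which transfer fails without wild training
accessions.

A complete simulate → QC → tags → BLUP → CV pipeline driven by a YAML
config is in `inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R my-config.yaml output-dir/
```

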