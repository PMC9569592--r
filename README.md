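# fusionlab

Clinical–genomic data fusion for binary cancer diagnostics.

Gene-expression classifiers for thyroid nodules are accurate but every
measured gene adds assay cost, while the clinical work-up — Bethesda
cytology grade, age, sex, tumour size — is already collected. `fusionlab`
compresses those discrete clinical variables into one continuous
**malignancy risk** feature (a cross-fitted Bayesian-network posterior
P(malignant | clinical)) and measures what fusing that feature with a gene
panel buys, in accuracy and in the reproducibility of the gene selection,
under three strategies evaluated in one paired bootstrap:

- **early fusion** — the risk feature is appended before feature
  selection and competes with every gene in the ranking;
- **late fusion** — the top *N* genes are selected first, the risk
  feature is appended afterwards (*N* + 1 model features);
- **no fusion** — genes only (plus a **clinical-only** reference).

## What is inside

| Stage | Functions |
| --- | --- |
| Synthetic cohorts with the assumed statistical structure | `generator_config()`, `generate_clinical()`, `generate_expression()`, `generate_dataset()`, `read_dataset()` |
| Clinical feature extraction | `discretize_clinical()`, `learn_structure()` (Tabu search, AIC), `estimate_parameters()` (Bayesian smoothing), `query_risk()` (likelihood weighting / exact), `extract_malignancy_risk()` (10-fold cross-fitting) |
| Dependency structure | `spearman_pairs()`, `kraskov_mi()` (k-nearest-neighbour mutual information), `dependency_report()`, `dependency_histogram()` |
| Feature selection | `wilcoxon_rank()` (rank-sum + Benjamini–Hochberg), `relieff_rank()`, `select_top()` |
| Bootstrap fusion evaluation | `zscore_normalize()`, `run_iteration()`, `run_experiment()`, `summarize_accuracy()`, `compare_models()` (Mann–Whitney) |
| Selection stability | `kuncheva_index()`, `gather_selection_sets()`, `stability_curve()` |

Results are tibbles throughout; `fusion_experiment` objects have
`tidy()`, `glance()` and `autoplot()` methods.

The core statistic for stability is the Kuncheva index of the K selected
feature sets S₁…S_K (each of size k from n candidates):

κ(S) = 2/(K(K−1)) · Σ_{i<j} (|S_i ∩ S_j| − k²/n) / (k − k²/n),

the mean pairwise overlap corrected for overlap by chance: 1 means
identical selections, 0 means chance-level agreement.

## Worked example

Generate a synthetic 200-sample cohort at 77/123 malignant/benign
prevalence with a 163-gene panel, extract the clinical risk, and compare
fusion strategies under ReliefF selection:

```r
library(fusionlab)

cfg <- generator_config(seed = 1)
ds  <- generate_dataset(cfg, tempdir())

clin <- discretize_clinical(ds$clinical)
risk <- extract_malignancy_risk(clin, k = 10, method = "exact", seed = 2)
head(risk, 3)
#> # A tibble: 3 × 3
#>   sample_id malignancy_risk label
#>   <chr>               <dbl> <fct>
#> 1 S001              0.838   malignant
#> 2 S002              0.808   malignant
#> 3 S003              0.00284 benign

ex <- run_experiment(ds$expression, risk, ds$clinical$label,
                     strategies = c("early", "late", "none", "clinical_only"),
                     methods    = "relieff",
                     n_features = c(3, 8, 15),
                     B = 100, seed = 3)
tidy(ex)
#> # A tibble: 10 × 7
#>    strategy      method  n_features median_acc ci_low ci_high kuncheva
#>    <chr>         <chr>        <int>      <dbl>  <dbl>   <dbl>    <dbl>
#>  1 early         relieff          3      0.854  0.790   0.918    0.496
#>  2 early         relieff          8      0.861  0.786   0.926    0.518
#>  3 early         relieff         15      0.864  0.781   0.929    0.473
#>  4 late          relieff          3      0.855  0.784   0.923    0.498
#>  5 late          relieff          8      0.865  0.787   0.936    0.549
#>  6 late          relieff         15      0.862  0.774   0.936    0.494
#>  7 none          relieff          3      0.727  0.613   0.803    0.334
#>  8 none          relieff          8      0.813  0.690   0.893    0.496
#>  9 none          relieff         15      0.84   0.736   0.914    0.463
#> 10 clinical_only relieff          1      0.858  0.791   0.907    1
```

Reading the table: each row is one grid cell summarized over 100 paired
bootstrap iterations — median out-of-bag accuracy with a 2.5/97.5
percentile interval, and the Kuncheva stability of the 100 selected
feature sets. Here a fused model with 3 molecular features (median 0.854)
already matches the expression-only model at 15 features (0.840), the
pattern the package is built to measure; `compare_models()` on the two
cells' accuracy vectors gives the Mann–Whitney p-value for that contrast,
and `autoplot(ex)` / `autoplot(stability_curve(ex))` draw the accuracy
and stability curves.

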