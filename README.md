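# appsig

Bootstrap discovery and out-of-bag validation of small gene-expression
biomarker signatures separating **phlegmonous** (PA, uncomplicated) from
**gangrenous** (GA, complicated) pediatric appendicitis.

At realistic cohort sizes for this question (13 PA vs 16 GA patients,
tens of thousands of genes) a single train/test split cannot support
either feature selection or an honest accuracy estimate. `appsig`
implements the resampling design built for that regime, for analysts who
want the whole chain — preprocessing, differential expression, signature
search, ROC aggregation — reproducible from one seed:

* **Preprocessing** — classic across-sample quantile normalization
  (rank-k values replaced by cross-sample rank-k means, ties averaged)
  followed by log2.
* **Differential expression** — per-gene Welch unequal-variance t-test,
  Welch–Satterthwaite df, two-sided p, log2 fold change
  ( mean<sub>GA</sub> − mean<sub>PA</sub> ), significance at raw
  p < 0.05.
* **Signature search** — B bootstrap iterations; each draws a discovery
  multiset (n with replacement) and its out-of-bag validation set, ranks
  genes by |t| on the discovery samples only, forms nested top-k
  candidate signatures (k = 1..k_max), and fits a ridge-penalized
  logistic regression per candidate, maximizing
  ℓ(β) − (λ/2)‖w‖² by IRLS on z-scored features.
* **Selection** — winning size k\* = argmax over k of the mean validation
  AUC (ties → smaller size); the signature is the k\* most frequently
  top-ranked genes.
* **Evaluation** — concordance AUC
  (#{s<sub>GA</sub> > s<sub>PA</sub>} + ½·ties)/(n<sub>GA</sub>n<sub>PA</sub>),
  threshold-swept sensitivity/specificity as mean ± bootstrap SE (SD
  across iterations), and the AUC summary with normal and percentile
  lower 95% confidence limits.

A seeded synthetic-data generator emulates the study design (13 vs 16
samples; 2,000 genes with 4 informative genes for routine work, or the
full 56,666-gene layout with ~6% differentially expressed via
`emulateStudyScale()`), so every stage is testable with known ground
truth and no downloads.

## Worked example

```r
library(appsig)

cfg <- pipelineConfig(synthetic = syntheticConfig(seed = 7L),
                      B = 1000L, seed = 7L, outDir = "appsig_demo")
res <- runPipeline(cfg)
res$selection
#> SignatureSelection: 4-gene signature
#>   genes: g01216, g01444, g01608, g01289
#>   mean validation AUC 0.876 (SE 0.145, n = 1000 iterations)

reportRun("appsig_demo")
#> Selected signature (4 genes): g01216, g01444, g01608, g01289
#> Mean validation AUC by signature size:
#>   size  1: 0.854 (n = 1000)
#>   size  2: 0.866 (n = 1000)
#>   ...
#>   size  4: 0.876 (n = 1000)
#>   ...
#> AUC was 88% (SE 14, CL 59.2)
#>   percentile lower 95% limit: 50.0%
```

What the numbers mean: this synthetic cohort planted 4 informative genes
(truth recorded in `appsig_demo/truth.tsv`: g01216, g01289, g01444,
g01633). The search settled on a 4-gene signature containing three of
them plus one noise gene; its mean out-of-bag validation AUC across the
1,000 bootstrap iterations is 0.876, the bootstrap SE (the SD of the
per-iteration AUCs — wide, because each out-of-bag set holds only ~10
samples) is 0.145, and the normal-approximation lower 95% confidence
limit is 59.2%. The run directory also holds the full DE table,
per-iteration records, per-size summary, threshold-wise ROC table and a
manifest sufficient to re-run the analysis bit-identically.

Real data enter the same way via TSV files (genes × samples matrix;
two-column sample/class labels with classes `PA`/`GA`):

```r
cfg <- pipelineConfig(matrixPath = "matrix.tsv", labelsPath = "labels.tsv",
                      B = 1000L, seed = 1L, outDir = "run1")
runPipeline(cfg)
```

A thin command-line wrapper with `simulate` / `run` / `report`
subcommands is installed at `inst/scripts/appsig.R`.

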