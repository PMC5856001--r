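# dsbpredict

Kilobase-resolution prediction of DNA double-strand breaks (DSBs) from
epigenomic occupancy, DNA motifs and DNA shape.

## The problem

Endogenous DSBs, as mapped genome-wide by assays like DSBCapture or BLESS,
concentrate in accessible, active chromatin. `dsbpredict` is for
computational genomicists who want to (i) quantify which chromatin marks,
transcription-factor motifs and DNA-shape features colocalize with DSB
sites, (ii) train classifiers that predict DSB sites from those features
alone, and (iii) score whole genomes for DSB propensity in fixed-width
bins — all reproducibly, including a synthetic-data generator so every
stage can be exercised without any external download.

## The model

Sites are intervals (0-based half-open). The positive class is the DSB
peak set (optionally the intersection of two replicates); the negative
class is random genomic sites matched per-site on length, GC and repeat
content. Each site *i* is encoded as a feature vector:

- **occupancy** `x_ij ∈ [0,1]`: fraction of site *i* covered by peaks of
  track *j* (a peak over 60% of the site gives `x = 0.6`);
- **motif counts** `m_ik ∈ ℕ`: PWM hits of motif *k* at min–max relative
  score ≥ 0.8, both strands;
- **shape** 48 statistics: for each of MGW, ProT, Roll, HelT (pentamer
  lookup), the 11 quantiles at 0,10,…,100% plus the variance.

Two classifiers: a random forest (500 Gini trees, `mtry = ⌊√p⌋`, score =
vote fraction, variable importance = mean decrease in out-of-bag accuracy
under permutation) and L1-penalized logistic regression
(cross-validated λ; coefficients report as odds ratios `OR = exp(β)`).
Association of single features uses 2×2 tables:
`OR = (a·d)/(b·c)`, two-sided Fisher exact p, Bonferroni/BH correction.
Evaluation: ROC (trapezoid AUROC = Mann–Whitney concordance) and
precision–recall (step-integral AUPR), with a 2000-replicate percentile
bootstrap CI for AUROC.

## Worked example

Simulate a 2-Mb genome with 1000 planted DSB sites whose marks follow the
observed colocalization probabilities (DNase-like 0.91 vs 0.11, CTCF-like
0.25 vs 0.02, H3K4me2-like 0.74 vs 0.11), draw matched controls, train
and evaluate a forest:

```r
library(dsbpredict)

sim  <- simulate_dsb_experiment(chrom_length = 2e6, n_dsb = 1000, seed = 1)
neg  <- sample_matched_negatives(sim$truth$dsb_sites, sim$genome, seed = 2)

pos_f <- featurize_sites(sim$truth$dsb_sites, tracks = sim$truth$tracks)
neg_f <- featurize_sites(neg, tracks = sim$truth$tracks)

data   <- assemble_dataset(pos_f, neg_f, test_fraction = 0.3, seed = 3)
forest <- train_forest(data, seed = 4)
evaluate(forest, data, seed = 5)
#> <dsb_eval> AUROC = 0.9815 (CI [0.9712, 0.9906], 2000 bootstraps), AUPR = 0.9781 (300 pos / 300 neg)

tidy(forest)
#> # A tibble: 3 × 2
#>   feature importance
#>   <chr>        <dbl>
#> 1 DNase       0.289
#> 2 H3K4me2     0.0707
#> 3 CTCF        0.0380

enrichment_report(pos_f, neg_f)
#>   feature pct_pos pct_neg odds_ratio         p     p_adj
#> 1   DNase    89.4     8.4       91.9         0         0
#> 2    CTCF    26.7     1.6       22.4   7.8e-68   2.3e-67
#> 3 H3K4me2    75.0    16.5       15.2  7.6e-162  2.3e-161
```

The AUROC (0.98 with a tight bootstrap CI), the DNase-dominated variable
importance, and the enrichment table (DNase OR ≈ 92 from ~89% vs ~8%
colocalization) are the synthetic analogue of what the method reports on
real keratinocyte DSB data. Genome-wide scoring tiles the genome into
250-base bins, featurizes them with the same encoders, and calls
high/low-score bins:

```r
scan <- score_genome(forest, sim$genome, tracks = sim$truth$tracks)
calls <- call_high_low(scan, low = 0.25, high = 0.75)
# 8000 bins -> 1835 predicted DSB, 5466 predicted control
```

A thin command-line wrapper with subcommands (`simulate`, `sample-null`,
`enrich`, `train-eval`, `scan-genome`, `pipeline`) ships in
`inst/cli/dsb.R`; `run_pipeline()` executes the whole workflow from a
JSON config and writes TSV artifacts plus a reproducibility manifest.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — simulate the synthetic world, sample matched controls,
featurize, train forest and lasso, evaluate with the bootstrap, and scan
the genome in 250-base bins — and writes a JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness flows from `--seed`; progress and headline numbers are
printed to stderr.

See `vignettes/dsb-prediction-methods.Rmd` for the full account of the
models, encodings, numerical conventions, and what the synthetic world
does and does not establish.
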