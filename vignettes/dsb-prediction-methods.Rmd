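---
title: "Predicting DNA double-strand breaks: models, encodings and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA double-strand breaks: models, encodings and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbpredict)
```

## The problem

Endogenous DNA double-strand breaks (DSBs) are not scattered uniformly over
a genome: they concentrate in accessible, active chromatin. Assays such as
DSBCapture or BLESS map DSB ends and yield peak calls at sub-kilobase
resolution (typical peak median around 391 bases). `dsbpredict` asks the
complementary question: given only the epigenomic context (ChIP-seq and
DNase-seq peak tracks), DNA motif content and DNA shape, how well can DSB
sites be predicted — and which features carry the signal?

The workflow has three steps:

1. **Sites.** DSB peaks (optionally the intersection of two biological
   replicates, via `intersect_replicates()`) form the positive class.
   Non-DSB control sites are drawn at random from the genome, matched
   per-site to the positives on length, GC content and repeat (soft-mask)
   content (`sample_matched_negatives()`). Matching prevents the
   classifier from keying on raw sequence composition.
2. **Features.** Every site is encoded identically
   (`featurize_sites()`): the fraction of its bases covered by each peak
   track (a peak over 60% of a site contributes `x = 0.6`), the number of
   position-weight-matrix motif hits at a minimum relative score of 0.8,
   and 48 DNA-shape summary statistics.
3. **Models.** A random forest (500 Gini-split trees,
   `mtry = floor(sqrt(p))`, scores = vote fractions, permutation variable
   importance on the out-of-bag sample) and an L1-penalized logistic
   regression with cross-validated penalty. Evaluation uses ROC and
   precision-recall curves on a held-out split, with a percentile
   bootstrap (2000 replicates by default) for the AUROC confidence
   interval.

## Encodings and their conventions

**Coordinates.** Everything is 0-based half-open (BED). Readers convert at
the boundary; there is exactly one internal convention.

**Replicate intersection.** `intersect_replicates()` keeps the *full*
first-replicate peak when it overlaps the second replicate by at least one
base. Clipping to the overlap is available (`clip = TRUE`) but off by
default: retained whole peaks are consistent with the observed peak-size
distribution, and nothing in the procedure forces clipping. This is a
genuinely open choice, hence the switch.

**Occupancy.** `overlap_fraction()` merges track peaks before counting
covered bases, so the encoding is invariant to how a covering peak happens
to be split — the fraction is a property of coverage, not of peak
bookkeeping.

**Motifs.** JASPAR position frequency matrices are converted to log2-odds
weight matrices with a total pseudocount of 0.8 distributed by the
background (uniform by default; both are configurable and declared rather than
inferred, since the scanning convention itself fixes neither). A window scores on the min–max-normalized scale:
`rel_score = (score - min) / (max - min)` over the PWM's attainable
extremes, and the classical "80% matching score" is `rel_score >= 0.8`.
Both strands are scanned, overlapping hits all count, windows containing
`N` are skipped.

**Shape.** Four features are predicted by sliding-pentamer lookup: minor
groove width (MGW, Å) and propeller twist (ProT, °) at base resolution,
roll and helix twist (°) at step resolution. The consumed table carries one
value per pentamer per feature; for the step-level features this is the
mean of the two central steps, which gives uniform vector lengths — a
declared flattening choice. Each site is then summarized per feature
by 11 quantiles (0, 10, …, 100%, linear interpolation between order
statistics — R's type 7) plus the
*population* variance: 4 × 12 = 48 predictors. Quantile type and variance
convention are fixed and documented so results are exactly reproducible.

**Enrichment.** Colocalization is compared between classes in 2×2 tables;
association is the odds ratio `(a·d)/(b·c)`, significance a two-sided
Fisher exact test (chosen for validity at small counts; the suite
cross-checks it against exhaustive hypergeometric enumeration). Zero cells surface as 0/`Inf` flags unless
the Haldane 0.5 correction is requested, so reports never shift silently.
Multiple testing uses Bonferroni or Benjamini–Hochberg. Logistic
coefficients convert to odds ratios as `exp(beta)`.

## The matched-control sampler

Candidates are placed uniformly on the genome and accepted when they
contain at most 10% `N`, match their paired positive's GC within 0.02 and
repeat fraction within 0.05 (absolute), and overlap neither the exclusion
set nor an already accepted negative. Matching is deliberately *per site*
rather than distribution-level: it is stricter, trivially verifiable
(recompute the composition of what was emitted), and implies
distribution-level matching. Each negative takes its positive's exact
length, so the size multiset is preserved exactly. Sites that cannot be
matched within the attempt budget are dropped with a warning; more than 5%
unmatched is a hard error, because silently thinning the control set would
bias downstream class ratios. Rejection against the genome's own
composition slightly tilts accepted candidates toward the genome mean
within the tolerance window; this is bounded by the tolerance and visible
in `composition_report()`.

## Classifiers and evaluation

The forest is implemented in C++ inside the package (no forest
implementation ships in the target environment): bootstrap resampling,
per-node feature subsampling, unbounded depth, leaf majority votes.
Variable importance is the mean decrease in out-of-bag accuracy under
per-feature permutation, averaged over trees — importances are
comparable across features but, like all permutation importances, split
credit between correlated predictors.

The lasso is `glmnet` with binomial deviance cross-validation;
coefficients are reported on the original feature scale at `lambda.min`
(`lambda.1se` selectable). Unpenalized logistic regression
(`train_logistic()`) supplies Wald p-values; (quasi-)separation is
detected (diverging coefficients, non-convergence, or numerically 0/1
fitted probabilities) and raised as an error recommending penalization,
because the MLE does not exist there.

AUROC integrates the threshold-sweep ROC by trapezoid, which equals the
Mann–Whitney concordance with ties counted ½ (the suite verifies this
against brute-force pairwise enumeration). AUPR uses the step-wise,
non-interpolated integral: linear PR interpolation is optimistically
biased, and the step integral is the conservative choice under the heavy
class imbalance of genome-wide scanning. The bootstrap CI resamples test
rows with replacement (plain, unstratified; resamples that lose a class
are redrawn) and takes the 2.5/97.5 percentiles, so with small test sets
the point estimate can sit near a CI edge.

Genome-wide prediction tiles chromosomes into 250-base bins
(`bin_genome()`, trailing partial bins truncated rather than dropped so
coverage is conserved), featurizes them with *the same encoders as
training* — a round-trip the tests check bit-for-bit — and scores them.
High/low calls default to score thresholds (0.25, 0.75); no principled
cutoff exists a priori, so these are explicit configuration
with the middle band left unassigned and excluded from validation
profiles. `signal_by_score()` stratifies an independent signal by score
quantile; a genuine break signal should rise with the score, while a
megabase-spreading damage mark (γ-H2AX-like) can fall at precisely
predicted break points. Transfer to another cell type or assay
(`transfer_predict()`) refuses silently-missing features: the feature
intersection must be chosen before training, never imputed.

## The synthetic world

Everything is testable offline because the package ships its own
generator:

* **Genome** — i.i.d. bases at GC 0.41 with lowercase repeat blocks
  (~30%, mean block 500 b), the composition regime of the human genome.
* **Sites** — non-overlapping, sizes log-normal with median 391 b
  (the observed DSB peak median) truncated to [100, 2000] b; the
  dispersion (σ_log = 0.5) is a package default — only the median is
  pinned by observation. Controls reuse the positive size draws. Placement samples
  uniformly among all feasible positions via gap bookkeeping, so it never
  fails while space remains.
* **Marks** — each site receives a peak of each mark with the mark's
  conditional probability: defaults 0.91/0.11 (DNase-like), 0.25/0.02
  (CTCF-like), 0.74/0.11 (H3K4me2-like) — the strong observed
  colocalization contrasts. Peak centers are jittered (small for
  accessibility/factor marks, large for the histone mark, giving the
  centered-versus-shoulder average-profile structure) and peaks are
  clipped to their site's free territory so they never touch a
  neighbouring site. That clipping is what makes the realized conditional
  frequencies exactly Bernoulli; the presence vector is additionally
  redrawn (bounded) until within 3 binomial sd of specification, so a
  generated world always states its own probabilities.
* **Motifs** — consensus copies are overwritten into sites with per-class
  probabilities chosen to hit a target odds ratio over a background rate.
* **Shape table** — a deterministic synthetic stand-in: seeded values per
  canonical pentamer within plausible ranges (MGW 2.8–6.2 Å, ProT −16–0°,
  Roll −8–8°, HelT 30–38°), copied to reverse complements so the
  structural symmetry invariant holds exactly. It is a *stand-in*: it
  validates the lookup/summarization machinery, not any biophysical
  claim.

What a green test on this world does establish: the encoders, sampler,
classifiers and metrics interlock correctly, planted signal of the stated
strength is recovered (forest AUROC > 0.9, the largest-gap mark ranks
first in importance), and metric behavior under imbalance is reproduced
(stable AUROC, collapsing AUPR at 1:60). What it cannot establish:
performance on real chromatin, where marks are spatially correlated,
peak calls are noisy, and DSB ground truth is itself assay-dependent.
The generator deliberately omits spatial correlation between marks,
copy-number structure and read-level noise.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dsb_experiment(chrom_length = 2e6, n_dsb = 1000, seed = 1)
neg <- sample_matched_negatives(sim$truth$dsb_sites, sim$genome, seed = 2)

pos_f <- featurize_sites(sim$truth$dsb_sites, tracks = sim$truth$tracks)
neg_f <- featurize_sites(neg, tracks = sim$truth$tracks)

data <- assemble_dataset(pos_f, neg_f, test_fraction = 0.3, seed = 3)
forest <- train_forest(data, seed = 4)
evaluate(forest, data, seed = 5)
tidy(forest)

scan <- score_genome(forest, sim$genome, tracks = sim$truth$tracks)
call_high_low(scan)
```

## Known limitations

* Permutation importance shares credit among correlated marks; on real
  data, ranking below the top feature should be read qualitatively.
* The sampler's per-site matching is rejection-based; on small or
  composition-extreme genomes it can legitimately fail (by design, with a
  clear error) rather than degrade matching quality.
* AUPR depends on the class ratio by construction; reported AUPRs are
  only comparable at equal ratios.
* The shape stand-in table carries no biophysical information; analyses
  of real data should load an experimentally derived pentamer table via
  `read_shape_table()`.
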