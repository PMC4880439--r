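# snvconsensus

An R framework for building calibrated consensus predictors of single-nucleotide
variant (SNV) deleteriousness from the raw scores of arbitrary external
prediction tools.

Many tools score how damaging a genomic variant is likely to be, but their
scores live on incompatible scales, their optimal decision cutoffs differ by
genomic context, and no single tool dominates everywhere. `snvconsensus`
implements the full meta-prediction recipe around such tools:

1. **Categorize** each SNV into one of five genomic categories — regulatory,
   splicing, missense, synonymous, nonsense — from gene models (GFF3/GTF) and a
   reference FASTA.
2. **Learn a decision threshold** per tool × category that maximizes normalized
   (balanced) accuracy on labeled training variants.
3. **Calibrate** each tool's raw score into a binary prediction plus an integer
   confidence on a uniform 0–99 scale, using a binned observed-accuracy
   transform (equal-count bins, moving-average smoothing, side-specific
   accuracy for deleterious vs. neutral calls).
4. **Combine** the calibrated tools by confidence-weighted majority vote into a
   consensus score, select the best-performing tool subset per category, and
   re-calibrate the consensus itself so its confidences are also observed
   accuracies.
5. **Evaluate** with balanced accuracy, AUC, MCC, per-category threshold
   comparisons, inter-tool score correlation and prediction-agreement matrices.

The package also ships dataset-construction utilities (overlap filtering
against disease databases, nearest-position neutral matching, strict
date-cutoff splits, sequence-identity-clustered splits) and a first-class
synthetic-data module: a controllable multi-tool score generator and a small
synthetic genome with planted variants of every category, used throughout the
test suite.

## The model

For a tool *t* with polarity "higher is deleterious", category *c*, and
threshold θ<sub>t,c</sub>, the prediction is **D** iff score ≥ θ<sub>t,c</sub>.
Thresholds are chosen from the midpoints of consecutive distinct training
scores (plus one candidate beyond each extreme) to maximize

> normalized accuracy = (sensitivity + specificity) / 2,

breaking ties toward higher sensitivity.

For calibration, training variants are sorted by raw score and split into up to
66 equal-count bins; the per-bin fraction of deleterious labels is smoothed by
a centered moving average over 11 neighboring bins (truncated at the edges).
The confidence of a prediction at raw score *s* is the smoothed fraction
interpolated at *s* for a **D** call, or its complement for an **N** call,
mapped to `min(99, round(100·a))`.

The consensus score of tools *T* at a variant is

> S = Σ<sub>t∈T</sub> w<sub>t</sub>·v<sub>t</sub> / Σ<sub>t∈T</sub> w<sub>t</sub>,

with votes v<sub>t</sub> ∈ {+1, −1} and weights w<sub>t</sub> =
confidence<sub>t</sub>/100. Per category, all tool subsets of size ≥ 2 are
scanned; the subset with the best training normalized accuracy (ties: fewer
tools) wins, and the consensus score is thresholded and calibrated exactly like
a single tool.

## Worked example

Simulate scores from five tools (three informative higher-is-deleterious
tools, one informative tool whose scale points the other way, and one pure
noise tool), train the full model, and predict held-out variants:

```r
library(snvconsensus)
library(dplyr)

spec <- score_sim_spec(n_per_class = 1000, seed = 42)
sim <- simulate_scores(spec)
train <- filter(sim, split == "train")
test  <- filter(sim, split == "test")

bundle <- train_model(train, spec$specs)
bundle
#> <model_bundle> 5 tools, 5 categories
#> <consensus_model> category=regulatory tools={toolA, toolB, toolC, toolD} train NA=0.978 (best single: toolA 0.908)
#> <consensus_model> category=splicing tools={toolA, toolB, toolD} train NA=0.976 (best single: toolA 0.899)
#> <consensus_model> category=missense tools={toolA, toolB, toolC, toolD} train NA=0.975 (best single: toolA 0.901)
#> <consensus_model> category=synonymous tools={toolA, toolB, toolD} train NA=0.981 (best single: toolA 0.914)
#> <consensus_model> category=nonsense tools={toolA, toolB, toolD} train NA=0.975 (best single: toolA 0.903)
```

The noise tool is excluded from every selected subset, and the learned
thresholds differ by category, tracking the simulated score shifts:

```r
tidy(bundle$thresholds)
#> # A tibble: 25 × 6
#>    tool  category   polarity              threshold train_normalized_accuracy n_used
#>    <chr> <chr>      <chr>                     <dbl>                     <dbl>  <int>
#>  1 toolA regulatory higher_is_deleterious     0.534                     0.908   1000
#>  2 toolA splicing   higher_is_deleterious     0.629                     0.899   1000
#>  3 toolA missense   higher_is_deleterious     0.723                     0.901   1000
#>  4 toolA synonymous higher_is_deleterious     0.392                     0.914   1000
#>  5 toolA nonsense   higher_is_deleterious     0.691                     0.903   1000
#>  6 toolB regulatory higher_is_deleterious     0.488                     0.884   1000
#>  # ... 19 more rows
```

Predict the held-out half and evaluate:

```r
preds <- predict_variants(test, test, bundle)
select(preds, pos, category, consensus_prediction, consensus_confidence,
       toolA_pred, toolA_conf)
#> # A tibble: 5,000 × 6
#>      pos category   consensus_prediction consensus_confidence toolA_pred toolA_conf
#>    <int> <chr>      <chr>                               <int> <chr>           <int>
#>  1     2 regulatory D                                      99 D                  99
#>  2     4 regulatory D                                      98 D                  99
#>  3     6 regulatory D                                      99 D                  88
#>  4     8 regulatory D                                      59 N                  94
#>  ...

report <- evaluate_model(test, bundle)
filter(report, aggregation == "macro") %>%
  select(predictor, normalized_accuracy, auc, mcc)
#> # A tibble: 6 × 4
#>   predictor normalized_accuracy   auc     mcc
#>   <chr>                   <dbl> <dbl>   <dbl>
#> 1 consensus               0.969 0.996 0.938
#> 2 noise                   0.501 0.505 0.00110
#> 3 toolA                   0.907 0.971 0.816
#> 4 toolB                   0.870 0.949 0.742
#> 5 toolC                   0.840 0.924 0.682
#> 6 toolD                   0.782 0.874 0.568
```

The consensus beats the best single tool by about six balanced-accuracy points
on held-out data. Models persist losslessly to JSON (`save_model()` /
`load_model()`), and predictions export as TSV or annotated VCF
(`write_predictions()`).

For the genomic side, `simulate_genome()` builds a FASTA + GFF3/GTF fixture
with multi-exon genes on both strands and planted variants of every category,
and `classify_variants()` recovers the planted truth:

```r
fx <- simulate_genome(seed = 1)
all(classify_variants(fx$variants, fx$models)$category == fx$variants$category)
#> [1] TRUE
```

Plotting helpers (`autoplot()` on curves, threshold models and reports,
`plot_reliability()`, `plot_score_distributions()`) and broom-style `tidy()` /
`glance()` methods are available for all fitted objects. See the methods
vignette (`vignettes/consensus-methodology.Rmd`) for the full description of
the algorithms, parameter choices, and limitations.

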