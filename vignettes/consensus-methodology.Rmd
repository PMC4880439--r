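---
title: "Consensus methodology: thresholds, calibration, and the weighted-vote ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus methodology: thresholds, calibration, and the weighted-vote ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvconsensus)
library(dplyr)
```

This vignette documents the algorithms in `snvconsensus`, the parameter
defaults and their rationale, the numerical conventions that make results
reproducible to the bit, and the known limitations.

## 1. The five-way categorization

Every SNV receives exactly one of five categories, decided against a set of
transcript models (`read_gene_models()` on GFF3/GTF + FASTA):

* **nonsense** — a CDS substitution whose affected codon becomes a stop codon
  while the reference codon was not one;
* **missense** — any other CDS substitution changing the encoded amino acid
  (start-codon and stop-codon losses are counted here: the residue changes);
* **splicing** — an intronic position within `splice_window` bases of an exon
  boundary of any transcript;
* **synonymous** — a CDS substitution leaving the residue unchanged;
* **regulatory** — everything else: intergenic, deep intronic, UTR/non-coding
  exonic, flanking sequence. It is defined as the *remainder*, so the
  categorization is total.

Coding calls are codon-local: the affected codon is located via the spliced
CDS coordinate (reverse-complemented for minus-strand transcripts) and only
that codon is retranslated. The test suite proves this equals whole-protein
retranslation for every possible CDS SNV of a simulated multi-gene,
both-strand genome.

When transcripts disagree, the most severe call wins:
nonsense > missense > splicing > synonymous > regulatory. The variant's `ref`
allele is checked against the reference sequence; a mismatch is an error
naming the offending position, since silently mis-anchored variants would
poison every downstream step.

`splice_window = 2` by default: the canonical donor/acceptor dinucleotides
(GT/AG) are the near-universally essential splice positions. The window is a
parameter because annotations with broader splice-region conventions exist.

## 2. Threshold learning

For tool $t$ with polarity "higher is deleterious", the rule is
$\text{D} \iff s \ge \theta$. Scores are negated internally for
lower-is-deleterious tools, so one implementation serves both polarities.
`optimize_threshold()` maximizes normalized (balanced) accuracy,
$(\text{sens} + \text{spec})/2$, which is insensitive to class imbalance and
equals plain accuracy on the 1:1-balanced datasets the builders construct.

Candidates are the midpoints of consecutive *distinct* sorted scores plus one
candidate below the minimum and one above the maximum (allowing the degenerate
all-D / all-N rules). Only these candidates can change the confusion matrix,
so the search is exact. Ties in normalized accuracy break toward the higher
sensitivity, i.e. the lowest threshold on the oriented scale — when accuracy is
equal, missing a deleterious variant is considered the worse mistake. The
implementation is an $O(n \log n)$ cumulative-count sweep; the test suite
checks exact equality (argmax value *and* tie-broken argument) against an
exhaustive per-candidate scan on a thousand random instances.

Thresholds are learned **per tool × category**. Class-conditional score
distributions genuinely shift between genomic contexts, so a pooled threshold
is systematically suboptimal; `compare_thresholds()` quantifies the gain, and
an acceptance test demonstrates it is strictly positive on a two-category
fixture with shifted means.

## 3. Score calibration

`fit_confidence_curve()` turns raw scores into observed accuracies:

1. sort training variants by raw score;
2. partition into $B = \min(66, \lfloor n/2 \rfloor)$ equal-count bins
   (base size $\lfloor n/B \rfloor$; the remainder is distributed one extra
   point per bin starting from the lowest-score bin);
3. compute each bin's fraction of deleterious labels;
4. smooth with a centered moving average over `window = 11` bins, truncating
   the window symmetrically at the edges (bin $i$ of $B$ averages over
   half-width $\min(5, i-1, B-i)$, so the first and last bins are left as-is
   rather than padded).

The defaults 66 and 11 target training sets of thousands of variants; the
$\lfloor n/2 \rfloor$ reduction keeps at least two points per bin on small
data, and fewer than four points is an error — a curve from three points is
noise. Fitting also rejects constant scores, where the transform would be
undefined.

`transform_score()` produces the final `(prediction, confidence)` pair. The
smoothed fraction-deleterious is interpolated linearly between bin centers
(mean raw score per bin) and clamped to the outermost bin value beyond the
training range. The two sides use complementary transforms: the confidence of
a **D** call is the fraction itself; of an **N** call, its complement. The
integer confidence is $\min(99, \text{round}(100 a))$ — a 0–99 scale, so a
stated confidence is always an empirical accuracy, never a certainty claim.
Missing scores propagate as `NA` prediction and confidence.

Curves are fit on the *training* split and all calibration claims are
evaluated on held-out data; the test suite requires every held-out
confidence decile of every simulated tool to sit within 0.10 of its empirical
accuracy. `reliability_table()` groups by quantile breaks of the confidence so
that tied confidence values always share a group; splitting ties by row order
would manufacture groups correlated with the input ordering rather than with
confidence.

## 4. The consensus

With calibrated votes $v_t \in \{+1, -1\}$ (D/N) and weights
$w_t = \text{conf}_t / 100$, the consensus score is

$$ S = \frac{\sum_{t \in T} w_t v_t}{\sum_{t \in T} w_t} \in [-1, 1], $$

over the tools with available scores at that variant (all-missing gives
$S = 0$). The consensus is then treated *exactly like another tool*: a
consensus threshold is learned on training consensus scores (ties in the vote,
$S$ at the threshold, resolve to D via the inclusive rule) and a consensus
calibration curve maps $S$ to a 0–99 confidence.

**Subset selection.** Per category, `select_consensus_subset()` enumerates
every tool subset of size ≥ 2 (26 subsets for five tools), re-learns the
consensus threshold for each, and keeps the subset with the highest training
normalized accuracy — ties prefer fewer tools, then lexicographic order, so
selection is deterministic. Weak tools genuinely drag the vote down, and the
acceptance suite verifies the selected subset is never worse than the
all-tools consensus in a fixture with injected noise tools. Subsets whose
consensus scores cannot be calibrated (e.g. constant) score `NA` and are
skipped; if no subset is fittable the best single tool is used. The best
single tool and the full subset scan are stored on the model for inspection
(`tidy()` on a `consensus_model`).

Why the ensemble helps at all: for five conditionally independent tools at
balanced accuracy 0.7 with equal weights, the majority vote is
right when at least three tools are, $P(X \ge 3), X \sim \text{Bin}(5, 0.7)$
$= 0.837$ — and the acceptance suite reproduces this number empirically.
Correlated tools gain less, which is why the score simulator exposes an
inter-tool correlation parameter `rho`.

## 5. Dataset construction

* `remove_overlaps()` drops neutral variants whose **allele-specific** key
  (chrom, pos, ref, alt) appears in any disease set — positional overlap alone
  would discard legitimate neutral alleles at multi-allelic sites.
* `match_neutral()` pairs each deleterious variant with the closest available
  neutral variant on the same chromosome, greedily in (chrom, pos) order and
  without replacement; distance ties take the lower position (deterministic).
  Unmatched deleterious variants are dropped with a warning, keeping the
  result exactly 1:1 balanced.
* `split_by_date()` sends a variant to the test set iff its date is strictly
  *after* the cutoff; a matched pair follows its deleterious member so pairs
  never straddle the split.
* `cluster_split_exonic()` avoids homology leakage: protein sequences are
  clustered greedily from longest to shortest, joining a cluster when the
  alignment identity to its *representative* is ≥ 0.50 (identity = matches
  divided by the shorter sequence length, global affine-gap alignment with
  match 1, mismatch 0, gap opening 1, extension 0.5). Whole clusters are then
  assigned to train or test. The greedy longest-first scheme is the standard
  fast clustering heuristic at this identity level.

## 6. The synthetic-data module

`simulate_scores()` draws class-conditional Gaussian scores for five tools ×
five categories with controllable separation, category-specific shifts, one
deliberately information-free "noise" tool, and one lower-is-deleterious tool
(so both polarities are exercised everywhere). Inter-tool correlation uses an
equicorrelated latent Gaussian: $z_t = \sqrt{\rho}\, z_{\text{shared}} +
\sqrt{1-\rho}\, z_t^{\text{ind}}$. The train/test split alternates variants,
preserving exact class balance. These defaults are the study conditions for
the test suite; they were chosen a priori from the generating model (e.g. the
analytic optimal threshold for equal-variance Gaussians is the midpoint of the
class means) and are not tuned to test outcomes.

`simulate_genome()` builds a deterministic synthetic genome: multi-exon genes
with ATG…stop CDSs on alternating strands, GT…AG introns, and planted
variants of all five categories whose truth is established *by construction*
(whole-CDS retranslation for coding variants, positional placement for
splicing/regulatory). `write_genome_fixture()` emits byte-stable FASTA, GFF3,
GTF and TSV files for any seed, which the I/O tests round-trip.

Known realism limits: scores are Gaussian with a single shared correlation
(real tool scores are skewed, multimodal, correlated blockwise); genes do not
overlap and lack UTRs (UTR handling is still exercised via non-coding-exon
paths in unit fixtures); the genome has a single chromosome.

## 7. Numerical and engineering conventions

* Deleterious iff score ≥ threshold — inclusive, favoring sensitivity.
* Vote ties ($S$ exactly at the consensus threshold) resolve to D for the same
  reason.
* Interpolation of calibration curves uses `stats::approx(rule = 2)`:
  constant extrapolation beyond the outermost bin centers.
* Confidence is capped at 99, never 100.
* Model persistence (`save_model()`/`load_model()`) writes JSON with 17
  significant digits, which round-trips IEEE doubles exactly; the test suite
  asserts bit-identical thresholds, curves and re-loaded predictions. A
  `schema_version` field guards against reading incompatible files.
* All stochastic components (simulators, random splits) take explicit seeds
  and are pure functions of them.

## 8. Problem sizes and limitations

The test suite runs at desk scale: thousands of simulated variants per
category, genomes of 3–10 genes, tool counts up to five (26-subset scans;
enumeration is exponential in the number of tools and is intended for small
panels — beyond ~15 tools a heuristic search would be needed).

Calibration of the *consensus* is harder than of a single tool: consensus
scores concentrate near ±1, so few bins cover the disagreement region and the
11-bin smoothing can leave the lowest-confidence decile underconfident by
~0.1 on held-out data. Single-tool transforms show held-out decile gaps well
under 0.10. Users who need sharper consensus calibration near the decision
boundary can lower `window` when training (`train_model(..., window = ...)`).

The categorizer intentionally implements substitution consequences only — it
is an SNV framework; indels, MNVs and structural variants are rejected at
input. Severity aggregation reports a single category per variant; per-
transcript calls are available in the `detail`/`transcript_id` columns of
`classify_variants()`.
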