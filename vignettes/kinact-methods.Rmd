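---
title: "Methods: kinome peptide-array analysis with permutation-based upstream kinase scoring"
author: "kinact authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinome peptide-array analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinact)
```

## The scientific problem

Tyrosine-kinase peptide microarrays measure the phosphorylation of short
substrate peptides incubated with a tissue lysate; each peptide's end-level
kinetic signal proxies the activity of the kinases able to phosphorylate
it. In ER+ breast cancer, the clinical question is whether loss of the
progesterone receptor (PR) — a marker of worse prognosis within ER+/HER2−
disease — is accompanied by a distinct kinase activity profile. `kinact`
implements the full analysis chain for this question: array preprocessing,
per-substrate differential phosphorylation between PR+ and PR− tumors,
permutation-based upstream kinase inference, and an expression/survival
cohort stage that cross-validates the kinase hits at the mRNA level.

Because the raw tumor arrays, the proprietary kinase–substrate prediction
database, and the access-controlled expression cohort are not available at
desk scale, the package ships seeded generators that emulate those data
sources with known ground truth. Every statistical claim the test suite
makes is a claim about recovery of planted structure, not about the
original tumors.

## Preprocessing model

The raw input is a non-negative signal tensor (peptides × samples ×
technical replicates) with saturation flags. Three rules are applied, in
this order:

1. **Saturation masking.** A flagged spot's intensity is censored at the
   scanner ceiling and carries no usable quantitative information, so it is
   treated as missing; peptides with no unmasked entry are dropped.
2. **Replicate collapsing.** Technical replicates are averaged on the raw
   scale and then log2-transformed. Replicate agreement is judged by the
   coefficient of variation on the raw scale; when it exceeds
   `replicate_cv_max` (default **0.5**), the single replicate farthest from
   the replicate median is excluded before averaging. The CV rule is a
   deterministic, single-pass stand-in for an unquantified "high variation"
   exclusion; the threshold is configurable because scanner noise differs
   between platforms.
3. **Detection filtering.** A peptide is *detected* in a sample when its
   collapsed value is non-missing and strictly above `detection_floor`
   (default 0 on the log2 scale). Peptides detected in fewer than
   `min_detect_frac` (default **0.25**, boundary inclusive — "at least
   25%") of samples are removed.

Sample identifiers and their order are never modified by preprocessing, and
the detection filter is idempotent. If the tensor is supplied already
log2-transformed (`input_scale = "log2"`), it is converted back to the raw
scale internally so the CV rule and the averaging behave identically.

## Differential phosphorylation

Within a receptor stratum (default ER+/HER2−), each peptide is tested with
a **Welch two-sample t-test** on log2 values between the PR groups, with
missing values dropped pairwise. Welch's test was chosen because
log-intensity data routinely violate equal-variance assumptions and the
reported group means are consistent with a mean-difference statistic. The
log fold change is `lfc = mean(PR+) − mean(PR−)`, so negative values mean
higher phosphorylation in PR− tumors. Multiplicity is handled by
Benjamini–Hochberg across all tested peptides, reported as `q`. Peptides
with fewer than two non-missing values in a group, or no variance in
either group, are skipped with a log entry.

Unsupervised peptide clustering uses agglomerative hierarchical clustering
(Euclidean distance, complete linkage — the defaults of the heatmap tools
standard in this field) cut at `k = 3`, matching the empirical structure of
these arrays: peptides separate into high-, moderate- and low-
phosphorylation groups. Per-cluster sample means with pairwise Welch tests
summarize subgroup differences.

## Upstream kinase analysis

Upstream kinase analysis asks which kinases best explain the observed
group difference, given predicted kinase → substrate sets (GMT format,
optionally with positive prediction weights).

* **Per-substrate effect.** `delta = (mean(PR−) − mean(PR+)) / pooled sd`,
  the standardized mean difference on log2 values. Substrates with zero
  pooled variance are excluded from the scoreable universe.
* **Kinase statistic.** `tau` is the weighted mean of `delta` over the
  kinase's predicted substrates (uniform weights when predictions carry no
  rank scores). By the sign convention, `tau > 0` means lower activity in
  PR+ samples. The aggregate used by the original scoring engine is
  proprietary; a weighted standardized-mean-difference average is the
  simplest statistic to which both permutation nulls below apply, and it is
  documented here as this package's own choice.
* **Q-scores.** `Q = −10·log10(max(m/M, 1/M))` where `m` counts the
  permutations whose `|tau_p|` strictly exceeds `|tau|` (ties never
  count). The logarithm is base 10, the established convention for
  Phred-like scores, so `Q` is capped at `10·log10(M)` ≈ 27 for the
  default `M = 500`. The **significance** score permutes sample labels
  within the stratum; the **specificity** score redraws substrate subsets
  of the same size (and weight multiset, applied in drawn order) from the
  scoreable universe. Whenever the number of distinct label assignments or
  subsets is at most `M`, exhaustive enumeration replaces Monte Carlo
  sampling, which makes small instances exactly reproducible and provides
  the suite's central oracle. Kinases are ranked by `q_sig + q_spec`
  descending, ties broken by `|tau|` descending and then kinase name.

Numerical note: the observed and permuted statistics flow through slightly
different floating-point paths (scalar weighted mean vs BLAS matrix
products), so an exact mathematical tie — e.g. the label complement, for
which `tau_p = −tau` — can differ by ~1e−16 between paths. The strict
exceedance count therefore uses a relative guard of 1e−12: genuine
exceedances are unaffected, and exact ties are never counted, as the strict
inequality requires.

Two reproducibility choices matter. Sample-label permutations are shared
across kinases (they permute the same columns), while specificity draws use
a per-kinase RNG stream derived from the seed and the kinase *name*, so the
ranking is invariant to the order the sets are supplied. Monte Carlo
permutations are sampled without uniqueness enforcement — simple,
unbiased, and seeded.

## Expression-cohort integration

The cohort stage validates kinase hits at the mRNA level: per-gene Welch
tests between PR groups in the HER2− stratum with **Bonferroni**
correction (family-wise control is appropriate because the selected genes
are then treated as a fixed signature); restriction of the hits to a
kinome catalogue (a packaged list of ~90 human protein tyrosine kinase
symbols, supplied as an input file, not hard-coded); two-cluster
hierarchical stratification of samples on the signature; and a
Kaplan–Meier / log-rank survival comparison.

Cluster labels are oriented deterministically: cluster 2 is the cluster
with the higher mean expression of the genes up-regulated in PR− samples,
so "cluster 2" is always the PR−-enriched, high-risk cluster regardless of
sample order. The log-rank test and the product-limit estimator are
implemented from their defining formulas (the hypergeometric
observed-vs-expected tables at each event time); the `survival` package
serves only as an independent cross-check in the test suite. Candidate
regulators are the kinases present in both the upstream ranking and the
differentially expressed kinome genes, annotated with the direction of
their activity difference and their expression fold change.

## Synthetic-data generators

`simulate_array()` draws log2 signal as
`baseline(peptide) + effect(kinase) · 1[substrate of kinase] · 1[PR−,
HER2−] + sample noise + replicate noise`, then converts to the raw scale,
clips and flags at a saturation threshold, and applies Bernoulli dropout.
Defaults emulate the profiled design: **144 peptides, 29 samples, 3
technical replicates**, baseline log2 level 7 ± 1.5 across peptides,
between-sample noise sd 1 (so planted effects are standardized), replicate
noise sd 0.25, 5% dropout, and a remote saturation ceiling of 2^16 so
saturation is rare unless provoked. The PR+/HER2− label fractions (0.75 /
0.7) mirror the predominantly PR+ composition of an ER+ series. Driver
effects raise PR− samples, matching the direction observed in tumors.

`simulate_cohort()` emulates a desk-scale ER+ cohort: 1000 genes × 300
samples (scaled down from the thousands of genes and ~1000 patients of a
real cohort), 30% PR−, 93% HER2−, and a 24-gene tyrosine-kinase signature
shifted by PR status within the HER2− stratum at magnitude **0.8** — a
moderate, realistic microarray effect. Each sample carries a latent risk
cluster concordant with PR status (probability 0.8), and survival is
exponential with the high-risk cluster's hazard multiplied by
`cluster_hazard_ratio` (default 2; baseline rate 0.012/month, ~30%
exponential censoring). The "recover exactly all 24 signature genes"
property belongs to the *large-effect* regime (magnitude 1.5, where
per-gene power under Bonferroni is essentially 1); at the moderate default
a gene occasionally fluctuates below the family-wise threshold, which is
the realistic behaviour, not a defect.

What the generators deliberately do **not** model: kinetic read cycles,
spatial array artifacts, batch effects across array runs, correlated gene
co-expression modules, and non-proportional hazards. Passing recovery
tests therefore demonstrate correctness of the statistical machinery under
the stated noise model, not robustness to those real-data complications.

## Problem sizes and determinism

The test suite and the acceptance script use: exhaustive permutation
oracles on 3+3 samples (20 label splits) and 4–6-substrate universes (6–20
subsets); driver recovery on 144 peptides × (10+10) samples × 3 replicates
with `M = 500` over 50 seeds; type-I calibration over 20 seeds; and
log-rank power at n = 300 with hazard ratio 2 over 50 seeds. These sizes
were chosen so each property is measured with enough replication to be
stable across seeds while the whole suite stays quick to run. Every
generator and every permutation routine is a pure function of its seed;
the pipeline driver (`run_pipeline()`) splits one top-level seed per stage
and reruns are byte-identical.

## Known limitations

* The kinase statistic and the replicate-exclusion rule are documented
  stand-ins for unpublished, proprietary procedures; rankings will differ
  from the original scoring engine in detail even on identical data.
* The upstream ranking depends entirely on the supplied prediction sets;
  with sparse or biased predictions, specificity scores lose meaning.
* Bonferroni DE selection is conservative by design; users wanting
  discovery-oriented lists should use the BH option and treat the
  signature clustering as exploratory.
* The survival stage implements the two-sample log-rank only; covariate
  adjustment (Cox regression) and multi-group comparisons are out of
  scope.
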