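---
title: "Developing and applying Gram-stain scoring systems for ovine vaginal inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and applying Gram-stain scoring systems for ovine vaginal inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gramscore)
library(dplyr)
```

## The problem

Before a vaginal product (a microbicide gel, an intravaginal ring) can be
tested in people, regulators expect evidence that it does not inflame the
mucosa or disturb the vaginal microbiome. The sheep is a standard large-animal
model for this work, but the reference assays — cytokine ELISAs, 16S
sequencing, qPCR community typing — are slow and equipment-heavy. A
Nugent-style score read off an ordinary Gram-stained smear under a ×100
oil-immersion lens would let any laboratory quantify inflammation cheaply.

`gramscore` implements such a scoring system for ovine vaginal smears and,
just as importantly, the workflow that produces and validates one:

1. **Reference labels.** Per-sample cytokine optical densities (TNF-α, IL-8,
   IL-1β, CXCL10) are categorized against within-cohort percentile splits and
   combined by a k-of-n rule into a binary inflamed/normal label.
2. **Stratified subsamples.** The labeled cohort is partitioned into
   statistically equivalent subsamples stratified by vaginal-microbiome
   community type (CT), so each development iteration can be validated
   prospectively on held-out slides.
3. **Weighting.** Per-field morphotype counts are compared between the
   inflamed and normal groups with two-sample t-tests; significant categories
   earn rule weights from p-value bands (smaller p, more points).
4. **Scoring.** A scoring matrix is a set of threshold rules ("fewer than 15
   Gram-negative rods = 2 points"); an image's score is the sum of points of
   the rules that fire, and a sample's score is the mean over its imaged
   fields.
5. **Evaluation.** Scores are compared with the cytokine labels via
   concordance, an ROC cut-off sweep with its AUC, and the Youden-optimal
   cut-off.

## The scoring model

An observation is one imaged field with counts for eleven categories:
Gram-positive cocci, rods, diplococci and pleomorphic forms; Gram-negative
cocci, short rods and long rods; immune cells; mature, intermediate and
parabasal epithelial cells — plus a 0–3 mucus grade and a scant-bacteria
flag. A matrix rule awards `points` when its predicate holds:

* `lt` / `gt` are strict: a count exactly at the threshold scores nothing,
  matching how the published rule cells are written.
* `range` is inclusive on both ends and applies to real-valued (averaged)
  inputs, so a mean diplococcus count of 0.4 satisfies "0–1" while 1.5 does
  not.
* `eq0` fires only on exact zero, also for real-valued inputs. These rules
  encode per-field presence/absence, and "almost absent on average" is not
  absence; we deliberately do not soften the comparison to `< 0.5`.

The derived category `gn_rods_combined` (short + long Gram-negative rods) is
computed on the fly whenever a matrix references it.

Eight published matrices ship with the package (`builtin_matrix_ids()`).
Their maximum totals — the sum of rule points — are part of the test suite.
The `v2.2` config keeps its zero-weighted Gram-positive rod cell exactly as
printed; the printed maximum of 10 only sums correctly with that zero, which
is why zero-point rules are legal here even though they contribute nothing.

```{r}
builtin_matrix("final_reduced")
```

Two cut-off conventions circulate for calling a score inflamed — "score ≥ 6"
and the Nugent-style "score > 4" — and the field has not reconciled them.
Both are supported via `cutoff_fixed(value, orientation)`; neither is
asserted as canonical. The count-based matrices default to "≥ 6"; the
score-based `vSubC` and `final_reduced` default to a Youden-derived cut-off
that must be resolved against labeled data, and `call_inflamed()` refuses to
guess it.

## Cytokine labeling

The built-in inflammation models are `Infl1` (binary low/high, 3 of 4
cytokines high — the recommended standard), its initial tertile variant,
`Infl2` (tertile, 2 of 4 high), `Infl3` (tertile, IL-8/IL-1β, 1 medium-or-
high) and `Infl4` (binary, IL-8/IL-1β, 1 high). Two descriptions of the
binary split circulate — "above the mean" and "50th percentile"; we default
to the median because the percentile phrasing is the operational one, and
offer the mean as an option. Tertile boundaries are the empirical 33.33rd and
66.67th percentiles of the cohort being labeled; no fixed reference ODs
exist, so thresholds are always recomputed within-cohort unless a persisted
thresholds file is supplied to score new samples against an earlier cohort.
Values exactly at a split fall into the lower category, which makes
relabeling reproducible under ties. A cytokine with constant OD yields a
degenerate threshold: everything is "low" and a warning is raised. IL-6 and
IL-17α are accepted in input but used by no built-in model; they are rarely
detected in ovine vaginal fluid.

## Stratified subsampling and equivalence

`stratified_partition()` honours predetermined subsample sizes (default
A–E = 53, 53, 53, 53, 52 for a 264-sample cohort) while balancing CT strata.
Within each stratum, samples are allocated across subsamples proportionally
and then drawn uniformly without replacement. The allocation is a controlled
rounding of the quota matrix, computed in integer arithmetic and completed
with augmenting paths, so three properties hold simultaneously: every
subsample gets exactly its planned size, every stratum is fully used, and
every stratum-by-subsample count is the floor or ceiling of its exact quota.
Each stratum consumes a seed substream derived from the master seed and the
stratum label, so adding a stratum leaves the other strata's shuffles
untouched.

Equivalence across subsamples is reported two ways. The asymptotic two-sample
Kolmogorov–Smirnov test mirrors common practice, but applying KS to
categorical CT labels requires an ordering; we use a fixed, documented CT
index ordering (alphabetical by default, overridable) and compute D directly
from the ECDFs so ties are unproblematic, with the p-value from the classical
Smirnov series. Because that encoding is a convention rather than a fact
about the data, the report also carries a chi-square homogeneity test on the
CT contingency table, which is the statistically proper categorical check.

## Weighting and evaluation choices

* **t-test variant.** Welch by default: the published group SDs are visibly
  unequal, and the printed (rounded) summaries cannot adjudicate between
  Welch and pooled forms. The pooled "student" variant is an option.
* **Weight bands.** `p < 1e-8` → 3 points, `< 5e-4` → 2, `< 0.05` → 1, else
  excluded. These bands are a package default calibrated once so that the
  printed first-pass p row maps exactly onto the published first-pass weight
  set; they are fully configurable.
* **No multiple-testing correction** is applied across the ~13 category
  tests, matching how such scoring systems are developed; results carry a
  note saying so.
* **ROC.** The reproducible object is the cut-off sweep on the total score
  (higher score ⇒ inflamed; "score ≥ c" calls). Its AUC equals the
  Mann–Whitney probability with ties counted ½ — an identity the tests
  exercise against a brute-force pairwise oracle. The multivariate logistic
  regression is reported as diagnostics only (coefficient signs, separation
  flags); `glm()` can converge onto a separated solution without warning, so
  separation is additionally detected from fitted probabilities numerically
  at 0 or 1.
* **Youden cut-off.** Ties in J are broken toward the lowest cut-off after
  grouping floating-point-equal J values (J differences are multiples of
  1/(n₊·n₋), far above rounding noise).
* **Rounding.** Concordance percentages round half up, as in the published
  concordance tables.
* **Recommendation.** `develop_iteration()` recommends the candidate with
  the highest sample-level AUC, ties broken toward higher concordance and
  then fewer rules (simpler systems are easier to train and audit).

## The synthetic cohort generator

No raw slide images or ODs are released with the study this workflow
reproduces, so the generator emulates the tabular layer the pipeline
consumes. Its defaults are the published subsample A group summaries:

* **Counts** are negative binomial with the published per-status mean/SD per
  category — morphotype counts are strongly overdispersed (variance ≫ mean
  for most categories). Where a target has variance ≤ mean (normal-group
  immune cells at 0.1 ± 0.3, for instance) the negative binomial has no
  parameterization and the generator falls back, with a notice, to a
  discretized normal censored at zero.
* **Within-sample correlation.** The 2–5 fields of one slide share a
  log-scale random intercept (SD 0.2 by default), so per-sample averaging is
  non-trivial rather than a no-op.
* **Mucus and scant bacteria** are presence draws at the published
  prevalences (39% of inflamed and 17% of normal fields for mucus); the
  published summary does not give a per-grade breakdown, so positive fields
  draw a uniform grade in 1–3.
* **Cytokine ODs** are log-normal (sdlog 0.5) with a log-scale shift of 1.2
  for inflamed samples. No OD distributions are published; the shift is
  calibrated to a stated target instead: per-cytokine P(high | inflamed) =
  Φ(1.2) ≈ 0.88 under cohort-median splits with equal groups, giving ≈ 95%
  agreement between Infl1 labels and true status. The config records this
  target (`target_label_agreement = 0.95`) and the tests check agreement
  within ±5 percentage points of it.
* **Quality.** A configurable fraction of fields (5% by default) is marked
  blurry/too-sparse/too-dense/duplicate; only `ok` fields are scoreable, and
  samples whose fields are all excluded yield an explicit missing score,
  never zero.

What passing recovery tests show — and what they do not: the generator
reproduces group-conditional count distributions, within-sample correlation
and label noise, so it exercises every pipeline stage and can detect
regressions in the statistics. It does not reproduce operator disagreement,
image-quality correlations with inflammation status, or the correlation
structure between morphotype categories on real slides; recovery AUCs on
synthetic cohorts (typically ≈ 0.97 at 200 samples per status) are therefore
not estimates of real-data performance, where the published overall average
for the final reduced system is appreciably lower.

## Problem sizes and runtime choices

The test suite exercises the ROC/Youden identities on several hundred random
instances of up to 50 scores, recovery on twenty seeded cohorts of 200
samples per status (each generating and scoring ~1,400 fields in well under a
second), and sign-recovery over forty logistic fits at 50 samples per
status — sizes chosen to make the stochastic checks stable without making
the default test run slow.

## Known limitations

* CT labels are inputs; deriving them from sequencing data is out of scope,
  as are ELISA curve fitting, image processing and any automated morphotype
  recognition — counts come from trained operators or the simulator.
* The published headline AUCs cannot be recomputed without the unreleased
  slide and cytokine data; the package validates the machinery on synthetic
  cohorts instead and makes no claim to reproduce those numbers.
* One published concordance row (144/27/171 → 81%) is arithmetically
  inconsistent (144/171 = 84%) and is not used as a reference point.
* KS on categorical CT encodings is a documented convention, not a canonical
  computation; prefer the chi-square column of the equivalence report when
  the two disagree.
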