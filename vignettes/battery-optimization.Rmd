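---
title: "Deriving minimal androgen-receptor assay batteries"
author: "ARbattery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving minimal androgen-receptor assay batteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ARbattery)
```

## The problem

High-throughput screening programs predict androgen-receptor (AR) agonism
and antagonism with a pathway model built on 14 in vitro assays spanning the
biological steps from receptor binding to downstream reporter readouts. The
full battery is expensive, and several of its assays are no longer
commercially available, so the practical question is: which *subsets* of
the 14 assays support activity predictions that are nearly as good as the
full model, and what is the smallest battery of assays that hosts one
acceptable agonist model and one acceptable antagonist model at the same
time?

ARbattery implements that workflow end to end:

1. **Subset models.** Every combination of 2-14 assays is a candidate
   model, written `"A"` followed by 14 binary characters (character *i* is
   assay A*i*; `A10000000001111` contains A1, A11, A12, A13, A14). There
   are $2^{14} - 15 = 16{,}369$ such subsets, or 16,368 excluding the full
   model; both counts are in circulation, so `enumerate_subset_models()`
   exposes an `include_full` flag rather than resolving the ambiguity.
2. **Pathways.** The agonist pathway spans A1-A11 and the antagonist
   pathway A1-A6 plus A12-A14; a subset model's per-mode pathway is its
   intersection with these sets (`pathway_assays()`).
3. **Scoring.** Each model yields a per-chemical, per-mode pathway AUC
   score, binarized into an active call at the cutoff 0.1 (values *at or
   above* 0.1 are active). Subset-model calls are scored against the
   binarized calls of the 14-assay reference with sensitivity
   $TP/(TP+FN)$, specificity $TN/(TN+FP)$, the Matthews correlation
   coefficient and balanced accuracy (`evaluate_all_models()`).
4. **Qualification.** A model qualifies when sensitivity exceeds 95% *and*
   specificity exceeds 85% (`qualify_models()`); sensitivity is weighted
   ahead of specificity because the intended use is prioritization, where
   false negatives are costly.
5. **Battery optimization.** Over every (qualifying agonist, qualifying
   antagonist) model pair, the assay union is the battery required to run
   both; `minimal_battery()` finds the smallest union and reports *all*
   pairs achieving it (`minimal_battery_search()` is the memory-light
   equivalent for large qualifying sets). `constrained_battery_search()`
   answers the converse question: given a fixed battery size that must
   still host a qualifying antagonist model, how good can the best
   contained agonist model be?
6. **Chemical clustering.** Chemicals are clustered on binary structural
   fingerprints by Tanimoto distance and Ward linkage with a fixed-height
   cut at 1; new chemicals are mapped onto existing clusters by 1-nearest
   neighbour. Clusters are labeled agonist-active / antagonist-active /
   both-effect / no-effect from the activity calls of their members, and
   volatile chemicals (Henry's law constant in the high or moderate
   category) are filtered out before testing.
7. **Prioritization scenarios.** Testing strategies are compared by their
   chemical-assay pair cost, $\sum_i n_i k_i$ over stages
   (`scenario_cost()`, `percent_of_max()`), an overall sensitivity weighted
   by the ~90/10 antagonist/agonist split among active calls
   (`overall_sensitivity()`), cluster-guided battery assignment
   (`cluster_based_assignment()`), and a Monte-Carlo simulation of the
   two-stage workflow (`simulate_multistage()`).

## The multi-stage simulation

Stage 1 screens all chemicals with a small battery whose agonist submodel
has only moderate sensitivity (defaults: 6 assays, sensitivity 0.714,
specificity 0.989). Clusters containing at least one stage-1 agonist
positive — true or false — are carried into stage 2, where *all* of their
chemicals are retested with the additional assays of the larger battery
(defaults: 3 more assays, sensitivity 0.960, specificity 0.977). Design
choices the underlying description leaves open, resolved here and echoed in
the result object:

- **Sampling.** "Sampling a percentage" is implemented as exact-fraction
  sampling without replacement: stage 1 draws `round(sens * n_pos)` true
  positives and `round((1 - spec) * n_neg)` false positives. Counts use
  R's round-half-to-even, which matters only at exact .5 boundaries but
  changes small-n results, so it is fixed and documented. A per-chemical
  Bernoulli mode (`sampling = "bernoulli"`) is available.
- **Final call.** Within selected clusters the stage-2 call supersedes
  stage 1 (stage 2 runs the superset battery); outside them the stage-1
  call stands. Because every stage-1 true positive selects its own
  cluster, detection reduces to the stage-2 draw over the selected
  clusters' true agonists.
- **False positives select clusters.** A stage-1 false positive pulls its
  whole cluster into stage 2 even if the cluster holds no true agonist;
  this inflates cost but not sensitivity.
- **Antagonists.** Antagonist detection is treated as complete at stage 1
  (its 5-assay submodel already qualifies); only agonist detection is
  simulated.
- **Seeding.** A master seed deterministically derives one sub-seed per
  run, so identical inputs and seed give identical results regardless of
  `n_runs` chunking.
- With no true agonists the detection sensitivity is undefined (reported
  `NA`) and the cost is the stage-1 screen only.

## The synthetic-data generator

No external databases are required: `generate_synthetic_dataset()` emulates
every input the workflow consumes, with the statistical structure the
analysis assumes.

- **Classes and prevalences.** Default prevalences are antagonist 0.131,
  agonist 0.009, both-modes 0.003 over 1,820 chemicals — matching a
  screening library in which the full model flags 244 antagonists and 22
  agonists, 6 chemicals being active in both modes.
- **Planted detector assays.** Each active chemical is assigned a primary
  mode-specific detector assay — drawn from A9/A11 for agonists and
  A12/A13/A14 for antagonists — which fires with probability 0.98; the
  other same-mode-specific assays fire at 0.05, the shared upstream assays
  A1-A6 at 0.30, and inactive chemical-assay pairs at a 0.01 false-positive
  rate. This "sole detector" construction is what makes the planted assays
  genuinely indispensable: a model lacking a chemical's primary detector
  sees only weak residual signal, so leaving any planted antagonist assay
  out of the enumeration drops the attainable antagonist sensitivity below
  the 95% qualification threshold, and the minimal battery must contain
  all five planted assays. The rates were chosen for that construction,
  not fitted to any dataset.
- **Surrogate AUC.** The per-chemical, per-mode score is
  `potency * (active pathway assays in model / pathway assays in model)`,
  with potency drawn from U(0.25, 1) for chemicals truly active in that
  mode and U(0, 0.095) otherwise, so the full model binarizes correctly on
  noiseless inputs and the score is monotone in pathway activity. This is
  deliberately *not* the published network-deconvolution AUC model — the
  workflow only consumes binarized calls and rankings, and reproducing the
  deconvolution is out of scope. Do not interpret surrogate AUC magnitudes.
- **Fingerprints.** Each of the (default 560) planted clusters has a
  729-bit prototype with per-bit density 0.2; members flip each prototype
  bit with probability 0.02. Agonist-bearing chemicals are confined to a
  small designated fraction of clusters (default 10/560), mirroring the
  observation that agonists concentrate in few structural clusters.
- **QSAR-like predictions** corrupt the truth with sensitivity 0.95 and a
  false-positive rate 0.03 — false-positive-biased, as consensus QSAR
  predictions for AR activity tend to be conservative.
- **Henry's law constants** are drawn log-uniformly over
  $10^{-9}$-$10^{-1}$ atm m$^3$/mol so the volatility filter always
  exercises all four categories.

What the generator does *not* emulate: real structure-activity
relationships (fingerprints are abstract bit vectors, not ToxPrints),
concentration-response curves, assay-specific noise structure, or the
correlation patterns of a real screening library. Tests passing on
synthetic data therefore demonstrate the correctness of the *computations*
(set algebra, confusion metrics, optimization, clustering, simulation), not
the field performance of any particular assay battery.

## Numerical and design choices

- **Threshold comparisons are strict** (`>`) at full floating precision:
  "greater than 95%" admits 0.952 but not 0.95 exactly. An inclusive mode
  is available via `qualification_criteria(strict = FALSE)`.
- **MCC with an empty marginal** (any of TP+FP, TP+FN, TN+FP, TN+FN zero)
  is defined as 0, the common convention.
- **Chemical alignment is explicit.** Call vectors over different chemical
  sets are an error; `align_calls()` intersects deliberately, mirroring
  analyses that first align two models on their common chemicals.
- **Ward variant.** `ward_cluster()` defaults to the squared-distance
  (`ward.D2`) update applied directly to Tanimoto distances. Ward linkage
  on a non-Euclidean distance is a standard cheminformatics approximation
  rather than an exact minimum-variance procedure; the classic `ward.D`
  form is available. Whether fingerprint bits should be scaled before
  linkage is left to the caller (they are not).
- **Tie-breaks** are deterministic everywhere: minimal-battery pairs are
  all reported (ordering by Hamming distance, antagonist specificity and
  model name is presentational); constrained batteries break ties by
  agonist specificity then lexicographic battery name; 1-NN assignment
  ties go to the lowest cluster id.
- **Empty fingerprints.** Distance between two all-zero fingerprints is 0
  (identical objects); empty vs non-empty is 1.
- **Volatility thresholds** default to high $> 10^{-3}$, moderate
  $> 10^{-5}$, slight $> 10^{-7}$ atm m$^3$/mol. These are configurable
  placeholders for the regulatory aqueous-volatilization cutoffs, which
  the workflow description cites but does not restate; they should be
  replaced with the authoritative values when available. Chemicals with a
  missing constant are retained and flagged, never silently dropped.
- **Problem sizes.** The package's own validation uses the full study
  scale where it matters — 1,820 chemicals against all 16,368 subset
  models plus the reference, clustering of all fingerprints, and a
  1,000-run simulation — which completes in well under a minute of
  arithmetic-heavy matrix work; unit tests use smaller configurations
  (tens to hundreds of chemicals) because they check exact equivalences
  against brute-force oracles, where size adds nothing.

## Worked example

```{r example, eval = FALSE}
library(ARbattery)

ds <- generate_synthetic_dataset(seed = 1)
models <- c(enumerate_subset_models(include_full = FALSE),
            "A11111111111111")

summaries <- lapply(c(agonist = "agonist", antagonist = "antagonist"),
  function(mode) {
    auc <- surrogate_auc_matrix(ds, models, mode)
    evaluate_all_models(auc, "A11111111111111", mode = mode)
  })

qa <- qualify_models(summaries$agonist)
qn <- qualify_models(summaries$antagonist)
minimal_battery_search(qa, qn, summaries$agonist, summaries$antagonist)
```

On the default synthetic dataset the qualifying antagonist models all
contain the three planted antagonist assays, leaving any one of them out
caps antagonist sensitivity below 95%
(`leave_one_out_max_sensitivity()`), and the minimal battery is the union
of the planted agonist and antagonist detector assays — the same
qualitative structure the workflow is designed to expose on real screening
data.

## Known limitations

- The surrogate AUC is a ranking device, not a mechanistic model; absolute
  AUC values carry no meaning.
- Cutting a Ward tree at the fixed height 1 is scale-dependent: with very
  small planted clusters (a handful of chemicals) between-cluster merges
  can fall below the cut, so exact partition recovery is only guaranteed
  for reasonably sized clusters.
- The constrained battery search enumerates all $\binom{14}{k}$ assay sets
  directly; this is instant at 14 assays but would need a smarter search
  for substantially larger rosters.
- Printed reference tables ship as fixtures for verification; the
  package does not recompute the published dataset-dependent counts (537
  and 109 qualifying models, the published leave-one-out maxima), which
  require the original screening database.
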