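# ARbattery

Optimal minimal in vitro assay batteries for androgen-receptor (AR)
bioactivity prioritization.

## The problem

Computational AR pathway models built on 14 high-throughput ToxCast/Tox21
assays predict chemical agonism and antagonism, but running all 14 assays
for every chemical in a large screening universe is expensive — and some of
the original assays are no longer available. ARbattery implements the
data-processing workflow that turns a comprehensive pathway model into
lean, defensible testing batteries:

- **Subset models** — every combination of 2–14 assays, named
  `"A" + 14 binary digits` (digit *i* marks assay A*i*; e.g.
  `A10000000001111` = {A1, A11, A12, A13, A14}), with the agonist pathway
  spanning A1–A11 and the antagonist pathway A1–A6, A12–A14.
- **Model evaluation** — binarization of pathway AUC scores at 0.1,
  confusion summaries against the 14-assay reference (sensitivity
  TP/(TP+FN), specificity TN/(TN+FP), MCC, balanced accuracy), and
  qualification at sensitivity > 95% and specificity > 85%.
- **Battery optimization** — the smallest assay union hosting one
  qualifying agonist and one qualifying antagonist subset model, plus
  constrained fixed-size and assay-exclusion variants.
- **Chemical clustering** — Tanimoto distance on binary fingerprints, Ward
  linkage cut at height 1, 1-nearest-neighbour assignment, cluster
  activity labels, and a Henry's-law volatility filter.
- **Prioritization** — chemical-assay-pair cost accounting,
  prevalence-weighted overall sensitivity, cluster-guided battery
  assignment, and a Monte-Carlo simulation of a two-stage testing
  workflow.
- **Synthetic data** — a generator that emulates every input (truth
  classes at realistic prevalences, noisy hit calls with planted
  indispensable detector assays, clustered fingerprints, QSAR-like
  predictions, surrogate AUC tables), so the whole pipeline runs without
  any external database.

It is intended for computational toxicologists designing or auditing
tiered screening strategies, and for anyone who wants a reproducible,
testable implementation of the battery-minimization arithmetic.

## Worked example

The 9-assay battery analysis from the printed subset-model names:

```r
library(ARbattery)

fx <- ar_fixtures()
pairs <- enumerate_pairs(unique(fx$table4_pairs$agonist_model),
                         fx$table4_pairs$antagonist_model)
minimal_battery(pairs)
#> Minimal assay battery: 9 assays (13 model pair(s) achieve it)
#>      agonist_model antagonist_model union_size hamming
#> 1  A00101011101000  A00101011101111          9       3
#> 2  A00101011101000  A00101010101111          9       4
#> ...
#> 13 A00101011101000  A00101000000111          9       7
```

The single 6-assay agonist model pairs with 13 antagonist models, each
union spanning 9 assays — the smallest battery supporting qualified
detection of both modes. Two-model agreement and testing-scenario costs:

```r
ant <- agreement_table(fx$table1_antagonist$calls_11,
                       fx$table1_antagonist$calls_14)
c(ant$agreement, ant$n, round(ant$mcc, 2))
#> [1] 1733.00 1817.00    0.79    # models agree on 1,733 of 1,817 chemicals

scenario_cost(c(387, 3848), c(9, 5))   # cluster-based testing
#> [1] 22723                           # chemical-assay pairs
percent_of_max(22723, 4235)
#> [1] 38                              # percent of the 14-assay maximum

overall_sensitivity(95, 70, antagonist_weight = 0.9)
#> [1] 92.5                            # 6-assay battery, 90/10 weighting
```

End-to-end on synthetic data — generate a screening library, evaluate all
16,368 subset models against the full model, qualify, and minimize:

```r
ds <- generate_synthetic_dataset(seed = 1)
models <- c(enumerate_subset_models(include_full = FALSE), "A11111111111111")
ag  <- evaluate_all_models(surrogate_auc_matrix(ds, models, "agonist"),
                           "A11111111111111", mode = "agonist")
ant <- evaluate_all_models(surrogate_auc_matrix(ds, models, "antagonist"),
                           "A11111111111111", mode = "antagonist")
minimal_battery_search(qualify_models(ag), qualify_models(ant), ag, ant)
```

See `vignettes/battery-optimization.Rmd` for the model description, the
generator's assumptions, and the numerical design choices. A thin
command-line wrapper over the same functions ships at
`inst/scripts/arbattery.R` (subcommands `generate`, `evaluate`, `qualify`,
`optimize`, `cluster`, `label`, `cost`, `simulate`).

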