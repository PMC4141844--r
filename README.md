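# xtalprop

Sequence-based prediction of protein crystallization propensity for
structural-genomics target triage.

Producing a diffraction-quality crystal is the rate-limiting step of X-ray
structure determination: most targets entering a crystallization pipeline
stall at cloning, expression, purification or crystallization, and each
failed step is expensive. `xtalprop` predicts, from the amino-acid sequence
alone, the probability that a protein passes each of the five consecutive
experimental steps — **CLF** (cloning), **MF** (material production),
**PF** (purification), **CF** (crystallization) and **CRYS**
(diffraction-quality crystal / solved structure) — and maps the
crystallizability score onto five difficulty tiers (Optimal / Suboptimal /
Average / Difficult / Very difficult, at cutoffs 0.6 / 0.55 / 0.45 / 0.2)
so that target lists can be ranked before any bench work.

It is aimed at structural-biology groups triaging target lists and at
methods researchers studying sequence determinants of crystallization.

## Method

1. **Feature encoding.** Each protein is encoded into a fixed registry of
   2,924 candidate features: 3 × 544 AAindex physicochemical averages
   (whole sequence, predicted exposed residues, predicted buried
   residues); 1,060 PROFEAT-style descriptors (dipeptide composition 400;
   normalized Moreau–Broto, Moran and Geary autocorrelations 90 each;
   composition/transition/distribution over seven physicochemical
   partitions 147; quasi-sequence-order 160; amphiphilic pseudo-amino-acid
   composition 80; total amino-acid properties 3); and 232
   sequence/structure features built from per-residue secondary-structure,
   disorder and exposure tracks (compositions, segment/run statistics,
   cross-combinations such as exposed-His frequency, plus global features
   like length, pI and net charge). Per-residue tracks come from built-in
   deterministic baseline annotators or from external predictor output
   files (ss2-style and tabular adapters).
2. **Feature selection.** Minimum-redundancy maximum-relevance (mRMR)
   ranking under the difference criterion, with mutual information
   computed on equal-frequency terciles. Either *one-step* (top 300 of all
   2,924) or *two-step* (top 100 from each AAindex block, then top 300
   from the 300-feature pool plus the 1,292 non-AAindex features). The
   ranked set is refined by a wrapper stage — incremental (IFS) or greedy
   forward (FFS) selection — scored by 5-fold cross-validated AUC of the
   classifier.
3. **Two-level stacked classification.** One probability-output SVM
   (POLY/RBF/SIG kernels, grid-searched C and γ, Platt-calibrated) per
   task forms the first level; the five out-of-fold probability outputs
   are the inputs of five second-level models, which exploit the strong
   correlations between the steps' outcomes.
4. **Evaluation.** AUC (rank estimator), MCC, accuracy,
   sensitivity/specificity/precision, ROC curves, inter-task output
   correlations, and per-feature contribution (Welch-t significance and
   single-feature AUC).

The package also implements the dataset-construction rules for
experimental status records (stop-status whitelist, 2006–2010 date
window, X-ray method filter, most-advanced-status collapse, five-class
assignment, per-task positive/negative composition, CD-HIT-style ≥40 %
within-class redundancy reduction, stratified 6-way train/test split with
an optional 25 % cross-set identity filter) and synthetic generators for
sequences, status tables and planted-signal feature tables.

## Worked example

```r
library(xtalprop)

# sequences -> per-residue annotation -> 2,924-feature table
proteins <- simulate_sequences(n = 60, length_range = c(80, 250), seed = 1)
proteins <- annotate_baseline(proteins)
features <- encode_features(proteins)
dim(features)
#> [1]   60 2925            # id + 2,924 features

# labels from a (here: simulated) experimental status table
status  <- simulate_status_records(n_targets = 60, seed = 1)
classes <- assign_class(filter_trials(status)$status)
crys    <- build_task_dataset(tibble::tibble(id = proteins$id,
                                             class = classes), "CRYS")
table(crys$label)
#>  0  1
#> 50 10                    # crystallizable targets are the rare class

# two-step mRMR: 100 per AAindex block, then top 300 of 1,592
y        <- crys$label[match(features$id, crys$id)]
selected <- two_step_select(features, y)
selected
#> # A tibble: 300 × 4
#>    rank feature_id               score relevance
#>   <int> <chr>                    <dbl>     <dbl>
#> 1     1 moran_polarizability_d20 0.170     0.170
#> 2     2 dipep_LY                 0.121     0.135
#> 3     3 aaseq_RADA880102         0.121     0.135

# incremental wrapper refinement and cross-validated performance
refined <- ifs(features, y, selected, max_size = 15, folds = 5, seed = 1)
refined
#> <xtal_selection> IFS: 7 features, cross-validated AUC 0.7720
cv <- cross_validate(features[c("id", refined$selected)], y,
                     folds = 5, seed = 1)
glance(cv)
#> # A tibble: 1 × 4
#>   folds   auc accuracy   mcc
#> 1     5 0.772    0.833 0.459

# difficulty tiers from the out-of-fold crystallizability scores
table(classify_difficulty(cv$scores))
#>        Optimal     Suboptimal        Average      Difficult Very difficult
#>             11              0              1              3             45
```

The out-of-fold AUC of 0.77 says a randomly chosen crystallizable target
outranks a randomly chosen non-crystallizable one 77 % of the time; the
tier table is the ranked triage list a laboratory would act on. For the
full five-task stacked predictor see `train_stacked()` /
`predict.xtal_stack()`, and `stacking_comparison()` for the level-1 vs
level-2 comparison.

A thin command-line front end over the same functions ships at
`inst/cli/xtalprop.R` (subcommands `simulate`, `encode`, `select`,
`train`, `predict`, `prioritize`, `evaluate`).

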