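---
title: "Predicting crystallization-pipeline success from sequence: models and design choices"
author: "xtalprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting crystallization-pipeline success from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalprop)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, the conventions adopted where a
convention had to be chosen, what the synthetic-data generators do and do
not emulate, and the known limitations.

## The prediction problem

A structural-genomics target must pass five consecutive experimental
steps — cloning, production of protein material, purification,
crystallization, and the yield of a diffraction-quality crystal — and can
stall at any of them. The package frames each step as a binary
classification problem over protein targets: the positive class passed
the step, the negative class stalled at it, and targets whose records are
uninformative for a step are excluded (for the purification task, targets
that already failed cloning or expression are excluded rather than called
negative, because many of them might well be purifiable). The practical
output is a calibrated probability per step and a five-tier difficulty
call on the crystallizability score (Optimal ≥ 0.6, Suboptimal ≥ 0.55,
Average ≥ 0.45, Difficult ≥ 0.2, Very difficult below; boundaries
inclusive at the lower edge of each tier).

## Dataset construction from status records

Experimental registries record one row per crystallization trial. Four
filters turn them into labels (`filter_trials()`): a stop-condition
whitelist ("current status: work stopped", "in PDB", "crystal structure")
keeps only targets whose experimental fate is settled; a 2006-01-01 to
2010-12-31 date window removes both obsolete chemistry and still-running
work; an X-ray method filter removes NMR and other trials; and each
target collapses to its *most advanced* status, with the latest trial
kept among equal statuses. "Most advanced" needs a total order, which the
registry vocabulary does not define; the package fixes

selected < cloned < expressed < soluble < purified < purification failed
< crystallization failed < poor diffraction < crystallized < diffraction
< structure successful < crystal structure < in PDB.

Two statuses — `crystallized` and `diffraction` — sit between
crystallization failure and a solved structure: a crystal existed but no
structure was deposited. They are assigned to the crystallization-failure
class (CF), reading them as "stalled before a solved structure"; this is
a genuine judgement call and the single most consequential vocabulary
decision in the module.

Redundancy is reduced within each class by greedy incremental clustering
(`reduce_redundancy()`): sequences are visited longest-first and join a
cluster when global pairwise identity (alignment matches over alignment
length, computed with Biostrings) reaches the threshold (default 0.4).
This reproduces the *contract* of word-based clustering tools, not their
exact cluster boundaries — the package needs "no two retained sequences
are ≥ 40 % identical", not a particular heuristic's output. The 6-way
stratified split (`split_train_test()`) keeps five subsets for training
and one for testing, optionally dropping test sequences ≥ 25 % identical
to any training sequence.

## The 2,924-feature registry

The encoder concatenates 23 blocks in a fixed order
(`feature_registry()`); total 2,924, of which 1,292 are not AAindex-based.

**AAindex blocks (3 × 544).** For each of the 544 indices of the bundled
AAindex snapshot, the mean property over all residues, over predicted
*exposed* residues, and over predicted *buried* residues. When an
exposure class is empty the block falls back to the whole-sequence mean —
a deliberate "no information" value that keeps vectors finite on
pathological sequences. The snapshot is built at run time from the
`aaindex` dataset shipped with seqinr, whose release contains exactly 544
entries — the count on which the registry arithmetic
(2924 − 3 × 544 = 1292) depends; later AAindex releases are larger and
must not be substituted. Fifteen missing values in the snapshot are
imputed with the per-index mean, which preserves each index's scale and
keeps downstream standardization well-defined.

**PROFEAT-style blocks (1,060).** Dipeptide composition (400);
normalized Moreau–Broto, Moran and Geary autocorrelations (90 each: three
property scales × lags 1–30); composition (21), transition (21) and
distribution (105) over seven three-class physicochemical partitions;
quasi-sequence-order descriptors (160); amphiphilic pseudo-amino-acid
composition (80); and per-residue means of the three autocorrelation
properties (3). The three autocorrelation scales default to one
hydrophobicity (KYTJ820101), one flexibility (BHAR880101) and one
polarizability (CHAM820101) index — a representative trio chosen once;
any three AAindex ids can be substituted via `autocorr_params()`.

Conventions worth stating precisely:

* Moreau–Broto uses the scale standardized over the 20 amino acids;
  Moran and Geary use the raw scale centred at the *sequence* mean.
  Zero-variance sequences (homopolymers) define Moran = Geary = 0, and
  lags not supported by the sequence length contribute 0.
* CTD distribution reports, per class, the 1-based position scaled by
  100/N of the first occurrence and of the ⌈q·n⌉-th occurrence for
  q ∈ {0.25, 0.5, 0.75, 1}; an absent class yields five zeros.
* QSO coupling terms are τ_d = Σ dist(s_i, s_{i+d})² for d = 1..30 under
  two 20 × 20 distance matrices, with weight 0.1; descriptors per matrix
  are the 20 normalized frequencies and the 30 weighted couplings, which
  sum to 1. The first matrix is Grantham's 1974 distance, recomputed from
  the published composition/polarity/volume formula. The second is a
  package-defined physicochemical distance — Euclidean over standardized
  Kyte–Doolittle hydropathy, Hopp–Woods hydrophilicity and Grantham
  side-chain volume — filling the role usually played by the
  Schneider–Wrede matrix, whose tabulated values are not redistributable
  here. Both have zero diagonal, so homopolymers have all τ = 0.
* APAAC uses λ = 30 and weight 0.05 over standardized hydrophobicity and
  hydrophilicity scales; the shared denominator uses Σ|τ|, so the 80
  features sum to exactly 1 whenever every correlation tier is
  non-negative and the denominator can never vanish. Sequences shorter
  than λ + 1 zero-pad the missing tiers.
* The block sizes follow the printed PROFEAT index ranges, which sum to
  1,060; no separate plain pseudo-amino-acid-composition block exists in
  the layout.

**Sequence/structure blocks (232).** Ten sequence-global features
(length, log-length, pI, mean residue mass, mean hydropathy, net charge
per residue at pH 7, K/R-vs-D/E balance, aromatic and sulfur fractions,
Cys-count parity); 87 composition features (20 amino acids, five
physicochemical classes, ten side-chain functional groups, 25 grouped
dipeptides over the five-class alphabet, 27 grouped tripeptides over a
three-class alphabet); and 145 annotation-derived features (exposure 65,
secondary structure 37, disorder 13, cross-combinations 20) covering
fractions, per-state segment statistics, run counts at fixed length
thresholds, amino-acid-class frequencies within states, terminal
disorder, and named cross-features such as exposed-His and buried-Glu
frequencies. The tripeptide alphabet assigns Trp to the hydrophobic class
so that the three classes partition all 20 amino acids; the ten
functional groups are sulfhydryl {M}, thiol {C}, phenyl {F,W,Y}, carboxyl
{D,E}, guanidyl {R}, imidazole {H}, primary amino {K}, amido {N,Q},
hydroxyl {S,T} and non-polar {G,A,V,L,I,P}.

The isoelectric point is the unique root of the Henderson–Hasselbalch
net-charge function over the ionizable side chains and termini
(EMBOSS-style pKa set), found by bisection on [0, 14] to 10⁻⁴ pH units.

## Per-residue annotation

The features above need three per-residue tracks: secondary structure
(H/E/C), disorder (D/O) and exposure (E/B). Adapters parse the output of
external predictors (ss2-style secondary-structure files, two-column
disorder and accessibility tables), validating the residue column against
the sequence. When no external predictions are available, deterministic
baseline annotators (`annotate_baseline()`) keep the pipeline
self-contained: exposure from a windowed Kyte–Doolittle mean (window 9,
threshold 0; hydrophilic stretches are exposed), secondary structure from
windowed Chou–Fasman helix/strand propensities against a fixed coil
baseline of 1 with ties resolved to coil (coil being the majority state),
and disorder from the windowed fraction of disorder-prone residues
(D,E,K,R,S,Q,P,G; window 21, threshold 0.3). These baselines are honest
*annotators*, not emulations of any particular predictor: the features
are defined over the annotation alphabet, and better tracks simply yield
better features. On compositionally uniform random sequences the
baseline calls are systematically biased (most residues hydrophilic
enough to be "exposed"); this does not affect the feature definitions,
only the realism of synthetic inputs.

## Feature selection

Mutual information is the plug-in estimate on equal-frequency terciles
(ties broken by value then index; a constant feature is a single bin with
MI 0), in bits. Terciles are parameter-free and invariant under monotone
transforms, which matters because many descriptor blocks live on very
different scales. The mRMR ranking is the greedy *difference* variant:
the first feature maximizes relevance I(f; y), each next feature
maximizes I(f; y) minus its mean MI with the already-selected set, and
ties break by registry order so the ranking is deterministic.

The one-step stage ranks all 2,924 features and keeps 300. The two-step
stage first keeps 100 from each of the three AAindex blocks — preventing
the highly inter-correlated AAindex family from crowding out everything
else — and then ranks the 300-feature pool together with the 1,292
non-AAindex features (1,592 candidates) for a final 300.

The wrapper stages score feature subsets by the out-of-fold AUC of the
package classifier under stratified 5-fold cross-validation with a fixed
seed and a fixed default kernel configuration (kernel tuning happens
after selection, not inside it, to bound cost). IFS evaluates growing
prefixes of the ranking and returns the prefix with maximal AUC, smallest
prefix on ties; FFS greedily adds the single best candidate per round and
stops when the improvement falls below 10⁻⁴ AUC — both tolerances are
package choices where "stop at the maximum" needed an operational
definition.

## Classification and stacking

The classifier is a libsvm C-SVC (via e1071) over features standardized
with training-set statistics frozen in the model; constant columns get
unit scale. Three kernels are supported (RBF, polynomial, sigmoid), with
C and γ grid-searched over powers of 4 (C ∈ 2⁻⁵..2¹⁵, γ ∈ 2⁻¹⁵..2³) by
out-of-fold AUC. Probabilities come from a Platt-style sigmoid — a
binomial GLM on the decision value — fitted on the training set and
clamped to [10⁻⁶, 1 − 10⁻⁶]. The built-in libsvm probability machinery
is internally randomized at the C level and would break the package's
reproducibility contract (identical seeds must give bit-identical
models); the explicit calibration is deterministic. Training is on the
natural, imbalanced class composition — no re-weighting — because the
probability scores, not the 0.5-threshold calls, are the primary output.

The stacked architecture trains one first-level model per task on its
selected features, then one second-level model per task on the 5-vector
of first-level probabilities. Second-level training inputs are
*out-of-fold*: each row's meta-features come from first-level models
refit with that row's fold held out, so no second-level training row was
seen by the models that scored it. The second level defaults to a linear
(degree-1 polynomial) kernel: with only five, strongly informative,
inputs, a low-variance linear combiner is the standard stacked-
generalization choice and empirically loses less to cross-validation
noise than an RBF on the same inputs. All five first-level outputs feed
every second-level model, since cross-step information is exactly what
stacking is meant to exploit.

## Synthetic data: what it emulates and what it does not

Three generators make the package fully testable without external data.

`simulate_sequences()` draws i.i.d. sequences, by default uniform over
the 20 amino acids with lengths uniform on [50, 300] — the typical range
of crystallization targets. Uniform composition is a *null* model: it
exercises every encoder but carries none of the compositional structure
of real proteomes.

`simulate_status_records()` plants a known class per target and emits a
consistent trial trajectory (successive in-window X-ray trials up to a
class-defining final status), plus, with probability 0.3 each, two decoy
trials — a pre-window 2005 trial and a non-X-ray trial, both carrying a
*more advanced* status — that the filters must remove for the planted
class to be recovered. Class mixture defaults to the failure-skewed
composition typical of structural-genomics registries (25/25/20/15/15 %
for CLF/MF/PF/CF/CRYS).

`simulate_planted()` generates unit-variance Gaussian features, k
informative features per task with per-feature logit effect δ, and a
shared latent factor z. With coupling ρ > 0, z is mixed into every
informative feature (variance-renormalized) and enters each task's logit
scaled by 2ρ. The mixing is what makes the five classifiers' *outputs*
correlate — with independent features and disjoint informative sets, no
label-side coupling alone can do that — and the direct logit term is the
signal that other tasks' probabilities can recover, making second-level
stacking genuinely informative at ρ > 0 and exactly neutral at ρ = 0.
What passing tests on this generator shows is that the selection and
stacking machinery behave correctly *in the regime the generator
creates*: linear-logit signal, Gaussian features, one global latent
factor. Real crystallization data have nonlinear effects, correlated
descriptor blocks and multiple latent factors; performance numbers on
synthetic data say nothing about attainable real-data AUC.

Test and simulation problem sizes (n = 600, p = 200, k = 10 for
selection recovery; n = 600, p = 25, k = 5 for the stacking comparison;
stratified 5-fold CV throughout; 5–10 seeds per property) were chosen
once as the smallest sizes at which the studied effects are comfortably
larger than seed-to-seed noise.

## Numerical and degenerate-input conventions

* Constant features: single MI bin (MI 0); unit scale in the classifier.
* Empty exposure class: AAindex fallback to whole-sequence mean; empty
  frequency denominators yield 0 throughout the structure blocks.
* Zero-variance autocorrelation denominators: Moran/Geary 0.
* Confusion-metric denominators of 0: metric 0 with a `degenerate` flag,
  never an exception.
* AUC ties: half credit (the rank estimator equals the trapezoidal ROC
  area).
* mRMR, IFS and FFS tie-breaks: registry order / smallest subset / first
  maximum, all deterministic.
* Bisection tolerance for pI: 10⁻⁴ pH units on [0, 14]; the net-charge
  function is strictly decreasing, so the root is unique.

## Known limitations

* The baseline annotators are far weaker than modern structure
  predictors; with real data, external predictions should be supplied
  through the adapters.
* The per-feature list of the 232 sequence/structure features follows a
  canonical layout fixed by this package (documented ids in
  `feature_registry()`); other implementations of the same feature
  families may order or normalize them differently.
* The greedy identity clustering is quadratic in the number of sequences
  per class and is not meant for six-figure corpora; an external
  clustering tool can be substituted upstream.
* Tier cutoffs are fixed, interpretable operating points on the
  probability scale, not optimized thresholds.
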