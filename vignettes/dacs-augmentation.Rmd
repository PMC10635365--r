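---
title: "Augmenting drug-synergy datasets with the DACS similarity score"
author: "dacsaug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmenting drug-synergy datasets with the DACS similarity score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dacsaug)
```

## The problem

Supervised prediction of drug-combination synergy is starved for labeled
data: screening every drug pair against every cancer cell line is
infeasible, so the experimental datasets cover a few thousand
(drug A, drug B, cell line, synergy score) instances for on the order of
a hundred drugs. `dacsaug` implements a data-augmentation strategy for
this setting: if a compound is, by several independent lines of
evidence, pharmacologically equivalent to a drug in a measured
combination, a new training instance can be minted by substituting it
into the pair, inheriting the measured cell line and synergy score.

Everything hinges on deciding when two compounds are equivalent. The
package quantifies drug-drug similarity three ways and fuses two of
them into the operating score.

## The similarity model

**Pharmacological response.** Each drug's monotherapy profile is the
map from cell line to pIC50 (the negative log10 of the half-maximal
inhibitory concentration; higher means more potent growth inhibition).
For two drugs, the cell lines screened with both are ranked by pIC50
in each profile and compared with Kendall's tau-b,

$$\tau_b \;=\; \frac{n_c - n_d}
 {\sqrt{(n_c + n_d + n_1)\,(n_c + n_d + n_2)}},$$

where $n_c$ and $n_d$ count concordant and discordant cell-line pairs
and $n_1$, $n_2$ count pairs tied in only one of the two rankings
(`kendall_tau_b()`, `concordance_counts()`). A positive tau says the
drugs inhibit the same cell lines and spare the same cell lines. With
fewer than two shared cell lines, or when one ranking is constant so
the denominator vanishes, the coefficient is defined as 0: no evidence
is encoded as no association, never as a small positive number. Ties
are detected by exact equality of the parsed values — pIC50 values are
data, not computed quantities, so no epsilon is appropriate.

**Mechanism of action.** Over a fixed protein universe (in the
full-scale study, the proteins of a reference protein-protein
interaction network), the 2x2 table of proteins targeted by both
drugs ($T$), one drug only ($A$, $B$), or neither ($N$) yields the
Matthews correlation coefficient
$\mathrm{MCC} = (TN - AB)/\sqrt{(T+A)(T+B)(N+A)(N+B)}$
(`target_mcc()`). Degenerate margins (a drug with no known targets, or
targeting the entire universe) return 0 rather than an undefined
ratio. Whether target associations should first be filtered by a
source confidence score is left to the user (`read_targets(min_score=)`);
the default applies no filter, using associations as exported.

**Chemistry.** Binary molecular fingerprints compared with the
Tanimoto coefficient, shared on-bits over the union (`tanimoto()`).
The built-in fingerprint (`path_fingerprint()`) hashes every linear
path of 2–7 atoms of the molecular graph into 1024 bits — the same
descriptor family as path-based fingerprints in standard
cheminformatics toolkits. The hash is documented in the source
(31-polynomial byte fold modulo $2^{31}-1$), and `drug_library()`
accepts any externally computed fixed-length fingerprint matrix
instead, so a toolkit fingerprint can be dropped in without touching
the rest of the pipeline. Two all-zero fingerprints score 0: absence
of features is not evidence of shared chemistry.

**The DACS score.** Chemistry and mechanism are fused as

$$\mathrm{DACS} = \sqrt{\mathrm{TC}^2 + \max(\mathrm{MCC}, 0)^2}
  \in [0, \sqrt2],$$

(`dacs_score()`). Negative MCC values carry no evidence of shared
action and are clamped to zero before squaring. The Euclidean form
means one sufficiently strong component can carry a pair over a
threshold on its own. Tau is deliberately not part of the score: it is
the *validation* axis — the quantity the threshold analysis checks the
score against — and in deployment candidate substitutes frequently
have no monotherapy profile at all.

## Choosing the operating cutoff

`threshold_curve()` computes, over a grid of thresholds (default 0 to
1.42 in steps of 0.01), the fraction of drug pairs at or above the
threshold whose tau is strictly positive. Strictness matters: tau = 0
encodes missing information and must not count as agreement. Threshold
comparison is inclusive (`metric >= threshold`) so the DACS maximum
$\sqrt2$ is attainable by identical pairs. An empty selection reports
`NA`, not 0 — reporting zero would fabricate a trend at high
thresholds. `substitute_count_curve()` counts, per threshold, the
distinct candidate compounds whose DACS to at least one study drug
reaches the threshold (each candidate counted once however many drugs
it matches).

The two curves move in opposite directions — raising the cutoff makes
substitutes more trustworthy and scarcer — and have incomparable
units, so `select_optimal_cutoff()` min-max normalises the count curve
to $[0,1]$ and returns where it crosses the fraction curve, linearly
interpolating between grid points. Two boundary decisions are worth
stating:

* With several transversal crossings, the one at the highest threshold
  is returned.
* On cleanly separated cohorts both curves sit at exactly 1.0 across
  the entire gap between the within-cluster and between-cluster DACS
  ranges. Such a contiguous tie run flanked by opposite signs is
  treated as a *single* crossing located at its first tie point — the
  point where quality first catches up with supply. A tie run flanked
  by equal signs is a tangency and no crossing at all.

The in-gap behaviour of the selected cutoff is a statistical property,
not a theorem: when the handful of highest-DACS cross-cluster pairs
happen to be tau-positive by luck, the fraction curve touches 1.0
early and the crossing can land marginally below the gap. The test
suite therefore asserts the property on a fixed low-noise cohort whose
premises (clean separation, concordant clusters) are themselves
asserted first.

## Augmentation

`build_substitute_map()` lists, per study drug, the candidates with
DACS at or above the cutoff (never the drug itself).
`augment_dataset()` then substitutes each position of each instance in
turn — position A, then position B, never both at once — creating
instances that inherit the parent's cell line and synergy score.
Generated pairs equal to the partner drug are dropped; duplicates on
the (canonical pair, cell line) key are removed, originals always
winning over generated rows and the earliest generated occurrence
winning otherwise (a conflict between two parents with different
scores is reported in a warning). Pairs are stored everywhere in
canonical lexicographic order, so one unordered pair has exactly one
representation. The augmented table keeps full provenance: parent
instance, substituted position, original/augmented flag. Inherited
quality scores travel along but are never used for filtering.

Labeling for classification (`label_instances()`) is inclusive at both
ends: synergy score $\ge 20$ is synergistic, $\le -20$ antagonistic,
and the ambiguous middle band is excluded. `class_balance()` turns
class counts into the totals and prevalence reported alongside.

When augmented instances are added to a training set,
`ratio_preserving_augment()` preserves the training set's
synergistic:antagonistic ratio, adding the largest pool subset whose
per-class counts stay within one instance of exact proportionality;
within a class, selection is a seeded shuffle. If the pool runs out of
one class the other is limited accordingly and the unusable remainder
is reported as a shortfall attribute.

## Evaluation without leakage

Features are 900-dimensional: drug A embedding, drug B embedding (in
canonical pair order), cell-line embedding, 300 dimensions each
(`build_features()`). The default drug embedder folds the fingerprint
into 300 dimensions by fixed index hashing; the default cell embedder
is a seeded Gaussian random projection of the expression profile. Both
are pluggable — the full-scale study used a pretrained molecular
embedding and a learned expression encoder, and any function returning
300 finite numbers can be substituted — but the defaults are
deterministic, dependency-free, and preserve neighbourhood structure,
which is all the desk-scale analyses require.

`make_folds()` supports the two protocols: a seeded stratified random
split into five folds (class proportions preserved within one
instance per fold), and a tissue-based split whose folds are exactly
the tissue groups of the cell lines — the harder, more honest protocol
in which the validation tissue is never seen in training.

`run_cv()` enforces the discipline that makes augmented evaluation
meaningful: models are validated *only* on original instances, and the
augmented instances added to a training round derive *only* from
parents inside that round's training folds. An augmented copy of a
held-out instance can therefore never leak into training; the
constraint is asserted at run time in every fold. This guard applies
to the random split too, where the risk is otherwise silent.

Classifiers are consumed through `classifier_config()`: a random
forest (300 trees, minimum 85 samples per leaf, sqrt-of-features per
split, balanced class weights; fitted with `ranger`) and gradient
boosted trees (650 stages, minimum 120 per leaf, learning rate 0.28,
maximum depth 5, sqrt-of-features per split node; fitted with
`xgboost`, where the leaf minimum maps to `min_child_weight`, the
hessian-sum analogue of a sample count for logistic loss). These are
the full-scale settings; every value is overridable, and desk-scale
runs on cohorts of a few hundred instances override the leaf minima
(which would otherwise exceed the fold size) and reduce the ensemble
sizes — the overrides are recorded in the configuration and the
report. The report (`eval_report`) carries ACC, TPR, FPR, PPV, AUC,
MCC and F1 per fold plus their fold-mean; AUC is computed per fold
from the continuous classifier score (via `pROC`) and aggregated as
the mean over folds, with the synergistic class positive.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` builds a self-contained study with the statistical
structure the method assumes, so every stage runs and is testable
without downloads:

* **Clustered chemistry.** Each latent cluster has a scaffold molecule
  (a linear SMILES chain, default 14 atoms over C/N/O/S/P); each
  member drug is the scaffold decorated with a couple of drug-specific
  substituent branches, the way an analog series varies around a
  common core. Shared backbone paths give within-cluster fingerprint
  similarity; branches provide drug-private bits. (An earlier design
  that mutated backbone atoms in place was rejected: point mutations
  destroy most shared paths, leaving almost no cluster geometry in
  fingerprint space — chemically unrealistic and fatal to any
  similarity-based method.)
* **Shared identifiers.** Original drugs and candidate compounds draw
  identifiers from one interleaved namespace, because real compound
  identifiers carry no information about which study a drug belongs
  to; a namespace that sorted all candidates after all originals would
  funnel every substitute into the same feature slot under canonical
  pair ordering and bias the evaluation.
* **Shared targets.** Each cluster owns a target set (12 proteins of a
  150-protein universe); members keep each cluster target with
  probability 0.8 and add two private ones.
* **Correlated response.** pIC50 is a cluster-by-cell surface
  (Normal(6, 1)) plus per-drug noise (sd 0.3 pIC50 units), so
  within-cluster tau is positive in expectation. Candidate compounds
  carry no monotherapy profiles, like database compounds never
  screened in the synergy study.
* **Latent synergy.** Synergy is a property of the *unordered* cluster
  pair: a base effect of magnitude 30 (positive with probability 0.72,
  mirroring the roughly 3:1 synergistic imbalance of real screens), a
  tissue modifier (sd 5), and instance noise (sd 10). 400 instances
  are drawn over 48 drugs (12 clusters of 4) and 25 cell lines in 5
  tissue groups, with 40 candidate substitutes and 300-gene expression
  profiles — the problem sizes used throughout the tests and the
  acceptance script.

All randomness flows from one spec seed through split sub-seeds, so
individual tables are independently reproducible. Latent cluster
labels and the synergy surface are returned for test assertions only.

Two honest caveats about what passing tests on this cohort shows.
First, after the ±20 labeling filter the synthetic labels are
effectively noiseless (the ±30 base keeps filtered scores away from
the class boundary), so desk-scale performance is limited by model
headroom, not label noise — real synergy labels are noisier. Second,
the cohort's cluster structure is far cleaner than real chemistry;
results on it demonstrate that the pipeline's machinery is correct and
that the augmentation direction of effect emerges when its assumptions
hold, not that any particular effect size transfers to real screens,
whose reproduction requires the external synergy, target and
expression datasets.

`worked_fixture()` is the complementary micro-cohort: four drugs, two
candidates, four cell lines, six instances, all values literal, every
similarity and every augmented instance enumerable by hand in the test
suite.

## Numerical and degenerate-input decisions

* tau-b and MCC denominators are computed as a single square root and
  clamped to $[\pm 1]$ to absorb last-bit floating-point spill.
* Curve grids must be strictly increasing; heatmap bins are
  left-closed with the top edge folded in; empty bins and empty
  selections are `NA`, never 0.
* TSV output writes numbers at 6 significant digits with
  provenance comment headers (package version, seed, config hash —
  never a timestamp), so identical runs are byte-identical and diffs
  are clean.
* Identifiers are opaque strings; no case folding or trimming.
* A training set lacking one class cannot be ratio-augmented and is
  reported as an error rather than silently skipped.

## Limitations

* The default embeddings are structural baselines, not learned
  representations; with them, absolute classification numbers on real
  data will differ from studies using pretrained chemical and
  expression encoders.
* The built-in fingerprint covers the SMILES constructs needed for
  path fingerprinting (organic subset, aromatics, branches, rings,
  charges ignored); exotic stereochemistry and isotopes are parsed
  permissively rather than modelled.
* Substituted instances inherit their parent's measured score
  unchanged; no re-estimation of synergy for the new pair is
  attempted, because inheritance *is* the method under study.
* Tissue grouping is an input mapping, not a hardcoded ontology; cell
  lines without a mapping are an error under the tissue protocol.
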