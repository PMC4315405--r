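---
title: "Reject-option pathogenicity prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reject-option pathogenicity prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricall)
```

## The problem and the model

Non-synonymous single-nucleotide variants cause amino acid substitutions,
the most common class of variation behind Mendelian disease, and far more
substitutions are observed than can ever be characterised experimentally.
tricall implements a machine-learning classifier for this triage problem
that deliberately refuses to answer when it cannot answer reliably: every
substitution is labelled *pathogenic*, *neutral*, or *unknown*.

The classifier is an ensemble of random forests over stratified bootstrap
resamples. Given a labelled training table, `fit_ensemble()` draws
`n_bootstrap` resamples (default 200), each the size of the training data
and with the original per-class counts preserved (sampling with
replacement within class), and grows one random forest (default 300
trees, 2 candidate features per split) on each. For a query variant,
member forest $b$ reports $P_b$, the fraction of its trees voting
pathogenic. The spread of $(P_1, \dots, P_B)$ measures how stable the
prediction is under resampling of the training data.

### The reliability gate

The distribution of bootstrap probabilities is unknown, so the gate uses
Chebyshev's inequality, which holds for any distribution: at least
$1 - 1/k^2$ of a random variable's mass lies within $k$ standard
deviations of its mean. With confidence level $c$ (default 0.95) we set
$k = 1/\sqrt{1-c}$ (so $1 - 1/k^2 = c$; $c = 0.95$ gives
$k = \sqrt{20} \approx 4.47$) and form the interval
$\mu \pm k\sigma$ over the member probabilities. If the interval excludes
0.5 the call is reliable — pathogenic when entirely above, neutral when
entirely below — otherwise the variant is reported unknown. Raising $c$
widens the interval, so rejection is monotone: a variant rejected at one
confidence level is rejected at every higher level, a property the test
suite asserts.

Numerical conventions in the gate, chosen where the method statement is
silent:

* $\sigma$ is the sample standard deviation (denominator $n-1$) of the
  member probabilities.
* Inequalities are strict, so an interval endpoint exactly at 0.5
  rejects; the midpoint $\mu = 0.5$ is unknown at every $\sigma$,
  including $\sigma = 0$.
* In the no-reject fallback (`binary_call`, threshold 0.5 on $\mu$) an
  exact tie goes to neutral, keeping false-positive behaviour
  conservative.

## The four feature families

`assemble_features()` builds one row per variant from four providers.
The default feature list is the eight-column set the final predictor
uses: the GO log-ratio, selective pressure $\omega$, three
sequence-profile features, and three amino acid property entries.

**Gene Ontology log-ratio (`go_lr`).** Each protein's annotated GO terms
are expanded with all ancestors (following `is_a` and `part_of` edges by
default; `is_a`-only is available) and deduplicated so the protein
carries each term once. Class-wise term frequency tables are accumulated
from the training partition only, and a protein's feature value is

$$LR = \sum_i \log\frac{f(P_i)+1}{f(N_i)+1},$$

the add-one-smoothed log ratio of the term's pathogenic and neutral
frequencies, summed over the protein's term set. Two conventions here
were genuinely open. First, the logarithm base is unspecified in the
method statement; we use the natural log, since any fixed base rescales
$LR$ monotonically and is absorbed by tree learners (the base is a
parameter of `go_log_ratio()`). Second, the frequency counting unit:
counts could be per variant or per protein. The default counts per
*variant* — each training variant contributes its protein's term set to
its class — because the feature context should reflect the class
composition of the variant dataset, in which proteins with many
pathogenic variants are over-represented; per-protein counting is a
config switch. Proteins with no annotation get a missing value, never a
zero.

**Amino acid properties.** AAindex1 entries are 20-value per-residue
indices; the feature is index(reference) − index(variant), so it is
antisymmetric under swapping the residues (any consistent direction is
equivalent for tree learners). AAindex2/3 entries are substitution
matrices; the value is read directly from the `[ref, var]` cell, with
triangular matrices symmetrised on load and asymmetric ones used as
stored (row = reference). Entries containing any missing cell are
dropped by `filter_complete_indices()` before feature assembly.

**Evolutionary conservation.** The codon-level ratio of non-synonymous
to synonymous substitution rates ($\omega$, Ka/Ks) measures selective
pressure: variable sites tolerate amino acid change, conserved sites do
not. A proper $\omega$ comes from a codon-model selection analysis and
enters tricall as an input column. `surrogate_omega()` is a clearly
labelled counting surrogate — per-codon synonymous and non-synonymous
pairwise differences to the reference, each normalised by
Nei–Gojobori-style per-codon site counts — provided only so the pipeline
runs end-to-end without external tools; it is not equivalent to a
codon-model estimate and is never used unless explicitly requested. When
the per-codon synonymous rate is zero the surrogate is missing rather
than infinite.

**Sequence profile.** From a multiple sequence alignment of orthologs
(reference flagged by id), three features per variant: the proportion of
sequences carrying the reference residue at the aligned column, the
proportion carrying the variant residue, and the number of sequences.
The denominator counts all rows including those gapped at the column
(the method statement is silent; `count_gaps = FALSE` excludes them),
and the reference sequence itself is included in the count.

### Missing features

Missing values are median-imputed with medians learned on training data,
with one exception: the GO feature is protein-level and entirely absent
for unannotated proteins, so imputing it would fabricate signal. When
training data contains GO-missing rows, a parallel fallback ensemble is
trained without the GO column and serves GO-missing variants at
prediction time. An impute-only mode exists for comparison.

## Functional-site annotation priors

Some site annotations (metal-binding sites, active sites, ...) are
strongly class-biased. `select_annotation_types()` computes, per
annotation type, the pathogenic proportion $P_a$ among training variants
inside that type's intervals and keeps types whose majority-class
proportion exceeds 0.85. At prediction time a variant inside a selected
site combines the prior with the forest probability by the noisy-OR rule

$$P_c = P_a + P_{rf} - P_a \cdot P_{rf},$$

which is symmetric, monotone in each argument, bounded by
$\max(P_a, P_{rf})$ and 1, is the identity at $P_a = 0$ and absorbing at
$P_a = 1$.

Two silent points needed decisions. When several selected types overlap
one position, the type whose $P_a$ is farthest from 0.5 (most
informative) wins by default; first-match order is a switch. And the
combination is applied *per bootstrap member* — each member probability
passes through the rule before $\mu$ and $\sigma$ are computed — because
combination is reported to reduce rejection rates, which requires the
reliability interval itself to move, not only its centre; mean-only
combination is available. The rule is applied exactly as written even
for neutral-biased types ($P_a < 0.5$), although noisy-OR can only raise
the pathogenicity probability; in practice retained types are
pathogenic-biased, so the case rarely arises.

## Two-step feature selection

Feature selection combines backward elimination and forward selection,
always under family-aware cross-validation: `family_kfold()` keeps all
variants of one protein family in a single fold, so homologous proteins
never straddle the train/test boundary (asserted in the tests).

*Step one.* On each of the $k$ (default 10) CV splits, a forest is
trained on the candidate features, accuracy measured on the held-out
fold, features ranked by mean decrease in Gini index, the weakest
feature dropped, and the forest retrained — down to one feature. The
feature set of the most accurate classifier on that split is kept (ties
resolve to the smaller set). *Step two.* The union of the $k$ subsets —
the non-redundant set — is searched forward: the top Gini-ranked feature
seeds the selected set, then each remaining feature is evaluated by CV
accuracy and the best strictly-improving addition accepted, until no
addition improves. "Improves by the highest percentage" is read as the
largest relative gain; absolute gain is a switch with the same argmax at
equal baselines.

Selection accuracy is binary accuracy over all predictions (threshold
0.5), not reliable-only, because selection precedes the reject gate.
Gini ties break by feature name for reproducibility. Selection forests
default to 100 trees for tractability; the final model always uses the
full ensemble configuration.

## Evaluation: six scores, nMCC, OPM, cuboids

`confusion_metrics()` computes PPV, NPV, sensitivity, specificity,
accuracy and MCC from TP/TN/FP/FN, plus the normalized MCC
$nMCC = (1+MCC)/2$ and the overall performance measure

$$OPM = \frac{(PPV+NPV)(Sens+Spec)(Acc+nMCC)}{8},$$

the normalized volume of the *performance cuboid*: an axis-aligned box
whose six face distances from the origin are the six scores
(`cuboid_geometry()` emits faces and vertices; its volume/8 is asserted
to equal OPM to 1e-12). Measures with zero denominators are explicit
`NA`, never silent NaN, and propagate into OPM. `evaluate_predictions()`
excludes unknown calls from the confusion table but keeps them in the
denominator of *coverage* (the proportion of submitted variants
classified), and reports the all-variant binary-fallback table
alongside. Tests verify the metric implementation against an independent
oracle that materialises label/prediction vectors and measures with
conditional means, using the identity that MCC is the Pearson
correlation of the 0/1 encodings.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the method
assumes, so every stage is testable without external resources:
approximately balanced classes (training on balanced data is the
standard design for this problem); protein families with heavy-tailed
log-normal sizes to stress the family-aware splitter; informative
features drawn from class-shifted unit-variance normals whose mean gap
is set by the `overlap` control ($\Delta = -2\,\Phi^{-1}(\text{overlap}/2)$,
so 0 gives disjoint supports and 1 identical distributions); a
right-skewed positive $\omega$ with pathogenic mass near zero (conserved
sites) whose class shift also vanishes at `overlap = 1`; noise features
independent of class; annotation sites placed so each type's realized
pathogenic proportion matches its configured $P_a$ by construction; and
GO tables built over a toy tree ontology with risk terms skewed toward
proteins of high pathogenic propensity.

What it does **not** emulate: real feature marginals or their
correlations, linkage between features and actual sequence content,
annotation interval structure (sites are single positions), or the
scale of real training corpora. Passing tests on generated data
demonstrate that the machinery is correct and well-calibrated under the
assumed structure — not that real-data performance figures transfer.

Generator defaults (40 proteins × 8 variants, class balance 0.5,
overlap 0.3, three annotation types with $P_a$ 0.95/0.90/0.88, GO skew
0.8) were fixed once as a realistic small working set for a problem in
which per-feature class separation is strong but imperfect; tests that
need a specific regime (disjoint supports, pure noise) set `overlap`
explicitly.

## Problem sizes and numerical tolerances in the shipped tests

The test and acceptance suites run on deliberately small instances: 200—
320 variants, 15—30 bootstrap members of 40—60 trees for behavioural
tests (full 200 × 300 is the production default, not needed to exercise
the logic), selection with 5-fold CV and 60-tree forests, and 10
generator seeds for the planted-feature recovery experiment.  Exact
identities (noisy-OR, OPM/cuboid, metric oracle) are checked to 1e-12;
stochastic properties (chance-level accuracy at `overlap = 1`, realized
annotation proportions) use tolerances derived from binomial standard
errors at these sizes.

## Known limitations

* The $\omega$ surrogate is a counting heuristic; serious use should
  supply codon-model estimates as the `omega` input column.
* The GO feature is protein-level: it cannot separate pathogenic from
  neutral variants within one protein, and the package's discriminative
  power inside a protein rests on the positional and substitution-level
  features.
* Chebyshev intervals are distribution-free and therefore conservative;
  the effective confidence is higher than nominal, and coverage
  correspondingly lower than a parametric gate would give.
* Inputs are protein-space substitutions; genomic coordinates, VCF and
  transcript mapping are out of scope, as is retrieval of orthologs or
  annotations from external services.
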