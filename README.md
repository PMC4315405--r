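# tricall

Tri-class pathogenicity prediction for amino acid substitutions with a
reject option.

## What problem this solves, and for whom

Exome and genome sequencing yield far more non-synonymous variants —
amino acid substitutions — than can be characterised experimentally, and
clinical or research triage needs to know which ones are likely harmful.
Binary predictors are forced to guess on every variant, including the
ones whose score sits right at the decision boundary. tricall is for
bioinformaticians who would rather have three honest answers than two
overconfident ones: each substitution is called **pathogenic**,
**neutral**, or **unknown**, where *unknown* means the classifier's own
stability analysis says the prediction would not be trustworthy.

## The method

The classifier is an ensemble of random forests over **stratified
bootstrap** resamples of the training data (defaults: 200 resamples,
300 trees each, 2 candidate features per split). Member forest *b*
reports a probability of pathogenicity *P<sub>b</sub>* (its fraction of
trees voting pathogenic). With mean μ and standard deviation σ of the
member probabilities, Chebyshev's inequality — valid for any
distribution — guarantees that at least 1 − 1/k² of the bootstrap mass
lies in μ ± kσ. At confidence c (default 0.95, so k = 1/√(1−c) = √20):

* μ − kσ > 0.5  →  **pathogenic**
* μ + kσ < 0.5  →  **neutral**
* otherwise    →  **unknown** (rejected)

Features span four families: a Gene Ontology log-ratio
LR = Σᵢ log[(f(Pᵢ)+1)/(f(Nᵢ)+1)] over a protein's ancestor-expanded term
set; codon-level selective pressure ω (Ka/Ks, supplied as input);
alignment sequence-profile features (proportions of reference and
variant residues, number of sequences); and AAindex physicochemical
properties (per-residue index differences and substitution-matrix
values). Variants at strongly class-biased functional sites (majority
class proportion > 0.85 in training) get a prior P<sub>a</sub> merged
into every member probability by the noisy-OR rule
P<sub>c</sub> = P<sub>a</sub> + P<sub>rf</sub> − P<sub>a</sub>·P<sub>rf</sub>.

The package also implements two-step greedy feature selection (backward
elimination per cross-validation fold, then forward selection over the
union) under **family-aware** folds that never split a protein family
across the train/test boundary, and an evaluation suite with the six
standard binary-classification scores, the normalized Matthews
correlation coefficient nMCC = (1+MCC)/2, and the **overall performance
measure** OPM = (PPV+NPV)(Sens+Spec)(Acc+nMCC)/8 — the normalized volume
of the performance cuboid whose six face distances are the six scores.
A synthetic data generator reproduces the statistical structure the
method assumes, so the whole pipeline is testable offline.

## Worked example

```r
library(tricall)

ds <- generate_dataset(generator_config(seed = 42))     # synthetic corpus
train <- ds$data$family_id %in% unique(ds$data$family_id)[1:8]

fit <- fit_ensemble(ds$data[train, ],
                    ensemble_config(n_bootstrap = 50, n_trees = 100, seed = 1),
                    features = c("go_lr", "f_ref", "aa_prop", "omega"))

sites_model <- select_annotation_types(ds$variants[train, ], ds$sites)
pa   <- annotate_variants(ds$variants[!train, ], ds$sites, sites_model)
pred <- predict(fit, ds$data[!train, ], annotation_pa = pa)
pred[1:4, c("variant_id", "mu", "sigma", "lower", "upper", "call")]
#> # A tibble: 4 × 6
#>   variant_id     mu   sigma  lower upper call
#>   <chr>       <dbl>   <dbl>  <dbl> <dbl> <chr>
#> 1 v0105      0.988  0.0188   0.904 1.07  pathogenic
#> 2 v0106      0.0194 0.0313  -0.121 0.159 neutral
#> 3 v0107      0.988  0.00642  0.959 1.02  pathogenic
#> 4 v0108      0.722  0.121    0.180 1.27  unknown

evaluate_predictions(pred, ds$data$label[!train])
#> <tricall_eval> 161/216 variants classified (coverage 0.745)
#> # A tibble: 2 × 14
#>   subset      tp    tn    fp    fn   ppv   npv sensitivity specificity accuracy
#>   <chr>    <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>       <dbl>       <dbl>    <dbl>
#> 1 reliable   103    57     1     0 0.990 1           1           0.983    0.994
#> 2 all        128    83     4     1 0.970 0.988       0.992       0.954    0.977
```

Reading the output: variant `v0108` has a mean bootstrap probability of
0.72, but its reliability interval (0.18, 1.27) straddles 0.5, so it is
rejected as unknown rather than called pathogenic. The evaluation shows
the point of the reject option: among the 74.5% of variants the model
agreed to classify, accuracy is 0.994, versus 0.977 when every variant
is forced into a binary call (`subset = "all"`).

`tidy()`, `glance()` and `autoplot()` methods summarise fitted
ensembles, selection traces, evaluations and cuboids;
`plot_reliability()` shows the μ/σ reject geometry.

A command-line wrapper over the same functions ships in
`inst/cli/tricall.R` with subcommands `simulate`, `train`, `predict`,
`select-features` and `evaluate`.

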