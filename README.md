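# awca

Robust PAM50-style intrinsic subtyping of breast-cancer RNA-seq profiles.

## The problem

Intrinsic molecular subtypes (Luminal A, Luminal B, Her2-Enriched, Basal,
Normal-like) are assigned by a nearest-centroid rule: a sample's log2
expression over a classification panel is centered against a *reference
profile* (per-gene Log2ratio), then the sample is called as the class whose
centroid has the maximal Spearman correlation with the centered profile,

    call(s) = argmax_k  rho( x_s - ref,  c_k ).

The conventional reference — the per-gene median over a cohort subset with a
fixed 60/40 ER+/ER− proportion — depends on the subset's subtype
composition, so equally legitimate reference subsets produce discordant
calls for borderline samples. This package is for computational biologists
who need reproducible, cohort-independent subtype calls from RNA-seq. It
provides:

* **AWCA reference construction** (*average of within-class averages*): per
  gene, the within-class means are averaged over classes, so every class
  contributes one term regardless of size — the reference is *exactly*
  invariant to class numerosity and supports true single-sample
  classification against a fixed external reference;
* the standard **median-reference PAM50 workflow** and a **stability
  experiment** that quantifies both strategies' dependence on the reference
  subset (concordance with reference labels, pairwise concordance across
  replicate subsets, at a ladder of subset sizes);
* **ROR scoring** (weighted sum of class correlations plus a tumor-size
  term, user-supplied coefficients, low/intermediate/high binning);
* an **elastic-net multiclass logistic regression** subtype caller
  (proximal-gradient optimizer with exact-zero sparsity, stratified
  cross-validation, hyperparameter grid search) plus **feature selection**:
  four univariate filters, pairwise-contrast DEG "limmaN" union signatures,
  and randomized multi-run backward elimination;
* an **evaluation harness** (concordance, Cohen's kappa, confusion matrices
  with macro-averaged recall/precision, pairwise concordance
  distributions) and a **synthetic cohort simulator** with planted
  subtypes, ER strata, ambiguous mixture samples and planted DE genes.

## Worked example

```r
library(awca)

# a 350-sample, 1000-gene synthetic cohort with planted subtypes; the 100
# informative genes play the role of the classification panel
co    <- simulateCohort(simulationConfig(seed = 20))
panel <- CentroidTable(exprValues(co$plantedCentroids)[co$panel, ])

# standard median-reference classification, then one AWCA round
pipe <- awcaPipeline(co$expression, co$annotations, panel,
                     subsetSize = 200, seed = 1)
pipe$finalCalls
#> SubtypeCallSet: 350 samples (correlation scores)
#>   calls: Basal=59, Her2=52, LumA=117, LumB=98, Normal=24

concordance(pipe$preliminaryCalls, co$trueLabels)  # median-based calls
#> [1] 94.86
concordance(pipe$finalCalls, co$trueLabels)        # AWCA-based calls
#> [1] 95.14
cohensKappa(pipe$finalCalls, co$trueLabels)
#> [1] 0.935
```

The concordances are against the cohort's planted labels; about 10% of the
simulated samples are deliberately ambiguous two-class mixtures, which is
why neither strategy reaches 100%. The stability experiment shows what AWCA
buys: across ten replicate reference subsets per size, AWCA-based calls
agree with each other more closely, and with less dispersion, than
median-based calls at every subset size:

```r
stabilityExperiment(co$expression, co$annotations, panel,
                    sizes = c(200, 100, 50), replicates = 10,
                    truthLabels = co$trueLabels, seed = 2)
#> StabilityReport (values in %):
#>  size strategy replicates mean_truth sd_truth mean_pairwise sd_pairwise
#>    50     awca         10      95.14    0.000         99.94        0.12
#>   100     awca         10      95.23    0.138         99.87        0.14
#>   200     awca         10      95.17    0.090         99.89        0.14
#>    50   median         10      94.57    0.522         98.77        1.04
#>   100   median         10      94.86    0.330         99.44        0.32
#>   200   median         10      94.86    0.301         99.37        0.65
```

With the AWCA reference fixed, classification is exactly single-sample —
one profile classified alone equals its call in any batch:

```r
solo <- classifySingleSample(co$expression[, "S0001"], pipe$reference, panel)
round(callScores(solo)[1, ], 3)
#>   LumA   LumB  Basal   Her2 Normal
#>  0.263  0.251 -0.006  0.016  0.081
calls(solo)
#>  S0001
#> "LumA"
```

The per-class values are Spearman correlations of the centered profile with
each centroid; the call is the arg-max (here a borderline luminal sample:
LumA barely above LumB — exactly the kind of profile whose call flips under
an unstable reference).

A command-line wrapper over the same functions ships in `inst/cli/awca.R`
(subcommands `simulate`, `build-reference`, `classify`, `ror`,
`select-features`, `train-mlr`, `predict-mlr`, `stability-experiment`,
`evaluate`); every output table carries a provenance header with the seed.

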