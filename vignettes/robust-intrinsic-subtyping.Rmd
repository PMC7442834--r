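---
title: "Robust PAM50 intrinsic subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust PAM50 intrinsic subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awca)
```

## The problem

Breast-cancer intrinsic subtyping assigns each tumor transcriptome to one of
five classes (Luminal A, Luminal B, Her2-Enriched, Basal, Normal-like) by a
nearest-centroid rule: the sample's log2 expression over a classification
panel is centered against a *reference profile* (one value per gene), and
the sample is called as the class whose published centroid has the maximal
Spearman correlation with the centered profile.

The weak link is the reference. The conventional reference is the per-gene
median over a cohort subset with a fixed 60/40 proportion of estrogen
receptor-positive (ER+) and -negative (ER-) cases. A median over a subset
depends on the subset's subtype composition, so two equally legitimate
reference subsets can yield discordant calls for samples whose profile sits
between two centroids. This package implements that standard workflow, a
reference construction that removes the dependence — AWCA, the *average of
within-class averages* — and the instruments to quantify the difference,
plus an alternative reference-free subtype caller (an elastic-net multiclass
logistic regression) with the feature-selection procedures that feed it.

## AWCA double averaging

Given any class assignment of the cohort (typically a preliminary standard
classification), the AWCA reference for gene $g$ is

$$\mathrm{ref}(g) \;=\; \frac{1}{|K|} \sum_{k \in K} \; \overline{x}_{g,k},$$

where $\overline{x}_{g,k}$ is the mean expression of $g$ over the samples
called class $k$, and $K$ is the set of retained classes. Because each class
contributes exactly one term regardless of its size, the reference is
*exactly* invariant to within-class sample duplication — the property the
package's acceptance checks verify bit-for-bit. The full pipeline
(`awcaPipeline`) performs exactly one round: ER-stratified subset, median
reference, preliminary whole-cohort classification, AWCA reference from
those calls, final whole-cohort classification. It deliberately does not
iterate to convergence; one round already removes the subset dependence, and
further rounds would trade transparency for no demonstrated gain.

Two exclusion rules shape $K$:

* `excludedClasses` removes classes by name (typical use: Normal-like, when
  it is undersized or considered clinically indeterminate);
* `minClassSize` (default 10 called samples) auto-excludes degenerate
  classes, with a message. At least two classes must survive.

A preliminary classification can be replaced by published labels
(`preliminaryCalls`), which is how an external "inner AWCA" reference is
built from an annotated cohort. A warning (not an error) is raised when the
reference subset has fewer than 50 samples; references built from fewer
samples are legal but empirically unstable.

## The single-sample contract

Nothing in centering or correlation looks at more than one sample: centering
subtracts a fixed per-gene reference, and the per-class correlations are
computed column-by-column. `classifySingleSample` is therefore *exactly*
equal to the same sample's call inside any batch, and the test suite asserts
identity to full precision under batch shuffling and subsetting. This is the
contract that makes a fixed external AWCA reference a genuine single-sample
classifier.

Numerical conventions, fixed because the field's descriptions leave them
open:

* ranks use average (fractional) tie handling;
* correlation ties between classes break by a canonical, documented order —
  alphabetical class name — so calls are reproducible;
* a constant centered profile has no defined rank correlation; the sample is
  called `UNCLASSIFIABLE` with the reason recorded, and such samples are
  excluded (and counted) by the agreement statistics;
* classification uses the intersection of matrix, reference and centroid
  genes, and errors when less than `minOverlap` (default 80%) of the
  centroid panel survives — partial overlap must be tolerated (public
  cohorts occasionally lack a panel gene) but not silently.

## Risk of recurrence

`computeROR` implements the correlation-weighted score
$\mathrm{raw} = \sum_k w_k \rho_k + w_T T$ (with $T$ a tumor-size
covariate), an optional affine rescaling $a\cdot\mathrm{raw}+b$, and
low/intermediate/high binning with boundary values assigned to the lower
group. The package ships **no** coefficient values: the published Cox-model
coefficients are not reproduced here, and the configuration in
`inst/extdata/ror_placeholder_synthetic.tsv` is a clearly labelled synthetic
placeholder showing the file layout. Normal-like is conventionally excluded
from ROR weighting. The affine hook exists because reported ROR scales
(e.g. 0-100) differ between assay descriptions; supplying $(a, b)$ is the
user's responsibility along with the weights.

## Elastic-net multiclass logistic regression

The reference-free caller is a softmax regression over per-gene z-scored
features minimizing

$$F(W, b) = \tfrac{1}{n}\,\mathrm{NLL}(W, b) + \lambda_1 \lVert W \rVert_1
          + \tfrac{\lambda_2}{2} \lVert W \rVert_2^2,$$

intercepts unpenalized. The optimizer is proximal gradient descent (ISTA)
with backtracking line search: a gradient step on the smooth part followed
by soft-thresholding, which yields *exact* zeros — required for the sparsity
properties (non-zero-weight counts weakly decreasing in $\lambda_1$, support
recovery). Tolerance is $10^{-6}$ relative objective change, capped at 1000
iterations with a warning; the iterate sequence is monotone in $F$ by
construction and the fit stores its objective trace so the property is
testable. Initialization at $W=0, b=0$ makes the fit deterministic;
the only randomness in the module is the stratified fold partition, driven
by an explicit seed. Standardization statistics are fitted on training data
only, stored in the model, and re-applied verbatim at prediction time (and
refit per fold inside cross-validation), so the model is single-sample by
construction.

Hyperparameters are selected by seeded stratified 10-fold cross-validation
over a grid (default $\{0.01, 0.1, 1\}^2$), maximal mean accuracy, ties to
the smaller $\lambda_1$ then $\lambda_2$. Published hyperparameter values
from hosted ML platforms are treated as grid points, not transferable
constants, because those platforms do not document their objective scaling.
An independent solver of the same objective (glmnet, with
$\lambda\alpha = \lambda_1$, $\lambda(1-\alpha) = \lambda_2$) is used in the
test suite as a cross-check on predicted probabilities, never as the
implementation.

## Feature selection

Three families, all operating on log2 expression and a label vector:

* **Filters.** Fisher score
  ($\sum_k n_k(\mu_k-\mu)^2 / \sum_k n_k \sigma_k^2$, population variances,
  denominator floored at $10^{-12}$); mutual information and chi-squared on
  per-gene quantile-binned expression (default 4 bins — fine enough to see
  non-linear association, coarse enough to keep cell counts honest at
  cohort sizes of tens per class; configurable); and a Spearman filter. A
  multiclass label has no canonical ordering, so the Spearman filter is
  defined as the maximum over classes of the absolute rank correlation with
  the one-vs-rest indicator — symmetric in the classes, and reducing to the
  obvious rank-biserial quantity for two classes. Rankings order by
  descending score with alphabetical tie-break, so `topK` is deterministic.
* **Pairwise-contrast DEG signatures.** One differential analysis per
  unordered class pair (10 for five classes), moderated t by default
  (limma's empirical-Bayes variance shrinkage; `moderation = "none"` gives
  the ordinary pooled t, which the tests verify against `t.test`),
  Benjamini-Hochberg within contrast, significance at $\alpha = 0.05$. The
  `limmaN` signature is the union of each contrast's top $N$ significant
  genes (all of them when a list is shorter than $N$) — monotone in $N$ by
  construction.
* **Backward elimination.** A wrapper over any trainer exposing
  "gene subset to CV accuracy". Each run shuffles the gene order (the sweep
  is order-biased; randomizing and unioning across runs is the mitigation),
  sweeps once per pass, removes a gene when accuracy without it improves by
  more than `gainThreshold` (default 0.001 absolute accuracy — below one
  sample at the cohort sizes used, so any reproducible gain qualifies), and
  stops when a pass removes nothing. The default trainer is a seeded 5-fold
  cross-validated elastic-net fit (5 folds, not 10, purely for the inner
  loop's cost). The final signature is the union of kept sets; aborted runs
  are reported, and the output is always a subset of the start set and a
  superset of the intersection of run-wise kept sets.

## What the simulator emulates — and what it does not

`simulateCohort` generates the statistical structure the methods actually
consume: class-specific centroid profiles (a common baseline
$\mathcal{N}(8, 2^2)$ on the log2 scale; the first `nInformative` genes get
independent per-class offsets $\mathcal{N}(0, \texttt{centroidSeparation}^2)$,
playing the role of the classification panel), independent Gaussian
per-gene noise, per-class ER+ probabilities (defaults 0.95/0.9/0.1/0.4/0.7
for LumA/LumB/Basal/Her2/Normal, echoing the luminal-ER association),
log-normal tumor sizes, ambiguous samples drawn from an even two-class
centroid mixture, and planted pairwise DE genes with recorded ground truth.
The default demo cohort is 1,000 genes (100 informative), classes sized
120/100/60/50/20, unit noise, 10% ambiguous samples — chosen once as a
realistic desk-scale regime (roughly 93% classification concordance with
truth, i.e. neither saturated nor hopeless) and not revisited.

The simulator does **not** emulate count-level properties: no
negative-binomial sampling, no library-size or normalization artifacts, no
RSEM/FPKM pipeline differences, no gene-gene correlation. Passing tests
therefore demonstrate the *procedural* claims — duplication invariance,
single-sample identity, the direction and dispersion of the
reference-stability comparison, recovery of planted structure — not
performance on real cohorts, where normalization mismatch alone is known to
cost substantial concordance.

Two auxiliary generators serve specific checks. The sparse-softmax
generator (`simulateSparseSoftmax`) draws labels from a known softmax model
whose active genes each discriminate a +effect/-effect pair of classes;
same-sign-across-classes patterns are deliberately never planted, because
they are shift-invariant directions of the softmax and carry no signal — a
nominally "active" gene of that kind would be statistically
indistinguishable from noise and would make support recovery ill-posed. The
backward-elimination fixture derives sub-seeds from the master seed and
takes the first two-gene cohort on which the noise gene strictly degrades
the fixed-fold CV accuracy, establishing the premise of the
noise-removal check deterministically for any seed.

## Problem sizes and runtime envelope

All simulations are desk-scale by design: the stability experiment runs 10
replicates at subset sizes 200/100/50 on the 350-sample demo cohort
(seconds); support recovery uses $n = 300$, 60 genes, 3 classes, 10 active
genes, effect size 2, fit at $\lambda_1 = 0.1, \lambda_2 = 0.01$; DEG
recovery plants 5 genes per pair with a 2-unit log2 shift across a 5-class,
180-sample cohort. These sizes are the package's documented study
conditions; headline percentages from thousand-sample public cohorts are
not reproducible at this scale and are not asserted anywhere.

## Known limitations

* Centroids are inputs; no centroid training or shrinkage is provided.
* ROR coefficients are configuration; no survival modelling is included to
  validate a user's choice.
* The AWCA pipeline performs one re-classification round by design.
* References do not transfer across normalization schemes; the package
  offers no cross-normalization conversion, deliberately.
* The CLI is a thin wrapper over the exported functions with per-subcommand
  flags; a single structured config file driving a whole pipeline run was
  considered and dropped — in R, the composable pipeline *is* the function
  layer, and a config schema would duplicate it.
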