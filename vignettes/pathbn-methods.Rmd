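---
title: "Differential analysis of pathway-structured Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential analysis of pathway-structured Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathbn)
```

## The model

pathbn asks which genes and which gene–gene relationships of a curated
signaling pathway differ between a case group (e.g. patients with an
autoimmune disease) and controls, when expression has been measured on
several array platforms by several independent studies.

The pathway topology is taken as the fixed structure of a
linear-Gaussian Bayesian network. For a gene $Y$ with pathway parents
$X_1, \dots, X_{p-1}$, each group's data are modeled as

$$\hat Y = \beta_0 + \beta_1 X_1 + \dots + \beta_{p-1} X_{p-1} + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2).$$

The intercept $\beta_0$ is the gene's **node parameter** — its
expression level in that group — and each parent coefficient is an
**edge parameter**, the strength of the parent–child relationship.
Fitting is ordinary least squares per gene, and the coefficient vector
carries its classical sampling distribution
$\beta \approx N(\hat\beta,\ \sigma^2 (X^TX)^{-1})$, with $\sigma^2$
estimated by $RSS/(n-p)$.

For every parameter estimable in both groups of a platform $j$, the
case-minus-control difference
$\beta^{*(j)} = \hat\beta_{case} - \hat\beta_{ctrl}$ has variance
$se_{case}^2 + se_{ctrl}^2$ because the two fits use disjoint samples.
We refer $\beta^{*(j)} / se$ to a t distribution with
Welch–Satterthwaite degrees of freedom; this Wald-type contrast is the
two-coefficient analogue of an independent two-sample t test, and is
forced by the fact that each group yields one estimate plus a standard
error, not two samples of values. p-values are Benjamini–Hochberg
adjusted **jointly over nodes and edges within each
(pathway, platform) family**, and a parameter is significant on
platform $j$ when $FDR_j < \alpha$ (default $\alpha = 0.05$).

Per-platform significant contrasts are merged by a moment-matched
mixture whose weights are the platform subject counts,
$p_j = N_j / \sum_k N_k$:

$$\mu(\beta_f) = \sum_j p_j\, \mu(\beta^{*(j)}), \qquad
  Var(\beta_f) = \sum_j p_j\,(var(\beta^{*(j)}) + \mu^2(\beta^{*(j)}))
  - \mu^2(\beta_f),$$

where a platform on which the parameter was **not** significant (or not
testable) contributes a zero-mean, zero-variance component. The final
score is the standardized mean
$\mu^*(\beta_f) = \mu(\beta_f) / \sqrt{Var(\beta_f)}$; its sign marks
up/downregulation for nodes and an increased/decreased biological
function for edges, and parameters are ranked by $|\mu^*|$.

Two consequences of this algebra are worth knowing when reading
results. First, a parameter significant on a single platform has
$|\mu^*| \le \sqrt{p_j/(1-p_j)}$ regardless of how large its effect is
(with three similar platforms, about 0.7): the zero components of the
other platforms dominate the mixture variance. Large $|\mu^*|$ scores
therefore signal *cross-platform consistency*, not merely effect size.
Second, parameters significant nowhere would give a meaningless $0/0$
score and are excluded from the output rather than reported as zero.

## Cross-platform normalization

Before fitting, each dataset is quantile normalized
(`limma::normalizeQuantiles`, ties receive the mean of the reference
quantiles at the tied ranks), same-platform datasets are merged on the
**intersection** of their gene sets (per-dataset lost-gene fractions
are reported), and the merged matrix is batch-adjusted with parametric
empirical-Bayes ComBat (`sva::ComBat`), one batch per dataset. By
default the case/control label enters ComBat's grand model as a
covariate (`preserve_group = TRUE`) so genuine group differences are
not absorbed into batch means; the flag exists because reasonable
analysts disagree on this and the choice should be explicit.
`qc_summary()` expresses the usual boxplot/PCA checks numerically:
per-sample quartiles, the top-two principal components, and the $R^2$
of PC1 regressed on batch, which should collapse after adjustment.

Zero-variance genes carry no batch information and are passed through
unadjusted with a warning; a platform holding a single dataset has
nothing to adjust and is returned unchanged. Many-probes-per-gene
arrays should be collapsed first with `collapse_probes()`, which keeps
the probe with the highest mean intensity.

## Pathway handling

`parse_kgml()` reads KEGG's XML: gene entries expand to their listed
symbols, group (complex) entries expand so every member inherits the
group's edges, and relations routed through gene-less entries
(compounds, maps) collapse to direct gene–gene edges; entries that
resolve to no symbol are reported, not fatal. `parse_sif()` reads the
three-column tab-separated format.

Bayesian networks require acyclicity but signaling pathways contain
feedback. `break_cycles()` removes back-edges found by a depth-first
search started from nodes in lexicographic order with children visited
in lexicographic order. The rule is a declared convention, not a
biological claim — the point is that it is deterministic, so removed
edges are reproducible and auditable (`removed_edges`, written to
`removed_edges.tsv` by the pipeline). Curated activation/inhibition
labels are stored and exported but not used in estimation: the model
estimates signed effects from data.

Other conventions of the same kind: parents absent from a platform's
matrix are dropped from that child's design (and logged) rather than
discarding the child, which is why platforms yield parameter sets of
different sizes; collinear parent columns are dropped deterministically
(scanning lexicographically, a column that does not increase the design
rank loses); a gene is unestimable when $n - p < 1$. Expression columns
enter the regression as-is after normalization — no per-gene
standardization — so the intercept keeps its "expression level"
reading. No shrinkage or structure simplification is applied; this is
deliberate plain OLS.

## The synthetic study generator

Real multi-platform compendia cannot be bundled, so `generate_study()`
produces studies with known ground truth from exactly the generative
model the fit assumes: genes are sampled in topological order, roots
from $N(\beta_0, \sigma^2)$, children as their linear parent
combination plus Gaussian noise. Its defaults emulate a six-dataset,
three-platform case-control compendium (two datasets per platform,
balanced groups).

Defaults and why:

* **Expression scale.** Intercepts are calibrated so every gene's
  marginal mean is 8 on the log2 scale, mid-range for arrays. This
  matters: quantile normalization is rank-based, and a gene whose
  values drift outside the occupied dynamic range is pinned at the
  global minimum/maximum in every sample and loses its variance — an
  artifact real genes do not exhibit, because real arrays are
  calibrated to their dynamic range.
* **Background genes** (`n_background = 200`, levels uniform over
  log2 2–14, sd 1). Quantile normalization and ComBat operate on whole
  arrays of thousands of genes; applying them to a dozen pathway genes
  alone is degenerate (ranks are too coarse, empirical-Bayes priors
  have nothing to pool over). Two hundred background genes are enough
  for stable ranks and priors while keeping a full study under a
  second of runtime.
* **Noise.** Residual sd 1 (log2 units) for children; root genes get
  marginal sd 2, since upstream regulators absorb all unmodeled
  biology and vary more between subjects than a downstream gene does
  around its parents.
* **Batch effects.** Per-dataset, per-gene location/scale:
  shifts $N(\text{shift}_d, 1^2)$ (dataset offsets 0 and 1.5 by
  default) and scales $e^{N(0, 0.1^2)}$ — the model class parametric
  ComBat removes, so the normalization stage's success or failure is
  interpretable.
* **Dropout.** One pathway gene absent from one platform by default,
  reproducing the lost-gene situation of real gene-set intersections.
* **Effect sizes.** `perturb_ground_truth()` expresses injected
  case/control differences in *contrast-SE units* computed analytically
  from the SEM moments ($(I-B^T)^{-1} \beta_0$ mean,
  $(I-B^T)^{-1} D (I-B^T)^{-T}$ covariance), so "a 3-SE edge" has a
  defined, detection-relevant meaning at a given per-group sample
  size.

What the generator does **not** emulate: probe-level artifacts,
RNA-seq counts, heavy-tailed or heteroscedastic noise, nonlinear or
saturating regulation, latent confounders, unbalanced group ratios
within a dataset. Passing validation on this generator shows the
pipeline recovers what its own model class produces after realistic
batch distortion; it does not certify behavior under model
misspecification.

## Validation design and problem sizes

The test suite exercises each stage against independent oracles: a
sort–average–restore reimplementation for quantile normalization; a
hand-coded parametric empirical-Bayes iteration for ComBat (agreement
to 1e-6); closed-form normal equations and a pairs bootstrap for the
OLS covariance; Kahn's algorithm (via igraph) for acyclicity;
million-draw sampling oracles for the mixture moments; and
Monte-Carlo calibration for type-I error. End-to-end experiments use
three-platform studies with 80 samples per group per platform: an
unperturbed run until 2000 parameter-level replicates accumulate
(empirical per-family FDR stays below the nominal 0.05 plus
Monte-Carlo error), and 50 seeded runs with five 3-SE node, four 3-SE
edge and one 5-SE edge perturbations, scoring recovery (significant on
at least one platform), sign agreement of $\mu^*$ with the injected
direction, and whether the 5-SE edge ranks in the top three
$|\mu^*|$ edges. These sizes keep the whole suite under a minute
while leaving the binomial noise of the pass criteria small.

A note on intercept testing: because regressors are uncentered (by
design — the intercept must mean "expression level"), a slope change
between groups also moves the fitted intercept by roughly
$-\Delta\beta \cdot \bar X$. Node and edge findings on the same child
are therefore correlated, which is inherent to this
parameterization and worth remembering when interpreting node hits on
children of strongly altered edges.

## Numerical and degenerate-input choices

* Welch df uses each coefficient's residual df; contrasts with both
  standard errors zero are refused as undefined.
* Untestable parameters (estimable in one group only) are excluded
  from the FDR family rather than penalized.
* $Var(\beta_f) = 0$ with $\mu(\beta_f) \ne 0$ (a single degenerate
  point-mass component) is flagged and reported with an infinite score
  sentinel, never silently divided.
* Ranking ties break lexicographically on the parameter key.
* All randomness in the generator flows from one integer seed;
  identical seeds give byte-identical TSV outputs.

## Limitations

Cycle removal and KEGG group expansion are conventions; other choices
yield other (equally defensible) DAGs, and removed feedback edges are
simply not tested. Plain OLS offers no protection against
high-in-degree nodes on small platforms beyond refusing to fit. The
mixture merge rewards cross-platform consistency and cannot
distinguish "significant on one platform with a huge effect" from
"significant on one platform with a modest effect" once standardized.
Real-data use requires the user to supply probe-to-symbol mapping and
log-scale matrices; no annotation retrieval or raw-array preprocessing
is included.
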