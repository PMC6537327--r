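---
title: "Benchmarking batch-effect correction by recovery of known gene-gene associations"
author: "coexBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking batch-effect correction by recovery of known gene-gene associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexBench)
options(coexBench.quiet = TRUE)
```

## The problem

Bulk expression matrices carry technical and sampling variation — processing
batch, time between death and sample collection (ischemic time), donor age
and sex, hidden factors — that inflates correlations between unrelated genes
and can mask real co-expression. Correction methods remove fitted confounder
effects, but aggressive variance removal also deletes biology. A diagnostic
that only checks "is the batch signal gone?" cannot see that loss. This
package evaluates corrections against an *external* standard: gene pairs with
high prior confidence of functional association (*true* edges) and pairs with
very low confidence (*false* edges), derived from a confidence-scored
interaction network such as a tissue-naive functional network. An effective
correction raises the separation between true- and false-edge association
scores; an overcorrection shrinks true-edge correlations toward zero and
lowers it.

## Gold-standard construction

From a confidence-scored edge list (`readEdgeList()`, file order preserved)
the first *n* edges (default 100,000) are taken as candidates
(`takeCandidateEdges()`). Two confidence cutoffs then define the labels:
confidence strictly above the high cutoff labels an edge *true* (1), strictly
below the low cutoff labels it *false* (0); mid-range edges are discarded.

`calibrateCutoffs()` balances the two label counts. Starting from
low = 0.01 and high = 0.7, each iteration counts prospective true edges
(confidence > high) and false edges (confidence < low) and, while the larger
count exceeds the smaller more than `balanceTol`-fold (default 1.25, chosen
so that a roughly 5:4 split still counts as balanced), moves the cutoff
guarding the *smaller* set: the low cutoff rises by 0.005 to admit more
false edges, or the high cutoff falls by 0.05 to admit more true edges. The
procedure was deliberately codified as a single-sided move per iteration —
the balancing idea constrains only the step sizes and directions, not the
schedule — because one deterministic schedule makes the result reproducible
and testable against a step-by-step replay. Reachable cutoffs therefore lie
on the grid {0.01 + 0.005k} x {0.7 − 0.05k}. Calibration fails loudly
(classed error carrying the last counts) when the cutoffs collide or leave
[0, 1]; some confidence distributions simply cannot be balanced, e.g. when
the false pool at the lowest admissible cutoff already dwarfs every
reachable true pool, and silently returning unbalanced labels would bias the
downstream AUC.

`restrictToDataset()` removes pairs with an unmeasured gene (typically
filtered for low expression), per label, and refuses a standard that loses
either class entirely.

Candidate selection supports both file order (default — ranked network
downloads ship in meaningful order) and descending-confidence order, since
"first *n*" is ambiguous for arbitrary inputs.

## Scoring model

Association is Spearman's rho: Pearson correlation of average-tied ranks,
with the classical `1 - 6*sum(d^2)/(n(n^2-1))` shortcut valid on tie-free
data (the rank-covariance form is used throughout because it is also correct
under ties). Significance uses the t approximation
`t = r_s*sqrt((n-2)/(1-r_s^2))` on n − 2 degrees of freedom. P-values are
two-sided: nothing in the gold standard promises that true associations are
positively co-expressed, so magnitude is the honest criterion. All edges of a
dataset — true and false together — form one Benjamini–Hochberg family; the
per-edge score is `-log10(p_adj)`, with the adjusted p floored at `10^-320`
(score capped at 320) so perfect monotone pairs stay finite without
disturbing the score ordering.

Constant gene rows are an error, not a silent zero: a constant row has no
rank variance, and letting it through would poison every correlation it
touches.

## Evaluation

`rocAuc()` computes AUC by the Mann–Whitney rank formulation, giving tied
score pairs half credit, and emits the ROC curve swept over distinct score
values; the trapezoidal area of that curve equals the rank AUC to machine
precision, which the `RocResult` validity check enforces as an internal
cross-check. AUC is invariant under strictly increasing transforms of the
scores. Note that the BH step-up map is monotone but *not* strictly
increasing — it can merge distinct p-values into ties — so the AUC of
`-log10(p_adj)` can differ slightly from the AUC of `-p` when a merged group
mixes labels; the package scores what the framework defines (the adjusted
scores) and documents the distinction rather than pretending the two are
identical.

`compareMethods()` requires the identical edge set from every method and
sorts by AUC; `densitySummary()` reports mean, sd and histograms of r_s per
method and label — the shrinkage of true-edge |r_s| toward zero under
component-removal methods is the overcorrection signature.

## Adjustment methods

All residualization methods share one core: per-gene ordinary least squares
of expression on a samples-by-confounders design, keeping the residuals as
adjusted expression. An intercept is always included even though the
adjustment model can be written without one — otherwise residuals would
retain gene means and the exact-fit identity (a gene that *is* a design
column residualizes to zero) would fail. Designs are built by treatment
coding with the first sorted level as reference; samples missing a requested
covariate are dropped from that adjustment only, which avoids imputation
assumptions the data cannot support. Collinear design columns are dropped
with a warning (QR pivoting); residuals are invariant to invertible
reparameterization of the design, which the tests assert.

* **LR** — residualize on known covariates.
* **PEER** — residualize on externally inferred hidden-factor columns
  (consumed from file; the package does not fit the factor model), plus any
  requested covariates such as sex.
* **PCA / PCA_opt** — residualize on the top-k principal-component scores of
  the gene-standardized matrix (each gene centered, unit variance; the
  variance criterion should reflect shared structure, not absolute
  expression scale — configurable in principle, standardized by default).
  Component signs are fixed by making each component's largest-magnitude
  loading positive, for cross-platform determinism. k comes from an explicit
  count or from the smallest cumulative explained-variance fraction
  (`chooseNumPCs()`); the cumulative-variance rule stands in for "components
  accounting for most of the variability", which has no single canonical
  criterion, and an explicit per-dataset k is always available (`PCA_opt`
  requires one).

### Empirical-Bayes batch adjustment

`combatAdjust()` implements the parametric location/scale model: genes are
standardized against the batch + covariate grand model; per-batch per-gene
additive (gamma) and multiplicative (delta²) effects are estimated, shrunk
with moment-matched priors (normal on gamma, inverse gamma on delta²) by a
joint fixed-point iteration to tolerance 1e-4 (capped at 10,000 iterations,
then a classed convergence error), removed, and the scale restored.

Two numerical choices matter. First, all variance estimators use ML (1/n)
denominators, so the estimators are mutually consistent: a single-batch
input — reachable through the `allowSingleBatch` test hook — standardizes to
exactly unit moments, every effect estimate is exactly zero/one, and the
input is returned unchanged to machine precision. Second, when the
across-gene spread of an estimate is (numerically) zero there is no
information to moment-match a prior from, and shrinkage for that parameter
is skipped; this is what makes the single-batch identity exact and keeps
degenerate simulations finite. A `shrink = FALSE` hook removes the raw batch
estimates, which exactly equalizes within-batch gene moments — the oracle
the tests check the shrinkage path against. EB shrinkage itself leaves a
per-gene residual of order `0.5*sqrt(2/n_b)` standardized units (shrinkage
toward the prior mean trades per-gene exactness for stability); the
aggregate planted shift is removed to well under 5%.

`combatPrefilter()` first drops samples alone in their batch (no scale
estimate from one observation), then genes with zero variance inside any
batch (they standardize to NaN).

`combatIterative()` adjusts several batch variables in a configured order
(default: death type, experimental batch, ischemic time, age, sex — the
conventional listing; no canonical order exists and the outputs are *not*
order-invariant, which a test documents). Each round uses one variable as
batch and supplies the not-yet-adjusted batch variables as model covariates,
protecting pending batch structure from absorption — the covariate reading
of "accounting for the yet unadjusted batches", chosen over mere deferral
because deferral alone provides no such protection. Continuous batch
variables are discretized into half-open bins [k·300, (k+1)·300) minutes,
labels 1..5 with the top bin clamped; boundary values go up (300 min is
bin 2), a convention fixed here because only the bin width and count are
canonical. Genes removed by any round's prefilter stay removed.

## Pre-processing

The canonical pipeline is low-expression filter (row mean strictly greater
than 0.1, in RPKM for raw input), quantile normalization within the dataset,
then per-gene inverse normal transform — applied in that order; the order
follows the conventional listing of these steps and is not otherwise forced.
Quantile normalization maps every column onto the across-sample mean of
order statistics; ties receive the mean of the reference values their sorted
positions span, so tied inputs stay tied. The inverse normal transform maps
average-tied ranks through `qnorm((r - 3/8)/(n + 1/4))`; the Blom offset 3/8
is the common default for rank-based normalization and is configurable.
Sample-quality filters (e.g. RIN > 6 where a RIN column exists) are exposed
as a generic predicate filter (`filterSamples()`) rather than hard-coded,
since quality metadata varies by source and is absent from synthetic data.

## The synthetic generator

`generateSynthetic()` emulates the four framework inputs with known ground
truth. Each planted true pair shares a standard-normal latent factor; with
loading lambda and idiosyncratic noise sd sigma, the batch-free observed
pair correlation is `lambda^2/(lambda^2 + sigma^2)`, and lambda is chosen as
`sigma*sqrt(rho/(1-rho))` so that `rhoTrue` *is* that observed correlation —
the quantity the downstream Spearman scoring estimates when no batch
structure interferes (for a bivariate normal with rho = 0.5 the population
Spearman is `6/pi*asin(rho/2) ≈ 0.483`, which the generator tests verify
empirically). False pairs and background genes are independent with the same
total variance. Categorical batch variables add per-gene, per-level shifts
(a rank-≤-levels structure, as real step-like batch effects are); continuous
confounders add per-gene slopes on the standardized covariate while the
phenotype table stores raw minutes-like values (uniform on [0, 1500],
spanning the five 300-minute discretization bins); hidden factors add
loadings recorded only in the generative parameter record. Confidences come
from Beta distributions — Beta(8,2) for true, Beta(1,40) for false,
Beta(2,10) for 20,000 filler edges between background genes — giving the
calibration a skewed, network-like mixture in which both cutoffs must move;
the edge list is emitted in descending-confidence order, the shape ranked
network downloads have.

Default conditions (2,000 genes, 200 samples, 300 true + 300 false pairs, a
4-level experimental batch with shift sd 1.0, a binary sex covariate with
shift sd 0.5, a continuous ischemic-time confounder with slope sd 0.5, noise
sd 1, rhoTrue 0.5) are sized for minutes-scale end-to-end runs while keeping
every effect comfortably estimable at n = 200. The `nModules` knob groups
true pairs onto a small number of shared module factors; with 5 modules of
120 genes each the module eigenvalues (≈ 60 on standardized data) rise far
above the noise bulk, making the biology a dominant variance component —
precisely the regime in which top-k PC removal deletes it. The package's
reference benchmark (ten seeds, `scripts/acceptance.R` and the acceptance
tests) runs at these conditions with `nModules = 5` and compares raw,
known-covariate regression, and top-20-PC removal.

What the generator does *not* emulate: count-level (negative binomial)
sampling and library-size artefacts, sample-quality covariates such as RIN,
non-linear confounder effects, and correlated batch assignment (batches are
assigned uniformly). Passing benchmarks on these data therefore show that a
method recovers planted monotone co-expression under additive batch
structure — not that it handles count noise or confounding by design.

## Numerical conventions and degenerate inputs

* Strict inequalities throughout the thresholds: expression filter (mean
  > 0.1), gold-standard labels (conf > high, conf < low; boundary values are
  dropped as mid-range).
* `|r_s| = 1` gives p = 0 before flooring; the floor `10^-scoreCap` applies
  to adjusted p-values only, and the score cap keeps ROC ordering intact.
* Expression round trips are written with 17 significant digits, so
  write-then-read reproduces doubles bit-identically.
* Constant rows/columns: constant genes error in rank transforms and edge
  scoring, are dropped (with a warning) before PCA, and constant design
  columns are dropped at design construction; constant hidden-factor rows
  are accepted with a warning since they carry no adjustable signal.
* Sample alignment is by identifier intersection, reordering silently,
  dropping non-shared samples with a logged count, and erroring on an empty
  intersection.
* Reproducibility: generation is a pure function of its configuration
  (seeded internally via `withr`), the pipeline seeds once from its
  configuration, and the manifest records package version, seed, config and
  its hash.

## Problem sizes used in the test suite

Unit tests run on matrices between roughly 5x5 and 300x120; the acceptance
benchmark uses ten datasets of 2,000 x 200 (about a second each end to end);
EB-adjustment checks use 200 genes x 60 samples (plus an 80 x 200 comparison
against the `sva` reference, where larger batches make the 1/n-vs-1/(n-1)
estimator difference negligible); the Spearman and AUC oracles run 1,000 and
500 randomized cases. These sizes were chosen so the full suite documents
the statistical claims in well under a minute of compute while keeping every
stochastic assertion far from its decision boundary.

## Known limitations

* The iterative multi-batch EB adjustment is order-sensitive; the default
  order is a convention, not an optimum.
* PEER-style hidden factors are consumed, never inferred.
* Only parametric EB priors are implemented; no reference-batch or
  count-model variants.
* Spearman p-values always use the t approximation, also at small n where an
  exact permutation p would differ; this matches the scoring definition the
  benchmark is built on.
* Near-saturated PC removal (k close to the sample count) leaves so few
  residual dimensions that correlations inflate rather than shrink; the
  overcorrection analyses therefore use k well below n.
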