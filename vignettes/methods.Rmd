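---
title: "Methods: Gaussian Bayesian networks for DMN structural covariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian Bayesian networks for DMN structural covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnbnet)
```

## The model

`dmnbnet` treats the mean grey-matter volumes of eight default-mode-network
regions (PCC, mPFC, lHP, rHP, lIPC, rIPC, lITC, rITC) as a continuous
random vector and models each subject group with a linear-Gaussian
Bayesian network: a directed acyclic graph (DAG) in which every node is a
linear function of its parent nodes plus independent Gaussian noise,

$$X_j = \beta_{0j} + \sum_{k \in \mathrm{pa}(j)} \beta_{kj} X_k + \varepsilon_j,
\qquad \varepsilon_j \sim N(0, \sigma_j^2),$$

so that the joint density factorizes into the product of the nodes'
conditional Gaussian densities. The implied joint distribution is
multivariate normal with mean $(I - W)^{-1}\beta_0$ and covariance
$(I - W)^{-1} D (I - W)^{-\top}$, where $W$ collects the edge weights and
$D$ the noise variances; the package's `joint_log_density()` is verified
against this closed form to $10^{-8}$ in the test suite.

Key assumptions: ROI volumes are approximately Gaussian (reasonable for
VBM-derived regional averages); relations between regions are linear; and
subjects are exchangeable within group. Directionality of individual edges
is *not* identifiable from observational Gaussian data — BIC assigns equal
scores to all Markov-equivalent DAGs (same skeleton and unshielded
colliders) — so learned arrow directions are a tie-breaking artifact and
edge-level conclusions should be read at the equivalence-class level.
`equivalence_class_key()` exists for exactly this purpose.

## Fitting and scoring

Before fitting, every ROI column is z-scored (mean 0, sd 1, denominator
$n-1$) and the statistics are stored in the model. This choice is
deliberate: regional volumes differ in absolute scale by large factors,
whereas network weight coefficients in this literature are reported as
scale-free magnitudes below one, consistent with standardized data. The
stored statistics are applied to any new subject the model scores, which
is what makes a model fitted on one cohort applicable to a cohort from a
different scanner; the log-density includes the Jacobian term
$-\sum_j \log s_j$ so that densities from models with different
standardizations remain comparable. No harmonization beyond
standardization is attempted.

Each node's parameters are the ordinary-least-squares solution, with the
noise variance taken as residual sum of squares over $n$ (the maximum
likelihood convention, not $n-p$). Degenerate zero-residual fits (exactly
collinear data) are rejected with an error rather than producing an
infinite likelihood.

The structure score is the decomposable BIC (higher is better):

$$\mathrm{score} = \sum_{j=1}^{d} \left[ \log \hat L_j -
\frac{\log n}{2}\, k_j \right],$$

with $k_j = |\mathrm{pa}(j)| + 2$ counting each local model's free
parameters (weights, intercept, noise variance). The penalty's exact
parameter count is the one genuinely open numerical choice in this design;
it is isolated behind the `param_count` argument, and the alternative
$k_j = |\mathrm{pa}(j)|$ (dropping the two terms shared by every
structure, which cancel in comparisons between structures over the same
nodes) can be selected everywhere. Both choices are score-equivalent
across Markov-equivalent DAGs, which the suite checks exhaustively on
three nodes at tolerance $10^{-8}$.

## Structure search

With $d = 8$ the score-optimal DAG can be found exactly: the package uses
the classic dynamic program over node subsets (for every subset $S$, the
best DAG on $S$ ends in some sink $v$ whose parents are the best-scoring
subset of $S \setminus \{v\}$), after precomputing all
$8 \times 2^7 = 1024$ local scores. This removes search stochasticity
entirely; `exact_search()` is the default algorithm.

Ties are broken deterministically: fewer edges first, then the smallest
parent set and earliest sink in the fixed ROI order (PCC, mPFC, lHP, rHP,
lIPC, rIPC, lITC, rITC). On continuous data, exact score ties essentially
arise only between members of one equivalence class, so the tie rule picks
the class representative.

Two companions exist for validation rather than production use.
`exhaustive_search()` enumerates every DAG on up to five nodes (543 at
$d=4$, 29281 at $d=5$) and is the oracle the exact search is tested
against on random datasets. `hill_climb()` is a greedy add/delete/reverse
searcher using iterated local search: the first climb starts from the
empty graph, and each of the (default) 20 restarts perturbs the best
structure found so far with 8 random legal moves before re-climbing. The
kick-based restart was adopted after plain random restarts were observed
to re-enter the same orientation local optima on strong-signal data; with
these defaults the climber reaches the exact optimum on at least 90% of
the 6-node strong-signal datasets in the test suite. Exact search is still
preferred whenever $d$ permits.

`max_parents` is unrestricted by default at $d = 8$ (up to 7 parents) and
becomes a practical necessity only for substantially larger node sets,
which are outside this package's scope (~20 nodes is a hard ceiling for
the exact search).

## Group comparison by permutation

The two groups' networks are learned and fitted independently. Every edge
in the union of the two learned edge sets is then tested for a
between-group difference in its regression coefficient. Three design
choices deserve explanation because the underlying procedure admits
variants:

* **Conditioning set.** The coefficient tested for edge $u \to v$ is the
  coefficient of $u$ in the regression of $v$ on
  $\{u\} \cup \mathrm{pa}_{NC}(v) \cup \mathrm{pa}_{AD}(v) \setminus \{v\}$.
  Using the union of the two groups' parent sets makes the tested quantity
  identical in both groups and well defined for edges present in only one
  group's structure.
* **Structures fixed under permutation.** The relabeling null refits only
  coefficients, not structures: the hypothesis concerns the strength of a
  connection, not the outcome of model selection, and refitting structures
  would mix the two sources of variation. (Re-learning per permutation is
  possible by scripting `fit_group_models` over relabeled tables, but is
  not the packaged default.)
* **One-sided pair without smoothing.** With $B$ permutations,
  $p_{NC>AD} = \#\{\text{permuted diff} \ge \text{observed}\}/B$ and
  $p_{AD>NC} = 1 - p_{NC>AD}$; ties count toward the $\ge$ side and no
  $+1$ smoothing is applied, so the two probabilities always sum to one
  exactly and a $0/B$ outcome prints as 0.0000. The cost of omitting
  smoothing is a slightly anti-conservative test
  ($P(p \le 0.05) \approx 26/501$ at $B = 500$ in the continuous case);
  the calibration test below shows the realized rate stays within the
  Monte-Carlo band of the nominal level.

The pooled table is standardized once before coefficients are computed;
being a shared affine transform, this rescales coefficients onto the
standardized-weight scale without changing any p-value. Rows are sorted by
`subject_id` before the permutation stream is drawn, so results are
invariant to the input row order. The default is $B = 5000$ permutations
and a per-direction $\alpha = 0.05$ with no multiple-testing correction,
mirroring per-edge reporting practice in this literature; Bonferroni
adjustment, if desired, is a one-line wrapper around the returned
p-values.

## Classification

Group membership of a subject $x$ is predicted by the sign of
$\log p_{AD}(x) - \log p_{NC}(x)$: with equal class priors this is the
Bayes rule for the two fitted densities. Exact ties (measure-zero in
floating point) go to NC. Priors enter, optionally, as a
$\log(\pi_{NC}/\pi_{AD})$ shift of the threshold. `evaluate_classifier()`
reports confusion counts with AD as the positive class, accuracy,
sensitivity, specificity, and an ROC curve obtained by sweeping the
threshold over all observed score values; the AUC uses the rank-sum
identity and is cross-checked against an independent ROC implementation in
the tests. Whether a published operating point corresponds to threshold 0
or an ROC-optimized cut is generally ambiguous; the package reports the
threshold-0 point and the full curve, which subsumes both readings.

## ROI extraction

`extract_roi_mean()` averages the voxels inside an ROI mask that *strictly
exceed* 0.15. Averaging only supra-threshold voxels (rather than zeroing
sub-threshold voxels and averaging over all ROI voxels) follows standard
VBM practice of excluding non-grey-matter voxels from a regional mean; the
alternative reading would shrink every mean toward zero by a
mask-dependent factor. The strict `>` versus `≥` choice is
documented here because it is observable only on voxels exactly at the
threshold, which do not occur in continuous data. An ROI in which *no*
voxel survives the threshold raises an explicit error naming the ROI,
since it indicates a failed segmentation or registration upstream.

The eight ROI definitions ship as unions of AAL region names (e.g. PCC =
posterior cingulate L/R + precuneus L/R); integer atlas labels are
supplied by the user's atlas file, keeping the package free of
redistributed atlas data. Images and atlas must already share a grid — the
pipeline deliberately starts *after* segmentation, DARTEL-style
registration, modulation and smoothing, and performs no resampling.

## The synthetic-data generator

`sample_sem()` draws subject vectors by ancestral sampling of a
linear-Gaussian structural equation model; `dmn_reference_generators()`
packages two such models whose edge lists and weights transcribe the
published NC (10 edges) and AD (11 edges) DMN networks, with group sizes
101 and 80. Because only weights are published, the generators adopt zero
intercepts and unit noise variances as a stated convention, and exogenous
nodes are standard normal while children keep their implied (non-unit)
variance — this keeps the model exactly linear-Gaussian and makes OLS
recovery of the generating weights unbiased, which is what the parameter
recovery simulations measure.

What the generator emulates: the multivariate continuous covariance
structure induced by a group-specific DAG, at realistic group sizes. What
it does not emulate: scanner and site effects, age/sex covariates,
non-Gaussian tails, measurement noise correlated across ROIs, and any
mean-level atrophy differences between groups (both generators are
zero-mean). Consequently, passing simulations demonstrate correctness of
the estimators and calibration of the test under the model's own
assumptions — not that real AD/NC cohorts are separable to any particular
accuracy. Classification accuracy on synthetic cohorts (around 60–70% at
the reference effect sizes) reflects the overlap of the two reference
densities and is not comparable to accuracies on real cohorts, which are
driven additionally by mean atrophy.

Small NIfTI fixtures for the extraction stage place each ROI as an
axis-aligned slab of constant (optionally noised) intensity in a
background below threshold; they exercise the I/O and masking logic, with
no pretense of anatomical realism.

## Numerical choices and degenerate inputs

* Noise variances below $10^{-12}$ (exact fits) are errors, as are
  rank-deficient parent designs and zero-variance columns (named in the
  message).
* Score comparisons in search use a $10^{-12}$ strict-improvement margin;
  equivalence-class score agreement is asserted at $10^{-8}$.
* Two searches may return different members of the same equivalence
  class; their scores then agree only to floating summation error
  ($\sim 10^{-13}$), which is why oracle-equivalence tests compare scores
  at $10^{-9}$ *and* require identical equivalence classes.
* All randomness is scoped: generator configs carry their own seed,
  `hill_climb` and `permutation_test` take seed arguments, and
  `run_pipeline` derives per-stage substreams from one global seed so that
  changing the permutation count cannot perturb earlier stages. Identical
  configurations reproduce byte-identical artifacts.

## Simulation sizes used by the test suite

Parameter recovery runs 200 cohorts per group at the study group sizes
(101/80); permutation calibration uses 500 replicate null datasets of
$2 \times 100$ subjects with $B = 500$ permutations; oracle equivalence
uses 50 random 4-node datasets; density agreement 20 random 3–8-node
models at 100 evaluation points each. These sizes give Monte-Carlo
standard errors comfortably below the assertion tolerances (e.g. the
recovery means are tested at $\pm 0.03$ with standard errors below 0.01).

## Known limitations

* Orientation of individual learned edges is not interpretable (score
  equivalence); only skeletons and colliders are.
* The exact search scales as $O(d \cdot 3^{d-1})$ score lookups plus
  $O(2^d)$ subset states and is not intended beyond ~20 nodes.
* The permutation test compares coefficients for a *fixed* edge set; it
  does not test the presence or absence of edges, and no bootstrap
  intervals for individual weights are provided.
* Classification assumes the fitted Gaussian densities; heavy-tailed
  contamination will degrade both calibration and the density ratio.
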