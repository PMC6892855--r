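---
title: "Severity-matched symptom networks: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity-matched symptom networks: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevnet)
```

## The scientific problem

A recurring question in psychiatric epidemiology is whether psychopathology
becomes more *specific* as illness severity increases: do symptoms organise
into denser, more clearly clustered networks in severely affected groups than
in people with subthreshold complaints? Answering it by comparing symptom
networks across severity groups runs into a statistical trap: more severe
groups endorse symptoms more often, which inflates item variances, which
inflates covariances — the very quantity networks are built from. Any
comparison must first neutralise this severity-driven variance difference.

`sevnet` implements the full comparison pipeline for ordinal symptom-domain
data observed in K severity-ordered groups:

1. **Prevalence-matched binarization.** Per group and domain, an integer
   cutoff on the domain sum score (endorsed iff score ≥ cutoff) is chosen to
   bring each group's endorsement prevalence as close as possible to a common
   per-domain target. Since a binary variable's variance is $p(1-p)$,
   matching prevalences matches variances, removing severity as a confound.
2. **Ising network estimation (eLasso).** For each group, a pairwise Markov
   random field over the binary domains is estimated by nodewise
   L1-penalised logistic regression with EBIC penalty selection, symmetrised
   by the AND rule.
3. **Comparison.** Global network strength (the absolute sum of edge
   weights) is compared between every pair of groups by a permutation test
   that repeatedly regroups individuals and refits both networks; structural
   similarity is summarised by Spearman correlations of edge weights and the
   Jaccard index of edge sets.
4. **Community detection.** Walktrap and Girvan–Newman (edge betweenness)
   partitions, scored by weighted Newman modularity $Q$, with $Q > 0.30$
   flagged as clear community structure.
5. **Stability.** Nonparametric bootstrap CIs for every edge weight, and a
   parallel re-analysis on unweighted (presence/absence) networks.

## Models

### The Ising model in \{0,1\} coding

All binary vectors $x \in \{0,1\}^p$ have probability

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} \beta_{ij} x_i x_j\Big).$$

The coding matters: couplings in $\{0,1\}$ coding are *not* the couplings of
the equivalent $\{-1,+1\}$ model. We use $\{0,1\}$ throughout because it is
the parameterisation under which the conditional distribution of one node
given the rest is a logistic regression with intercept $\tau_i$ and slopes
$\beta_{ij}$ — exactly what the nodewise estimator fits, and what the exact
enumeration oracle verifies.

For $p \le 16$ the full state distribution is enumerated
(`enumerate_ising_distribution()`), giving an exact sampler
(`sample_ising_exact()`) and exact conditionals against which everything
else in the package is validated. Beyond that bound a single-site Gibbs
sampler (`sample_ising_gibbs()`, burn-in 1000 sweeps, thinning 10 by
default) stands in; the two samplers are required by the test suite to agree
in first and second moments on enumerable networks.

### The synthetic cohort

Because the motivating cohort data are access-restricted, the package ships
a generator (`cohort_spec()` + `generate_ordinal_cohort()`) that emulates
its structure with a known ground truth:

* **Eleven symptom domains** named after the constructs usually aggregated
  from broadband self-report questionnaires (core depression, negative
  cognitions, worrying, fearfulness, fatigue, substance use, pain, emotion
  dysregulation, attention problems, hyperactivity, impulsivity).
* **A planted dependence structure** (`default_ground_truth()`): an
  ADHD-like triple (ATT–HYP–IMP, couplings 2.0) and a
  depression/anxiety-like quadruple (DEP–NCOG–WOR–FEAR, couplings 1.5),
  each fully connected internally, with the remaining four domains
  unconnected. Thresholds are set so latent endorsement sits in a realistic
  0.18–0.31 band. This gives community detection a known answer: two planted
  communities, ground-truth modularity 0.48. The coupling strengths are
  calibrated so that the *estimated* networks at the default group sizes are
  connected and community-bearing: ordinal emission plus re-binarization
  attenuates latent dependence considerably, and couplings half this size
  leave the conservative EBIC estimator with near-empty networks at
  n ≈ 200–500 — unlike the well-connected networks real symptom-domain data
  produce at those sample sizes.
* **Four severity groups** of sizes 492, 205, 291 and 303 (the default),
  sharing the ground-truth network but shifted by severity offsets
  (0, 0.5, 1.0, 1.5 on the logit scale).
* **An ordinal emission model.** Each domain contributes 4 items scored
  0/1/2. Item scores follow a cumulative-logit distribution with location
  `item_base + latent_effect * z + offset` (defaults −1.2, 3.5, and the
  group offset; second cutpoint 2.2). With these values the mildest group
  shows strong floor effects (most items 0) and group mean scores increase
  with severity — the pattern the thresholding stage exists to neutralise.

What the generator does *not* emulate: item-level content and skip
structures, comorbidity patterns, demographic covariates, longitudinal
dependence, and any misspecification of the Ising form itself (the latent
states really are Ising-distributed). Passing tests therefore demonstrate
that the pipeline recovers truth *when the model class is correct*; they say
nothing about robustness to model misspecification in real questionnaires.

All randomness descends from one master seed via deterministic child seeds
(one per stage and group), so a cohort is a pure function of its spec.

### Threshold fitting

The cutoff search is exhaustive over integer cutoffs $1..\max(\text{score})$
with the deviation $|{\hat p} - p_\text{target}|$ minimised and ties broken
toward the lower cutoff (higher prevalence). The default per-domain target
is the pooled-sample prevalence at the most severe group's cutoff, where
that group's cutoff is the smallest integer bringing its own prevalence to
at most 0.5 — endorsement then marks the clearly elevated part of the scale
while keeping binary variance near its maximum. For stochastically ordered
groups this makes fitted cutoffs non-decreasing in severity.

Matched prevalences can only agree up to the discreteness of the achievable
prevalence ladder; `prevalence_discreteness_bound()` computes the bound and
the test suite asserts the cross-group range stays inside it. Equality of
variances is checked with the Brown–Forsythe test (median-centred Levene,
i.e. one-way ANOVA on $|x - \text{median}_g|$), chosen for robustness to the
extreme non-normality of binary data.

### Estimation: eLasso details

Each node is regressed on all others along a log-spaced penalty path from
the data-derived $\lambda_{\max}$ (the KKT bound
$\max_j |x_j'(y-\bar y)|/n$) down to `lambda_ratio` times it; defaults are
100 path points and ratio 0.01. The penalty is selected by

$$\mathrm{EBIC}_\gamma = -2\ell + k\log n + 2\gamma k \log(p-1),$$

with $\gamma = 0.25$ by default, the convention of the estimator's
reference implementation; because published analyses rarely report these
hyperparameters, both $\gamma$ and the AND/OR rule are configurable and
recorded in the output. Following standard pathwise
practice the path stops early once the fractional deviance-explained gain
per step falls below $10^{-5}$; without this rule, near-saturated tail
models enter the EBIC comparison and the estimator loses the characteristic
conservativeness on null data that the test suite asserts (an empty network
on independent-noise data in at least 90% of replicates).

The solver is an iteratively reweighted least squares loop with cyclic
coordinate descent on the quadratic approximation, using precomputed Gram
matrices so each sweep is $O(p^2)$ independent of $n$, warm starts along the
path, and a convergence tolerance of $10^{-7}$ on the maximum coefficient
change (non-convergence is an error naming the penalty index, never a
silent result). Unit tests pin the solver to two independent oracles:
`glm()` at $\lambda \to 0$ and `glmnet` at matched penalties.

Edge weights are the arithmetic mean of the two directed coefficients when
the inclusion rule admits the edge, and exactly 0 otherwise. Nodes constant
in a sample cannot be regressed; by default they are dropped with a warning
and reported isolated (inside permutation and bootstrap loops the event is
counted and reported instead, since resampling it away would bias the null).

### The permutation comparison test

For two groups, individuals are pooled and repeatedly regrouped at random
into samples of the original sizes; both networks are refitted with
identical estimator settings each time and $|\Delta S|$ recorded. The
p-value uses the add-one estimator $(1 + \#\{|\Delta S|_{perm} \ge
|\Delta S|_{obs}\}) / (1 + B)$, so its smallest attainable value is
$1/(B+1)$ and p = 0 is impossible. Zero–zero edge pairs are included in the
Spearman similarity (excluding them would condition on the outcome); the
Jaccard index of two empty edge sets is defined as 1 (identical structure),
a logged convention.

### Community detection

Modularity is computed on absolute edge weights — modularity is not defined
for negative weights, and estimated symptom-domain networks here are
essentially all-positive. Walktrap (walk length 4) supplies an agglomerative
merge tree and Girvan–Newman a divisive removal sequence; in both cases
*every* cut of the tree is rescored with the package's own weighted $Q$ and
the maximum is returned (ties toward fewer communities), so the reported
partition is optimal within the algorithm's own sequence. For edge
betweenness, weights are transformed to distances as $1/w$: strong edges are
short. An all-zero network returns the trivial single-community partition
with $Q = 0$, which by construction is also the $Q$ of the trivial partition
on every input. On every fixture with $p \le 8$ the test suite compares the
algorithmic $Q$ against `exhaustive_modularity()`, a restricted-growth-string
enumeration of all set partitions.

### Bootstrap stability

`bootstrap_edges()` resamples rows with replacement at the original $n$
(2500 resamples and 95% percentile intervals by default), refitting the full
network each time; each resample's seed is derived from the master seed by
counter, so results do not depend on execution order. The percentile CI
describes the sampling variability of the *regularised* estimator: because
EBIC-selected lasso weights are shrunk toward zero, these intervals are
biased low relative to the raw coupling and should not be read as strict
confidence intervals for it. The test suite's calibration check (planted
coupling 2.0, $n = 1500$, $p = 5$, 30 replicates of 200 resamples) makes
this concrete: the 95% percentile interval excludes zero in every replicate,
but its coverage of the generating coupling falls visibly short of nominal —
the shortfall being exactly the shrinkage bias of the point estimator. This
is a known property of regularised edge weights and the reason
the pipeline also reports selection frequencies and the unweighted
robustness re-analysis rather than leaning on CI endpoints.

## Problem sizes used in the shipped checks

The test suite exercises the pipeline at sizes chosen to make every
statistical property measurable with stable rates: estimator recovery uses
50 replicates of a planted 6-node chain at $n = 2000$ (and 50 independence
nulls at $n = 1000$); permutation-test calibration uses 200 replicates of a
200-permutation test at $n = 300$ per group with a reduced 30-point penalty
grid for the refits (the test's validity is estimator-agnostic — any fixed
statistic yields an exact permutation test — so the grid choice affects
power, not level); bootstrap calibration uses 30 replicates of 200
resamples. The acceptance script runs the full default cohort with 500
permutations per pairwise test and 250 bootstrap resamples per group.

## Known limitations

* Binarization discards within-domain severity information by design; the
  cost is lower sensitivity to dependence that only manifests in the upper
  ordinal categories.
* The estimator assumes the binary data are Ising-distributed; ordinal
  aggregation plus thresholding makes the latent structure recoverable but
  attenuated, so estimated couplings are not numerically comparable to the
  generator's latent couplings.
* Only two-group comparisons are supported by the permutation test (K-group
  analyses are reported as all pairwise tests, uncorrected; the `alpha`
  setting is a per-comparison level).
* Modularity-based detection inherits modularity's resolution limit; with
  11 nodes this is immaterial, but the package should not be used unchanged
  for networks with hundreds of nodes.
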