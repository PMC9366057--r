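---
title: "Dual Gaussian Bayesian networks for MMPI-2 profiles: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual Gaussian Bayesian networks for MMPI-2 profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpibn)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and the design decisions taken where more than one
reasonable choice existed.

## The model

Profiles are vectors of thirteen MMPI-2 T-scores in a fixed canonical
order (`mmpi_scales()`): the validity scales L, F, K and the ten clinical
scales. T-scores are standardized questionnaire scores (population mean
50, SD 10); we analyze them on their raw scale, without re-standardizing,
because the clinical literature reports and interprets effects in T-score
units and because Pearson correlations — the downstream contrast of
interest — are unaffected by affine rescaling.

Each diagnostic group gets its own linear-Gaussian Bayesian network: a
DAG in which every scale is normally distributed around a linear function
of its parents,

$$Y \mid \mathrm{pa}(Y) \sim \mathcal{N}\!\big(c + \beta^\top \mathrm{pa}(Y),\ \sigma^2\big).$$

The joint distribution of such a network is multivariate normal with
mean $(I-B)^{-1}c$ and covariance $(I-B)^{-1} D (I-B)^{-\top}$, where $B$
stacks the coefficient vectors and $D = \mathrm{diag}(\sigma^2)$
(`to_joint_mvn()`). This closed form is used three ways: as the oracle
that the factorized density must reproduce (a property the test suite
checks to $10^{-8}$), as the basis for exact Schur-complement
conditioning in the what-if analysis, and for computing the
generator-implied correlations.

Arcs encode *statistical* dependence only. Nothing in the pipeline
licenses a causal (interventional) reading, and the what-if stage is
deliberately observational conditioning, not a do-intervention — with a
multivariate normal joint, conditioning is the only operation with an
exact closed form, and the scientific question ("given this observed
Sc score, what do the two groups' models predict for D and Pt?") is a
conditional-expectation question.

## Fitting and scoring

Parameters are maximum likelihood: ordinary least squares for $(c,
\beta)$ and the residual variance with denominator $n$ (not $n - p$).
The ML convention matters only in third-decimal ways at $n = 714$, but
it makes the per-family log-likelihood exactly the quantity the network
score maximizes, so the two are kept consistent. On data with an exact
linear dependence the residual variance is pure cancellation error
($\sim 10^{-15}$ relative); it is snapped to exactly zero below a
$10^{-12}$ relative threshold so that deterministic relationships are
represented honestly as $\sigma = 0$ rather than as a tiny spurious
noise level. A $\sigma = 0$ node then has no finite joint density:
evaluating a profile off the deterministic value returns $-\infty$, and
evaluating one on it raises an error rather than fabricating a density —
degenerate models should fail loudly in a pipeline, not silently.

The network score is the penalized log-likelihood form of BIC, higher is
better, with $k = |\mathrm{pa}| + 2$ free parameters per family (slopes,
intercept, variance):

$$\mathrm{BIC}(G) = \sum_j \left[\widehat{\ell}_j - \tfrac{k_j}{2}\log n\right].$$

This is the convention common to network-learning toolchains, and it is
*score equivalent*: Markov-equivalent DAGs receive identical scores
(verified numerically on enumerated 2–4-node equivalence classes). Score
equivalence is why the learned object should be interpreted as an
equivalence class (CPDAG) rather than as oriented causal arrows. Arc
strength is the BIC drop when one arc is deleted, the standard rendering
weight for network figures.

## Structure learning

The learner is a hybrid of the H2PC family: a constraint-based phase
proposes an undirected skeleton, then a score-based search is confined
to it.

* **CI test.** Fisher-z on partial correlations:
  $z = \operatorname{atanh}(r)\sqrt{n - |S| - 3}$, two-sided normal
  p-value. Exact under the Gaussian model the networks assume anyway.
* **Neighbor discovery.** Grow-shrink per node: greedily admit the
  candidate with the smallest p-value below $\alpha$ given the current
  set, then prune members rendered independent by any subset (size
  $\le$ `max_sepset`) of the remaining ones. Candidates are scanned in
  canonical scale order, making the result deterministic.
* **Skeleton.** The AND rule (both endpoints must nominate each other).
  The conservative choice: fewer false edges at the cost of a little
  recall, appropriate because the skeleton only *restricts* the score
  search that follows.
* **Search.** Greedy hill climbing from the empty graph over additions
  (skeleton-restricted), deletions and reversals, accepting the single
  best strictly improving move, ties broken in a fixed
  (operation, parent, child) order.

Defaults: $\alpha = 0.05$, `max_sepset = 3`. These are the common
toolchain defaults; nothing in the analysis is sensitive to `max_sepset`
at $p = 13$, and $\alpha$ trades skeleton recall against false edges in
the usual way. The grow phase conditions on its whole current set but
stops growing when $n - |S| - 3 \le 0$, so degenerate inputs (ten rows,
thirteen variables) degrade gracefully instead of crashing.

One search detail deserves its own paragraph. Because BIC is score
equivalent, hill climbing can converge onto a *plateau*: a set of
Markov-equivalent DAGs connected by score-neutral reversals, from some
member of which a strictly better move exists (the classic case is a
fork that should be a collider: each single reversal is score-neutral,
only the second one pays off). A strictly-greedy climber is blind to
this. `hill_climb()` therefore performs deterministic plateau traversal
at every local optimum: breadth-first over score-neutral reversals with
memoized states (bounded by `plateau_cap = 200`), resuming the climb
from the first plateau member that offers a strict improvement. On
enumerable problems (all 25 three-node DAGs; 543 four-node DAGs) this
makes the search reach the global optimum in every three-node instance
we generate and in well over 80% of four-node instances, without
sacrificing reproducibility — there are no random restarts anywhere.

## The classifier and its evaluation

With one network per group, classification is the likelihood ratio
$S(x) = \log p(x \mid G_h) - \log p(x \mid G_s) + \log(n_h / n_s)$,
healthy iff $S(x) > 0$, ties to healthy. The prior-odds term comes from
the training split's class frequencies; under the matched 714 + 714
design it is zero, which is precisely the regime in which likelihood
ratios are an honest posterior-odds surrogate.

Evaluation is 100-iteration random shuffle-split cross-validation:
stratified 80/20 splits, the *entire* model — skeleton, structure,
parameters — re-learned on each training part. Re-learning inside every
split is the leakage-free reading of the protocol; reusing a structure
learned on all data would let test information shape the model. Splits
are stratified so both strata stay fittable. Metrics: accuracy; F1 with
schizophrenia as the positive class (it is the detection target); AUC by
the rank/Mann–Whitney formulation with ties credited one half, which the
suite verifies against an $O(n^2)$ all-pairs brute force, ties included.
The comparison baseline is a logistic regression on the D/Pt/Sc
("Scale 278") T-scores under the identical split protocol.

On the synthetic design the dual-network classifier reaches the Bayes
accuracy of the generating model to within a few points (the acceptance
suite bounds the gap at three points), and collapses to chance when both
groups are generated from a single network — the two calibration poles
that matter.

## Correlation contrast and the permutation test

The group contrast that motivates everything is the difference of
Pearson correlation matrices. For a global test of "same correlation
matrix", the package uses a label-permutation test: statistic = the
Frobenius norm of the off-diagonal correlation difference (a `maxabs`
variant is available), null distribution built by permuting group labels
over pooled rows, p-value with the add-one convention
$(1 + \#\{T_{perm} \ge T_{obs}\})/(n_{perm} + 1)$, which can never
return an exact zero. The permutation design needs no distributional
assumptions about the correlation estimates, is exactly level-$\alpha$
under exchangeability (the suite checks the rejection rate lands in
[0.03, 0.07] at $\alpha = 0.05$), and has ample power to separate the
two calibrated networks at $n = 714$ per group.

## What the synthetic generator does — and does not — emulate

`mmpi2_preset()` builds the two calibrated 13-node networks. Arc set:
seven adjacencies shared by both groups (L–K, K–Hy, Hs–Hy, Pt–Sc, F–Sc,
D–Si, Pd–Pt), strong D–Pt, Pd–Ma and F–Hs coupling only in the healthy
network, and an Hs–Sc arc only in the patient network. Orientations
follow canonical scale order (earlier scale → later scale), because the
published figure's orientations are not recoverable from text and, for a
score-equivalent learner, only the equivalence class matters.

Calibration works on the standardized scale: arc coefficients are chosen
so the implied correlations hit the published group values exactly
(Pt–D 0.74 healthy / 0.29 patients; Pd–Ma 0.61 / 0.41; F–Hs
0.55 / 0.63 — possible in closed form because each node's parents are
mutually independent in these structures), residual variances are set so
every marginal variance is one, and each marginal is then affinely
rescaled to its published group mean and SD. Affine rescaling leaves the
correlation matrix untouched, which the tests assert numerically.

One structural decision was forced here. In the patient group the
published correlations Pt–D = 0.29 and Pd–Ma = 0.41 coexist with the
statement that the D–Pt and Pd–Ma *arcs* appear only in the healthy
network: in the real 21-arc patient network those residual correlations
travel through arcs the publication does not name, but a 13-node preset
restricted to the named arcs would leave D⫫Pt and Pd⫫Ma exactly
(correlation zero), contradicting the published values and severing the
D–Pt–Sc pathways the what-if analysis studies. The preset therefore
carries the patient-group residual correlation through weak direct
D→Pt (0.29) and Pd→Ma (0.41) arcs — attenuation rather than absence.
Interpretationally the headline contrast is preserved: the *strong*
coupling exists only in the healthy network. The patient preset has 11
arcs and the healthy preset 10; neither attempts to reproduce the full
unpublished 16- and 21-arc structures.

`make_two_group_study()` adds demographics: age $\mathcal{N}(28, 12^2)$
truncated to [16, 70] years; 75% male; education
$\mathcal{N}(11.4, 3.4^2)$ years truncated at zero; 30% married — the
published cohort summaries rounded to generator-friendly values. Marital
status is Bernoulli(0.30) even though the published SD for that row
(0.66) exceeds what any Bernoulli allows; we treat that SD as a
reporting artifact. Two knobs exist for exercising the matching stage:
`age_confounding` shifts the patient group's mean age (default analyses
use +5 years), and `healthy_pool_ratio` generates an oversized healthy
screening pool (the motivating study matched 714 patients against a
3,135-candidate pool, ratio ≈ 4.4). The pool matters: greedy 1:1
matching on *balanced* groups has a structural residual bias of roughly
0.1 SMD under a shifted confounder, because high-propensity patients
exhaust the comparable controls; with a 4:1 pool the same matcher
balances all four covariates below 0.1 SMD in ~98% of replicates.

What the generator does **not** emulate, and what passing tests
therefore do not show: real T-score marginals are bounded, skewed and
discretized, not Gaussian; real scale dependence need not be linear;
item-level response behavior (and the three MMPI-2 form lengths in the
original pool) is not modeled; and demographic covariates are
independent of the scales by construction, so matching cannot change the
profile distributions here — it demonstrates balance machinery, not
confounding control of the psychometric signal. Classifier accuracies on
this generator (≈ 0.80) describe the synthetic design, not any clinical
population; they say the *method* tracks its Bayes optimum, not that
schizophrenia is 80%-detectable from MMPI-2 profiles.

## Matching

Propensity scores come from a main-effects logistic regression of the
diagnosis on age, gender, education and marital status.
(Quasi-)separation is detected and raised as an error with advice,
rather than silently returning probabilities of 0/1. Matching is greedy
nearest-neighbor 1:1 without replacement on the *logit* of the score,
caliper 0.2 SDs of the logit (the conventional caliper), patients
processed in descending score order, distance ties to the smallest
control index — fully deterministic. This deliberately simplifies the
optimal full matching used in the motivating study: the downstream
analyses need only a balanced 1:1 cohort, and greedy matching with an
adequate control pool delivers that; network-flow optimal matching is
out of scope.

## Numerical and degenerate-input choices

* Partial correlations come from the inverse of the relevant correlation
  submatrix, with an SVD pseudo-inverse fallback for (near-)singular
  conditioning sets; $|r|$ within $10^{-12}$ of 1 is flagged `saturated`
  with p = 0.
* Conditional covariances are symmetrized after each Schur complement;
  conditional sampling uses an eigendecomposition square root, so
  positive-*semi*definite conditionals (deterministic directions) sample
  correctly.
* Strict-improvement threshold in the hill climb is $10^{-10}$;
  "score-neutral" in plateau traversal means $|\Delta| \le 10^{-10}$.
  Both are far below any data-driven score difference at the sample
  sizes involved and far above double-precision noise on scores of
  magnitude $10^4$.
* All stochastic functions take a `seed` and restore the caller's RNG
  state (`withr`); given a seed, every artifact in the pipeline is
  bit-reproducible.

## Problem sizes used by the test and acceptance suites

The suites run at sizes chosen to make every statistical assertion
sharp but quick: parameter recovery at $n = 10{,}000$ over 20 networks;
structure recovery on preset data at $n = 5{,}000$ over 20 seeds
(skeleton F1 ≈ 0.97, mean CPDAG SHD ≈ 0.4 against truth); CI-test
calibration over 2,000 null replicates at $n = 200$; search optimality
against full 3- and 4-node DAG enumerations; classifier consistency at
the study scale $n = 714$ per group with 10-iteration cross-validation
across 3 seeds against a 50,000-sample Bayes oracle; permutation-test
calibration over 400 nulls at 500 permutations and power at
$n = 714$/group over 20 seeds; matching balance over 50 confounded
cohorts at full pool scale. The analysis scripts run the full
100-iteration protocol.

## Known limitations

Beyond the generator caveats above: the networks are strictly linear
and Gaussian — hybrid discrete/continuous modeling (e.g., putting the
diagnosis or gender *inside* the network) is not supported; arc
confidence (bootstrap/model averaging) is not implemented; the
permutation test is global, with no per-entry multiplicity-corrected
localization of which correlations differ; and greedy search with
plateau traversal, while exact on enumerable problems, carries no
optimality guarantee at $p = 13$.
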