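# mmpibn — dual Gaussian Bayesian networks for MMPI-2 profiles

`mmpibn` analyzes how the thirteen MMPI-2 scales (validity scales L, F, K
and clinical scales Hs, D, Hy, Pd, Mf, Pa, Pt, Sc, Ma, Si; all T-scores)
depend on one another, and how that dependence structure differs between
healthy adults and patients with schizophrenia. It is aimed at
psychometric and clinical researchers who want to go beyond comparing
scale means: the object of study is the *network* of linear relations
among scales, estimated separately per diagnostic group.

## The model

Each group's profile distribution is modeled as a linear-Gaussian
Bayesian network on a DAG G: for every scale `Y` with parents `X`,

    Y = c + beta' X + eps,    eps ~ N(0, sigma^2)

so the joint is multivariate normal. Structure is learned by a hybrid
constraint/score algorithm in the H2PC family: Fisher-z partial-correlation
tests (`z = atanh(r) * sqrt(n - |cond| - 3)`) drive a grow-shrink discovery
of each node's neighbors; the AND-rule skeleton then restricts a greedy
hill climb that maximizes the decomposable BIC
`sum_j [ max loglik_j - (k_j / 2) log n ]`. Parameters are maximum
likelihood (OLS coefficients, residual variance with denominator n).

Fitting one network per group turns the pair into a generative
classifier: a new profile `x` is scored by the log likelihood ratio

    S(x) = log p(x | G_healthy) - log p(x | G_schiz) + log(n_h / n_s)

and called healthy when `S(x) > 0`. Around this core the package
provides propensity-score matching of the two groups on demographics,
repeated random shuffle-split cross-validation (accuracy, F1, rank-based
AUC), a permutation test for equality of the two groups' Pearson
correlation matrices (off-diagonal Frobenius statistic), and exact
Schur-complement conditioning for "what-if" imputation: clamp one scale,
read off what each group's network predicts for the others.

Because the motivating clinical cohort is not publicly deposited, the
package ships a calibrated synthetic generator (`mmpi2_preset()`,
`make_two_group_study()`): two 13-node networks whose marginal means/SDs
match published group summaries and whose key correlations (Pt–D 0.74 vs
0.29, Pd–Ma 0.61 vs 0.41, F–Hs 0.55 vs 0.63) reproduce the reported
group contrast. Every pipeline stage is testable against this generator's
known ground truth.

## Worked example

```r
library(mmpibn)

# a study-scale synthetic cohort: 714 patients, a 4.4x healthy pool,
# and a +5-year age confounder for matching to remove
cohort <- make_two_group_study(
  study_config(n_per_group = 714, age_confounding = 5,
               healthy_pool_ratio = 4.4), seed = 1)

ms <- match_study(cohort)              # propensity matching
nrow(ms$match$pairs)                   # 714 matched pairs
max(abs(ms$balance$smd_post))          # 0.058 — all |SMD| < 0.1

matched <- ms$cohort
evaluate_rsscv(matched, iterations = 100, seed = 2)
#> 100-iteration shuffle-split evaluation
#>   accuracy: 0.800 (0.019)
#>   F1:       0.803 (0.019)
#>   AUC:      0.890 (0.015)
```

The classifier sits close to the Bayes optimum of the generating model
(about 0.80 accuracy on this synthetic design), and well above the
logistic baseline using only the D/Pt/Sc scales (about 0.59): the signal
separating the groups lives in the dependence structure, not only in
three scale levels.

```r
x_h <- matched$profiles[matched$labels == 0, ]
x_s <- matched$profiles[matched$labels == 1, ]
ct <- permutation_equality_test(x_h, x_s, n_perm = 9999, seed = 3)
ct$p_value                              # 1e-04: correlation structures differ
round(ct$corr_a["Pt", "D"] - ct$corr_b["Pt", "D"], 2)   # ~0.45 gap
```

The full analysis is laid out as numbered scripts under `analysis/`
(simulate → match → learn → evaluate → compare correlations → what-if),
each a thin narrative driver over the package functions, writing its
tables under `results/`.

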