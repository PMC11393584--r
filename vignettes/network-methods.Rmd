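---
title: "Estimating and comparing psychometric symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing psychometric symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psychnet)
```

## The model

psychnet analyses questionnaire items as nodes of a Gaussian graphical
model (GGM). Under the GGM, items are jointly multivariate normal with
precision matrix $\Theta$, and an edge between items $i$ and $j$ carries
the regularized partial correlation

$$w_{ij} = -\,\theta_{ij}\,/\,\sqrt{\theta_{ii}\,\theta_{jj}},$$

the association between two items after conditioning on all others. A zero
$\theta_{ij}$ means conditional independence, so the sparsity pattern of
$\Theta$ *is* the network.

$\Theta$ is estimated by the graphical lasso: maximize
$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i \neq j}
|\theta_{ij}|$ over positive-definite $\Theta$, where $S$ is the item
correlation matrix. The penalty is applied to off-diagonal entries only
(the diagonal is unpenalized), which is the convention of psychometric
network estimation. The solver is a block coordinate descent over the
columns of the working covariance, each column solved as an L1-penalized
regression, implemented in C++ so bootstrap and permutation procedures can
re-estimate thousands of networks. Convergence is declared when the
largest parameter change in a sweep drops below `tol` (default `1e-6`,
maximum 10,000 sweeps). The unit tests check this solver against two
independent routes: the closed-form solution at $p = 2$ and an ADMM solver
for the same objective, with agreement around $10^{-10}$ — far inside the
$10^{-4}$ we consider equivalent.

The penalty is selected by the extended Bayesian information criterion

$$\mathrm{EBIC}_\gamma = -2L + E\log n + 4\gamma E \log p,$$

with $L$ the Gaussian log-likelihood of the fitted $\Theta$, $E$ the number
of nonzero edges, and $\gamma = 0.5$ the conventional default; the path has
100 logarithmically spaced $\lambda$ values from $\lambda_{\max} =
\max_{i\neq j}|S_{ij}|$ (the smallest penalty giving an empty network)
down to $0.01\,\lambda_{\max}$. EBIC ties are broken toward the larger
$\lambda$, i.e. the sparser model. All of this is configurable through
`estimate_network()`.

**Correlation input.** Items are ordinal (4-point Likert), and the
networks are estimated from Pearson correlations of the raw codes by
default, with Spearman behind a flag. Polychoric correlations would treat
ordinality head-on but introduce their own estimation noise at these
category counts; they are deliberately out of scope, and the attenuation
this costs is quantified below.

## Centrality conventions

Four indices per node: **strength** $\sum_j |w_{ij}|$; **expected
influence** $\sum_j w_{ij}$ (signed, one-step); **closeness** and
**betweenness** computed on shortest paths with edge lengths $1/|w_{ij}|$.
Closeness is $1/\sum_{j} d(i,j)$ and set to 0 when any node is unreachable;
betweenness splits equal-length geodesics fractionally and excludes
endpoints. `centrality_table()` reports raw and z-standardized columns,
since published figures are usually standardized while worked examples
quote raw values. Betweenness is validated against exhaustive path
enumeration on small graphs.

## Stability: the case-dropping bootstrap

`case_dropping_bootstrap()` re-estimates the network on subsamples that
retain $\lceil (1-q)n \rceil$ rows for each drop proportion $q$ in a grid
of ten equal steps from 0.05 to 0.75, and correlates each subsample's
centrality vector with the full-sample one. The CS-coefficient is the
largest $q$ at which the empirical 5th percentile of those correlations
still reaches 0.7 — "with 95% probability the subsample centralities
correlate at least 0.7 with the original". The 0.05–0.75 ten-point grid is
the one on which conventionally reported CS values (0.05, 0.60, 0.67,
0.75) land after rounding. A CS of 0 is reported when even dropping 5%
fails the criterion, read as "< 0.05".

## Group comparison: permutation invariance tests

`nct()` compares two groups' networks with the permutation scheme of the
network comparison test: the observed statistic is computed from networks
estimated per group with identical settings, the null distribution by
pooling all rows, re-splitting them at random into the original group
sizes and re-running the *entire* estimator (including $\lambda$
selection) per permuted group — the conservative choice that propagates
model-selection variability into the null. Two global statistics are
reported: $M = \max_{i<j} |w^A_{ij} - w^B_{ij}|$ for structure invariance
and $S = |\,\mathrm{GS}_A - \mathrm{GS}_B|$ for global-strength invariance,
$\mathrm{GS} = \sum_{i<j}|w_{ij}|$. P-values use add-one smoothing,
$(\#\{ \text{perm} \ge \text{obs}\} + 1)/(B + 1)$, so they can never be
exactly zero; the unsmoothed count is available behind a flag. Per-edge
differences reuse the same permutation draws, are reported uncorrected by
default (Holm behind a flag, matching how published per-edge p-values in
this literature are typically raw), and are classified as strengthened /
weakened / lost / new link with group A fixed as the control group.

The suite checks calibration directly: across null replicates (two groups
drawn from one network) the rejection rate of $S$ at $\alpha = 0.05$ must
stay within [0.01, 0.10].

## Bridge centrality

With communities fixed a priori by instrument (GSES items vs PHQ-9 items —
the "clusters" of the motivating design, not detected algorithmically),
bridge strength is the per-node sum of absolute cross-community weights and
bridge expected influence its signed companion. Bridge plus
within-community strength equals total strength exactly, which the tests
assert. The combined 19-node network for bridge analysis is estimated on
the pooled sample of both groups, since that is how a single
bridge network is conventionally presented; a per-group analysis is a
one-liner with the same functions.

## The synthetic-data generator

No raw questionnaire data are distributed, so the generator is a
first-class module that emulates the motivating study's conditions:

* two groups — 3,094 controls and 560 depressed participants — answering
  10 GSES items (codes 1–4) and 9 PHQ-9 items (codes 0–3);
* a planted control network: within-instrument blocks with 82% of possible
  edges at weights uniform in [0.03, 0.20] (dense, weak-positive item
  networks, the empirical signature of these instruments), no
  cross-instrument edges except five negative bridges concentrated on S6
  and D9 with weights −0.04 to −0.06;
* a depressed network derived from the control one by eight edge edits
  (two strengthened, two weakened, one removed, three added — the
  published change-profile semantics, planted at the published weights)
  plus a global-strength deficit planted at exactly 0.25 over the GSES
  block by uniformly rescaling the unedited block edges;
* ordinal responses drawn from the latent-Gaussian threshold model: latent
  rows $\sim N(0, \Sigma)$ with $\Sigma$ the correlation matrix implied by
  the planted partial correlations, discretized at per-item thresholds.
  Default thresholds reproduce group-level marginals close to the
  published totals (GSES means ≈ 27.3 vs 21.9; PHQ-9 means ≈ 3.4 vs 13.9);
* covariates (age, gender, education) drawn from the published group
  margins.

Positive-definiteness is enforced by uniform shrinkage (factor 0.9 per
step, tolerance `1e-8`, at most 100 steps) of *non-protected* edges only,
so planted edits and bridges survive repair exactly; an infeasible edit
raises a construction error rather than silently moving the target.

Seeds: one master seed; every stage (network construction, each group's
sampling, covariates, each bootstrap, the permutation test) derives its own
child stream deterministically, so the full pipeline is bit-reproducible.

**What the generator does not emulate.** Latent-Gaussian discretization
attenuates correlations (the tests pin the attenuation against numerical
integration of the discretized-normal moments), but real Likert data also
carry item-specific response styles, local dependence and measurement
non-invariance between groups. Passing recovery tests on this generator
therefore shows the estimator chain works under a clean ordinal GGM; it
does not certify behaviour under model misspecification. One visible
consequence: a planted "lost" edge (true weight exactly 0 in one group)
can re-appear as a small estimated weight because discretization distorts
the correlation matrix away from exact GGM consistency, so the change
classifier may report "weakened" rather than "lost" — the direction is
recovered, the literal zero is not guaranteed.

## Problem sizes and numerical choices

The default analysis estimates 10-node group networks and one 19-node
pooled network; bootstraps default to $B = 1000$ and the comparison test
to 1000 permutations. The test suite and the numbered analysis scripts run
reduced designs (hundreds of bootstraps, 100–500 permutations, groups of a
few hundred rows) chosen so each experiment still has the statistical
resolution its assertion needs — e.g. null calibration uses 100–200
replicates, which bounds a true 5% rate away from the asserted [0.01,
0.10] band with high probability. Degenerate inputs are handled
explicitly: constant items are an error naming the item; mildly indefinite
correlation matrices are repaired by eigenvalue clipping and flagged;
$n < p$ estimation proceeds with a warning (the penalty handles it) but
fewer than 10 rows is an error; empty networks report `NA` mean edge
weight rather than NaN.

## Design choices that were genuinely open

* **Student's pooled-variance t, not Welch**: recomputing the published
  group table from its printed summaries matches the pooled statistic
  (17.08, 3.08) and not Welch's, so the summary-based `pooled_t()`
  implements the pooled form and documents it.
* **Yates continuity correction for 2×2 tables only**: the published
  gender statistic (14.92) matches the corrected value (uncorrected
  ≈ 15.28); larger tables are uncorrected (education ≈ 8.60).
* **Cutoff conventions**: PHQ-9 ≥ 10 defines the depressed group; mild
  scorers (5–9) are controls with no further exclusions; severity bands
  10–14 / 15–19 / ≥ 20.
* **Gender/education coding** for correlation tables: {male 0, female 1}
  and ordinal {1, 2, 3}.
* **Analysis configuration** is a validated R list (`analysis_config()`)
  rather than an external YAML schema: every consumer of this package
  drives it from R scripts, where a constructor with defaults is both the
  validator and the documentation.

## Known limitations

Pearson-on-ordinal attenuates edge weights by roughly 10–15% at four
categories; group comparisons remain valid because both groups are
attenuated alike, but absolute weights are biased toward zero. The NCT
$S$ statistic inherits sample-size asymmetry: with very unequal groups the
smaller group's network is sparser at the same truth, which inflates
observed strength differences — visible in the default study, where the
planted 0.25 gap is over-estimated unless group sizes are balanced.
Betweenness is unstable at these network sizes (its CS-coefficient is
expected near the grid floor), a property of the index, not a defect of
the bootstrap.
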