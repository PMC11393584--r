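# psychnet

Psychometric network analysis of ordinal questionnaire data: regularized
partial-correlation (Gaussian graphical model) networks, centrality and
bridge centrality, bootstrap stability, and permutation-based two-group
network comparison — with a synthetic two-group Likert-data generator so
the whole pipeline is testable end to end without access to raw
questionnaire data.

The package is written for researchers studying symptom networks — here,
the interplay of self-efficacy (10-item GSES, codes 1–4) and adolescent
depressive symptoms (9-item PHQ-9, codes 0–3) — who want the standard
network-psychometrics toolchain as plain, tested R functions.

## The method

Items are nodes of a Gaussian graphical model. Edges carry regularized
partial correlations $w_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$
from a sparse precision matrix $\Theta$ estimated by the graphical lasso,

$$\hat\Theta = \arg\max_{\Theta \succ 0}\; \log\det\Theta -
\mathrm{tr}(S\Theta) - \lambda \sum_{i\neq j} |\theta_{ij}|,$$

solved by block coordinate descent (C++), with $\lambda$ chosen on a
100-point log-spaced path by the extended BIC
($\mathrm{EBIC}_\gamma = -2L + E\log n + 4\gamma E\log p$, $\gamma = 0.5$).
On top of the estimated networks:

* **Centrality** — strength, closeness, betweenness, expected influence
  (distances $1/|w_{ij}|$), raw and z-standardized (`centrality_table()`);
* **Stability** — nonparametric edge bootstrap and the case-dropping
  subset bootstrap with the CS-coefficient: the largest case-drop
  proportion at which subsample centralities still correlate ≥ 0.7 with
  the full sample, with 95% probability (`cs_coefficient()`);
* **Comparison** — permutation network comparison test with structure
  statistic $M = \max_{i<j}|w^A_{ij}-w^B_{ij}|$, global-strength statistic
  $S = |\mathrm{GS}_A-\mathrm{GS}_B|$, and per-edge invariance tests with
  a strengthened / weakened / lost / new-link taxonomy (`nct()`,
  `edge_difference_tests()`);
* **Bridge analysis** — bridge strength and bridge expected influence
  across a-priori item communities (`bridge_table()`);
* **Generator** — planted sparse partial-correlation truths with exact
  edge edits and an exact global-strength gap, ordinal data via the
  latent-Gaussian threshold model (`generate_two_group_study()`).

## Worked example

The numbered scripts under `analysis/` run the full study replica on the
synthetic sample (3,094 controls, 560 depressed; seed 1). `Rscript
analysis/01_simulate.R` writes the data, then:

```text
$ Rscript analysis/03_networks.R
control: 43/45 edges (95.56%), mean |w| = 0.082, GS = 3.507
  highest strength: s5 (0.98 raw, 2.18 z)
depressed: 38/45 edges (84.44%), mean |w| = 0.076, GS = 2.894
  highest strength: s5 (0.90 raw, 1.86 z)

$ Rscript analysis/05_comparison.R
Network comparison test (500 permutations)
  M = 0.145 (p = 0.030)   S = 0.613 (p = 0.004)
  global strength: A = 3.507, B = 2.894
8 of 45 edges change significantly:
   from  to weight_a weight_b abs_diff       p       change
2    s1  s3  0.01920   0.1085   0.0893 0.02196 strengthened
3    s2  s3  0.14087   0.0000   0.1409 0.00399         lost
...

$ Rscript analysis/06_bridge.R
strongest cross-community edges:
  from to weight
1   S6 D9 -0.065
2   S1 D9 -0.060
...
key bridge nodes: D9 (0.18) and S6 (0.13)
```

Read: both groups show dense, weakly positive self-efficacy networks; the
depressed group's network is less interconnected (lower global strength,
significant $S$), specific edges strengthen, weaken or vanish (the planted
change profile is recovered, e.g. the lost s2–s3 edge), and the
self-efficacy–depression link concentrates on the S6 and D9 bridge nodes
with negative cross-community edges. Stage 4 reports CS-coefficients per
group and index (e.g. strength 0.75 in the control group, and betweenness
as low as 0.05 — betweenness is unstable at these network sizes, as
expected).

The `vignettes/network-methods.Rmd` vignette documents the model,
conventions, generator assumptions and numerical choices.

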