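---
title: "Methods: a hierarchical belief-network analysis of household water treatment behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hierarchical belief-network analysis of household water treatment behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwtbbn)
```

## The model

`hwtbbn` analyses household interview surveys about point-of-use drinking
water treatment (HWT). Each household contributes three blocks of answers:
socio-economic characteristics (SEC) — parental education, religion, water
access, a binary asset checklist —, sixteen psychological items organised by
the RANAS framework into Risk, Attitude, Norm, Ability and Self-regulation
sub-factors (five-point Likert scales plus one binary barrier-planning item),
and five HWT behaviour items (a binary self-report plus four frequency /
habit / intention questions).

The analysis treats behaviour as the output of a three-layer discrete
Bayesian belief network: the eight SEC variables are root nodes, the five
RANAS factors are intermediate nodes, and the discretized behaviour
(non-user / irregular user / regular user) is the single sink. Every SEC node
is a parent of every RANAS node and every RANAS node is a parent of the
behaviour node; there is no direct SEC → behaviour edge. This encodes the
mediation assumption that socio-economic conditions act on behaviour only
through household psychology. `network_spec()` accepts any alternative DAG
(read from YAML via `read_network_spec()`), because the mediation structure
is a modelling assumption, not a finding.

### Continuous indices and discretization

Each latent construct is summarised by the first principal component (PC1) of
its standardized items: the asset checklist for the wealth index (the
DHS convention — heterogeneous item scales are why the decomposition uses the
correlation, not covariance, matrix), the sub-factor items per RANAS factor,
and the five behaviour items. Reverse-coded items declared in the codebook
are flipped first. PC1 has a sign ambiguity; we fix it by requiring a
non-negative correlation between the score and the mean of the *standardized*
items. Anchoring on the standardized mean (rather than the raw item mean)
makes scores invariant to positive affine rescaling of any item; jointly
negating all items then flips the scores exactly, which is the correct
semantics — a scale whose every item is reversed measures the opposite
construct.

Missing items are mean-imputed within a factor when at least half of that
factor's items are observed; otherwise the factor score, and hence the node
state, is missing and is handled by EM downstream. This keeps every
interviewed household in the network stage while the regression stage (below)
uses listwise deletion.

Scores are discretized by rank: wealth 40/40/20 into Poor/Middle/Rich,
everything else into tertiles. Cut sizes are `diff(ceiling(cumsum(q) * m))`
over the `m` non-missing scores and ties are broken by household id, so
category counts are exact and the whole pipeline is byte-reproducible. One
degenerate case is special-cased: if every non-missing score is identical the
vector carries no ordering information and all households are assigned the
lowest state, with a warning. Cutpoints are recorded on the returned dataset.

### CPT estimation

With complete data, each conditional probability table (CPT) cell is
`(count + ess/k) / (config total + ess)` where `k` is the child's state count
and `ess` a symmetric Dirichlet prior ("equivalent sample size") per parent
configuration. The default `prior_ess = 1` is deliberate: under the
complete-bipartite structure each RANAS CPT has 3,456 parent configurations,
vastly more than any realistic survey has households, and pure maximum
likelihood would leave most columns undefined. Unvisited columns with zero
prior default to the uniform distribution.

Under missing data, `em_learn()` iterates an exact E-step — for every
household and every family (node plus parents) containing a missing member,
the posterior over the missing members given all of the household's observed
nodes, computed by variable elimination — and the smoothed M-step above. With
`prior_ess > 0` the fixed point maximizes the Dirichlet-penalized
log-likelihood, and it is that penalized objective whose trace is asserted to
be non-decreasing on every run (the raw observed-data log-likelihood is also
recorded; with smoothing it need not be monotone). Convergence is declared
when the relative objective change falls below `tol = 1e-6`, with
`max_iter = 500`. Initialization is uniform CPTs by default — deterministic,
and on complete data the algorithm reduces to the counting estimator after a
single iteration — with seeded Dirichlet-random restarts available.

### Exact inference

Queries are answered exactly. The production path is variable elimination
with a greedy min-weight elimination order (alphabetical tie-break, so runs
are deterministic); a brute-force enumeration of the factored joint (capped
at 10^7 configurations) serves as an independent oracle, and the two are
asserted to agree within 1e-9 on hundreds of random networks. Evidence with
zero prior mass raises an "impossible evidence" error rather than returning
NaNs; querying a node that is itself evidence returns the degenerate
posterior.

### Model interrogation

* **ΔP inference.** For each non-target node and state, the node is clamped
  as hard evidence and P(behaviour = regular) recomputed; a node's ΔP is the
  spread (max − min) of those updated probabilities. Probabilities are
  reported as integer percentages, but the spread is computed on unrounded
  values and rounded last, so the reported column is internally consistent.
  Impossible states are excluded from the spread with a warning.
* **Scenario propagation** returns the full three-state outcome posterior for
  a clamped node distribution (a non-degenerate distribution yields the
  corresponding mixture of clamped posteriors).
* **Sensitivity analysis.** Under proportional co-variation (the complement
  of a perturbed CPT entry rescales to keep the column normalized) the
  evidence-free target probability is linear in each CPT column, so the
  derivative with respect to every entry of a node's CPT follows in closed
  form from two family-marginal inference runs — one with the target clamped,
  one without. Entries at the simplex boundary fall back to one-sided linear
  evaluation, which is exact for the same linearity reason. Central finite
  differences serve as the numerical oracle in the tests. A node's aggregate
  is the maximum absolute derivative over its parameters; because a
  parameter's derivative scales with the probability of reaching its column,
  this aggregate is most meaningful when comparing nodes within the same
  layer.
* **Cross-validation.** Folds (default k = 10) are stratified by observed
  outcome state from a seeded permutation (default seed 0), so they are
  reproducible; households with missing outcome train but are never scored.
  Each held-out household is predicted from all of its observed non-outcome
  nodes. Per-class one-vs-rest AUC uses the rank (Mann–Whitney) statistic
  with ties counted half; the single summary is the unweighted macro average
  — the aggregation behind a single published multiclass AUC is rarely
  stated, and the macro average is the neutral choice. Accuracy uses argmax
  with ties broken by state order.

### Supporting classical statistics

The forced-entry regression fits the behaviour score on all sixteen
sub-factor items at once (no selection) after listwise deletion, reporting B,
SE(B), the standardized beta `B·sd(x)/sd(y)`, t and two-sided p values,
adjusted R², and significance stars at 0.05/0.01/0.001. The binary
barrier-planning item enters as a raw 0/1 regressor. Chi-square tests are
Pearson, without continuity correction, with structural-zero expected cells
rejected. P values are reported, never used for automated decisions.

## The synthetic survey generator

`make_ground_truth()` builds a fully known generative model used by every
end-to-end test. Its CPTs follow a monotone logistic parameterization: parent
states are scored evenly in [−1, 1], a weighted mean of parent scores shifts
the child's logits, and one effect-size knob per edge group (`effect_sec`,
`effect_hwt`, with per-node weights) controls the gaps. Column weights are
then iteratively calibrated so every latent marginal equals its
discretization fractions (uniform thirds; 40/40/20 for wealth) — this keeps
the rank-based quantile cut consistent with the latent states, so
discretization error reflects emission noise rather than a marginal mismatch.
Likert items are emitted as `round(clamp(Normal(mu_state, sigma), 1, 5))`
with means 2/3/4; binary items are Bernoulli; every cell is masked missing
independently (MCAR) with probability `missing_rate`.

The study-like defaults encode the surveyed population as published:
marginals such as 16.8% of mothers and 25.7% of fathers without formal
education and a 55% recent child-diarrhea rate; `sigma = 1.2`, giving total
item dispersions near the reported 1.2–1.5 SD range; `missing_rate = 0.012`,
which leaves roughly three quarters of households complete across the
twenty-one regression variables, matching the published analysis attrition;
strong behaviour effects (`effect_hwt = 1.8`) consistent with the very high
reported regression fit; and SEC weights that make maternal education the
dominant characteristic and recent diarrhea negligible, mirroring the
study's qualitative findings. These are generative *conditions*, not targets:
no published model output (ΔP values, AUC) was used to adjust them.

What the generator does **not** emulate: response styles (acquiescence,
social desirability), informative missingness, within-village clustering, or
item-level factor cross-loadings. Passing tests therefore demonstrate that
the pipeline recovers the truth of *this* data-generating process, not that
real interview data satisfy its assumptions.

### The recovery benchmark

Per-column CPT recovery on the complete-bipartite structure is statistically
impossible at survey scale (3,456 columns versus a few thousand households),
so the estimator benchmark `recovery_ground_truth()` uses a pruned,
identifiable configuration chosen on identifiability grounds before any
results were inspected: two SEC parents per RANAS node (every SEC node still
used), low emission noise `sigma = 0.3`, no missingness. In that regime the
information loss of the discretization stage is small and reported separately
(the latent-state recovery rate), so the reach-weighted CPT L1 distance —
each column weighted by its exact probability of being reached under the
true model — measures estimator error. The tests run 20 generator seeds at
n = 5000 and check the median weighted L1 and the recovery of the ΔP node
ranking for pairs whose true ΔP differs by at least five points.

One published-style check is knowingly beyond reach at these conditions: a
null model (all behaviour CPT columns uniform) should show ΔP ≈ 0, but with
243 outcome columns at n = 5000 (~20 observations each) each clamped-node
posterior carries roughly a percentage point of sampling noise, so the
largest spread across thirteen nodes is typically several points. The
corresponding test asserts the idealized one-point bound and documents the
failure rather than relaxing it, because shrinking the noise away would mean
smoothing the estimate toward the very null being tested.

## Problem sizes and runtime choices

Test and acceptance runs use the sizes the analyses were designed for:
study-scale pipelines at n = 202 with ten-fold cross-validation, recovery at
n = 5000 over 20 seeds, generator-marginal convergence at n = 20,000, and
oracle equivalence over 200 random 5–8-node networks. The enumeration oracle
is restricted to networks whose joint state space fits in 10^7
configurations; all larger inference goes through variable elimination.

## Known limitations

* The complete-bipartite default structure is honest about its cost: at
  n ≈ 200 the smoothed RANAS CPTs retain little SEC signal, clamped-SEC ΔP
  values shrink toward zero and cross-validated AUC sits near chance. Sparser
  structures (supplied as YAML) are the remedy when interpretable SEC effects
  are required at survey scale.
* Hard evidence only: scenario distributions are handled as mixtures of
  clamped posteriors, not as virtual (likelihood) evidence.
* No structure learning, no continuous or hybrid nodes, no sampling-based
  inference, no missing-not-at-random mechanisms.
* The per-node sensitivity aggregate compares naturally within a layer;
  across layers it is confounded by the number and reach of parameters.
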