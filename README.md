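# hwtbbn

Determinants of household water treatment (HWT) behaviour, modelled with a
hierarchical discrete Bayesian belief network (BBN).

## The problem

In many low- and middle-income settings piped or stored water is not reliably
safe, and point-of-use treatment — boiling, filtration, chlorination, solar
disinfection — only protects health when it is practised *regularly*.
Interview surveys can measure both a household's socio-economic
characteristics (SEC: parental education, wealth, religion, water access) and
its psychology towards treatment, structured here by the RANAS framework
(**R**isk, **A**ttitude, **N**orms, **A**bility, **S**elf-regulation, each
measured by several Likert sub-factor items). The package is for researchers
and WASH-programme analysts who want to turn such a survey into a causal
what-if model: *which characteristic or psychological factor, if improved,
would most raise the probability of regular treatment?*

## The model

The analysis pipeline is:

1. **Index construction.** A relative wealth index is the first principal
   component (PC1) of the binary asset checklist (the DHS convention); each
   RANAS factor and the HWT behaviour outcome is the PC1 of its standardized
   items (reverse-coded items flipped, within-factor mean imputation when at
   least half the items are observed).
2. **Discretization.** Wealth is cut 40/40/20 into Poor/Middle/Rich; the five
   factor scores and the behaviour score are cut into rank-based tertiles
   (Low/Moderate/High; non-user / irregular user / regular user).
3. **Network learning.** A three-layer directed acyclic graph — 8 SEC root
   nodes → 5 RANAS nodes → 1 behaviour node, with SEC effects fully mediated
   by the psychological layer — carries one conditional probability table
   (CPT) per node, estimated by expectation-maximization: the E-step computes
   each household's exact posterior over its missing node states by variable
   elimination, the M-step re-estimates CPTs from expected counts under a
   symmetric Dirichlet prior.
4. **Interrogation.** Predictive ΔP inference (clamp each node to each of its
   states, read off the updated P(behaviour = regular); ΔP = max − min),
   CPT sensitivity under proportional co-variation (exact derivatives of the
   target probability with respect to every CPT entry), ten-fold stratified
   cross-validation with one-vs-rest ROC AUC, plus a forced-entry OLS of the
   behaviour score on all sixteen sub-factor items and chi-square tests of
   independence.

A synthetic survey generator with a known ground-truth network (ancestral
sampling, Likert/Bernoulli item emission, MCAR missingness) makes every stage
testable end to end and quantifies how well CPTs and ΔP rankings are
recovered.

## Worked example

```r
library(hwtbbn)

truth <- make_ground_truth()                 # study-like generative model
sim   <- generate_survey(truth, n = 202, seed = 1)
print(sim$survey)
#> Household survey: 202 households, 36 variables (82 missing cells, 0 invalid cells coerced to missing)

an <- hwt_pipeline(sim$survey, cv_k = 10)
print(an)
#> Household water treatment determinant analysis
#>   households: 202; EM iterations: 12
#>   baseline P(hwt_behaviour): non-user 33%, irregular user 33%, regular user 33%
#> Predictive inference for P(hwt_behaviour = regular user)
#>   baseline: 33%
#>                node delta_p
#>                risk       9
#>     self_regulation       8
#>            attitude       8
#>                norm       4
#>             ability       3
#>    mother_education       0
#>              wealth       0
#>            religion       0
#>    father_education       0
#>       accessibility       0
#>  information_access       0
#>        access_water       0
#>      health_problem       0
#>   CV: accuracy 31.7%, macro AUC 0.489
```

Reading the output: the baseline chance of a household being a regular
treater is 33%; `delta_p` is how many percentage points that chance moves
between the worst and best state of each node when it is clamped as hard
evidence. At n = 202 the default complete-bipartite structure leaves each
RANAS CPT with 3,456 parent configurations, so SEC-level effects are heavily
smoothed away and the cross-validated AUC sits near chance — an honest
property of this structure at this sample size, which is why the package also
ships a pruned, identifiable configuration (`recovery_ground_truth()`) for
benchmarking the estimator itself:

```r
rec <- recovery_experiment(recovery_ground_truth(), n = 5000, seeds = 1:20)
print(rec)
#> Recovery over 20 seed(s): median reach-weighted CPT L1 = 0.0415
#>   delta-P ranking agreement: 100% of seeds; mean state recovery 94.1%
```

A thin command line covers the same stages
(`simulate`, `score`, `discretize`, `learn`, `infer`, `delta-p`,
`sensitivity`, `cv`, `regress`, `chisq`, `recover`, `all`):

```sh
Rscript inst/cli/hwtbbn.R simulate --out sim --seed 3
Rscript inst/cli/hwtbbn.R all --paths.survey=sim/survey.csv --out results
```

To analyse a real survey, supply a codebook mapping its column headers onto
the instrument vocabulary (see `inst/extdata/codebook.yaml`) and call
`reproduce_study("survey.xlsx", read_codebook("codebook.yaml"))`.

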