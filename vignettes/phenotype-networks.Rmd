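---
title: "Cross-prediction phenotype networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-prediction phenotype networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Symptom-defined conditions such as functional bowel disorders resist the
usual diagnostic workflow: there is no biomarker, subtype labels overlap and
shift, and much of what matters to the patient — impact on daily life,
treatment response, healthcare burden — is only loosely coupled to the
diagnostic label. `phenonet` implements a deep-phenotyping strategy for such
questionnaire cohorts: instead of modelling one outcome, it models *every*
feature from all the others, then asks what the resulting web of
predictability says about how patient factors organise.

The pipeline has four stages:

1. **Cross-prediction.** For each eligible target feature, a tuned
   gradient-boosted tree model is fitted on all features not trivially
   related to it. Held-out performance says what *can* be known about a
   patient factor from the rest of their data.
2. **Importance network.** The per-target feature importances form a
   directed weighted graph: edge $j \to i$ carries the scaled importance of
   feature $j$ in the model predicting feature $i$.
3. **Community structure.** A nested weighted stochastic block model (SBM),
   fitted by minimum description length (MDL), compresses the network into a
   two-level hierarchy of feature communities.
4. **Centrality contrasts.** Weighted eigenvector, hub and authority
   centralities, z-scored and compared across second-level communities by
   one-way ANOVA with Tukey HSD, quantify which communities act as hubs
   (pointing at much of the network) versus authorities and influencers
   (concentrating incoming predictive weight).

Because the motivating cohort data cannot be redistributed, the package
ships a synthetic-cohort generator with planted structure; every claim the
test suite makes is a claim about recovery of known ground truth or about
internal mathematical consistency, not about any real cohort.

## The synthetic cohort generator

`generate_cohort()` draws, per patient, `n_latent` independent standard
normal factors $z$ and forms each feature as $x_j = \ell_j^\top z +
\varepsilon_j$ with $\varepsilon_j \sim N(0, \sigma_j^2)$. Binary features
are thresholded at the quantile matching their target prevalence; ordinal
features are cut at equal-probability quantiles into integer codes $1..L$.
Quantile discretisation preserves rank dependence, so Pearson-based stages
behave as they do on real Likert data. The generator records which factor
dominates each feature (`ground_truth`), which is what recovery tests score
against.

Defaults emulate the intended study conditions: 1000 patients, 40 features
in 8 questionnaire domains (demographics, nosology, pain, bowel habit,
treatment, life impact, healthcare, COVID), 4 cross-domain latent factors
with loadings 0.8 and residual SD 0.6, treatment use/effectiveness pairs
sharing a relatedness group, two rare binary flags (minority fractions 0.03
and 0.02) that trip the 20:1 imbalance gate, and 15% missing-at-random
cells. The 40-feature schema is a desk-scale stand-in for a table roughly
50% larger; nothing in the machinery depends on that size.

Missingness is injected by a logistic missing-at-random mechanism: cell
$(i, j)$ is masked with probability $\mathrm{logit}^{-1}(a + \beta z_i)$
where $z_i$ is the patient's standardised value of a single always-observed
driver feature (age by default) and $a$ is calibrated by root finding so the
expected masked fraction equals the requested rate. This is the simplest
mechanism that depends only on observed data — hence testable as MAR — and
the slope is a parameter, so tests can verify that masking tracks the
driver.

What the generator does *not* emulate: real item wording and instrument
scoring, non-monotone dependencies between features, informative (MNAR)
missingness, and measurement error correlated across items. Passing
recovery tests therefore show the machinery is sound, not that any
particular clinical conclusion transfers.

## Preprocessing chain

The chain mirrors standard practice for questionnaire tables, with every
leakage-sensitive parameter fitted on training rows only:

* **Missingness filters.** Rows with more than 40% missing cells are
  removed first; columns are then re-assessed on the surviving rows and
  removed above the same threshold. Strict inequality at the boundary.
* **Imputation.** Chained equations with predictive mean matching (PMM):
  each incomplete column is regressed on all others (logistic for binary,
  linear on the integer codes otherwise — ordinal features are treated as
  continuous codes inside the regressions) and each missing cell takes the
  observed value of one of the `pmm_donors = 5` donors nearest in predicted
  mean. PMM guarantees imputed values lie in the observed support and that
  observed cells are never touched. `imputation_config()` defaults to 50
  chains of 50 sweeps; the pipeline's default desk scale is 5 chains of 10
  sweeps, which the stability tests show is already reproducible at the
  cohort sizes used here. The chains are pooled into one locked table —
  cell-wise mean for continuous columns, modal value for categorical ones —
  because all downstream analysis operates on a single locked database;
  per-analysis pooling across imputations is deliberately out of scope.
* **Clamping and normalisation.** Ordinal/continuous columns are winsorised
  at the 0.1th and 99.9th percentiles (linear-interpolation percentiles,
  i.e. `quantile(type = 7)`) and min–max scaled to [0, 1]; binary columns
  pass through. Bounds come from training rows and are applied unchanged to
  test rows.
* **Split.** A uniform random 80:20 partition without stratification (the
  simplest defensible default); the test rows are frozen before any tuning.
* **Imbalance gate.** A categorical target whose majority:minority count
  ratio on training rows exceeds 20:1 is excluded as a target but kept as a
  predictor.
* **SMOTE.** Classification training data are balanced by synthetic
  minority oversampling — each synthetic case is $p + u(q - p)$ for a
  minority row $p$, one of its $k = 5$ nearest minority neighbours $q$ and
  $u \sim U(0,1)$ — applied once to the training partition before
  cross-validation, never to test rows. Applying it inside each fold would
  also be defensible; the once-per-partition choice matches the protocol
  the pipeline documents and keeps fold scores comparable across the grid.

## Cross-prediction models

Targets are classification tasks when binary or ordinal with at most 7
levels (the cap keeps Likert items as classifiers while long scales become
regressions), otherwise regression on the z-scored value (training mean/SD),
so errors are comparable across targets with different ranges. Leakage
exclusion is schema-driven: all features sharing the target's relatedness
group are dropped from its predictor set, plus any configured name-pattern
matches (the regular-expression generalisation).

Models are gradient-boosted trees (xgboost) tuned by exhaustive grid search
over six axes — learning rate, boosting rounds, depth, row subsampling,
minimum split gain, minimum child weight — with 5-fold cross-validation
scored by negative log loss (classifiers) or RMSE (regressors). The `desk`
grid (4 combinations, 20 fits per target) keeps a full suite tractable on
one CPU; the `full` preset has cardinality 3240 (16,200 fits per target at
5 folds) and is intended for bookkeeping and full-scale runs. Grid values
themselves are configuration, not science: the tests pin the protocol
(fit-count arithmetic, degenerate-grid equivalence, leakage bit-identity),
not specific hyperparameters.

Feature importance is the split-count (frequency) vector of the refit
model, normalised to the unit simplex per target so edge weights are
comparable across targets with different tree counts. Attributions are
additive SHAP values on test rows; local accuracy (base value + row sum =
raw margin) is enforced in tests at a relative tolerance of 1e-6 because
the tree library computes margins in single precision — absolute agreement
to 1e-6 is not meaningful on wide logit margins.

## The importance network and its block model

The suite's importance vectors assemble into a directed weighted graph with
one node per feature (gated targets included, as nodes without incoming
edges) and per-target incoming weights summing to 1. Node size is the sum
of outgoing weights: a feature's total importance in predicting everything
else. No pruning is applied by default (`min_weight = 0`).

Communities are inferred with a degree-corrected directed SBM under an MDL
objective, in nats:

$$
\Sigma \;=\;
-\sum_{rs} e_{rs}\ln\frac{e_{rs}}{e_r^{\mathrm{out}} e_s^{\mathrm{in}}}
\;+\; \ln\binom{B^2 + E - 1}{E}
\;+\; \ln\binom{N-1}{B-1} + \ln\frac{N!}{\prod_r n_r!}
\;+\; \sum_{rs: e_{rs}>0}\Big[ e_{rs}\big(\ln\tfrac{W_{rs}}{e_{rs}} + 1\big)
      + \tfrac12\ln e_{rs} \Big]
$$

where $e_{rs}$ counts edges from block $r$ to block $s$, $W_{rs}$ sums
their weights, and the last bracket is the negative exponential
log-likelihood of the edge weights under the plug-in MLE rate
$\hat\lambda_{rs} = e_{rs}/W_{rs}$ with a $\tfrac12\ln e_{rs}$ penalty per
fitted rate. Exponential weights are the natural first choice for positive,
right-skewed importance weights. Partition-independent constants (the
degree-sequence encoding) are dropped, as they cancel when comparing
partitions of one graph; consequently $\Sigma$ values are comparable across
partitions, not across graphs. The graph is treated as simple-directed with
a weight likelihood; block multigraph multiplicities enter at the next
level.

Optimisation is simulated annealing with a record-keeping stop rule:
initialisation agglomerates greedily from one block per node all the way
down to a single block — accepting locally worsening merges, because the
landscape between the singleton end and the planted scale is not monotone —
with greedy single-node resettling sweeps between merges, keeping the best
state seen. Annealing then refines with 80% single-node moves
(neighbour-informed proposals) and 20% merge/split moves under a Metropolis
rule whose inverse temperature ramps geometrically from 1 to 10, stopping
after 1000 proposals without a new record-low $\Sigma$; three independent
restarts per fit return the best record, which is polished by greedy sweeps.
The trivial one-block partition is always evaluated, so the result never
loses to it. On all bundled 8-node fixtures the search attains the
exhaustively enumerated global minimum (Bell(8) = 4140 partitions), and
30-node three-block plants with a 5:1 weight ratio are recovered at
adjusted Rand index 1 in essentially every seeded run.

The hierarchy has exactly two levels: level 0 partitions the feature graph;
level 1 partitions the level-0 block multigraph (multiplicities $e_{rs}$,
weights $W_{rs}$). All community-level statistics read level 1, and deeper
hierarchies are out of scope.

## Centralities and block contrasts

Eigenvector centrality is computed on the symmetrised matrix $W + W^\top$
(direction is captured separately by HITS, and symmetrisation guarantees a
real non-negative leading eigenvector) by shifted power iteration to 1e-10;
the Gershgorin shift removes sign-flip oscillation on bipartite-like
spectra without changing the leading eigenvector. HITS iterates
$a \leftarrow W^\top h$, $h \leftarrow W a$ with L2 normalisation;
equivalently the leading eigenvectors of $W^\top W$ and $W W^\top$. All raw
score vectors have unit Euclidean norm and are z-scored across nodes before
testing.

Community contrasts are one-way ANOVA on the z-scored metric across
level-1 blocks followed by all pairwise Tukey HSD comparisons via the
studentized range distribution; blocks with fewer than two nodes are
excluded. A block is flagged "top" when its mean exceeds every other
block's and all its pairwise comparisons are significant. Each metric is
tested per panel without cross-metric correction; centralities of nodes in
one network are not independent, so these p-values are conservative
screens, which the report states explicitly.

## Numerical choices and degenerate inputs

* Percentiles everywhere use linear interpolation between order statistics.
* Constant columns: an error in the correlation stage (correlation is
  undefined), a warned all-zero column in normalisation, a skipped target
  in model fitting.
* A column with no observed values is a hard imputation error; imputation
  assumes inputs already passed the 40% filters.
* SMOTE reduces `k` with a warning when a minority class is small and
  refuses classes with fewer than 2 members.
* Block-state bookkeeping is incremental for single-node moves (with
  residue zapping at 1e-9 so emptied block pairs are exactly zero) and
  recomputed from scratch for merge/split moves; equality of the two paths
  is a tested invariant.
* All randomness flows from per-stage seeds derived from one master seed;
  rerunning any stage with the same seed is bit-identical, which the
  pipeline manifest makes checkable via file checksums.

## Problem sizes used by tests and the acceptance script

Unit and acceptance tests run the full pipeline at the generator's default
scale (1000 × 40, desk grid) and the block-model suites at 8–30 nodes;
imputation tests use 2–5 chains of 3–10 sweeps. These sizes were chosen so
the whole battery documents the method's behaviour in minutes on a single
CPU while remaining at the scale regime the defaults emulate; every size is
a config parameter, and `grid = "full"` with `imputation_config()` defaults
restores the full protocol cardinality.

## Known limitations

* The SBM weight family is exponential only; model selection across weight
  families is out of scope.
* Eigenvector centrality on directed graphs is direction-ambiguous; the
  symmetrisation choice is principled but not unique.
* The single locked imputed table discards between-imputation variance;
  downstream standard errors are conditional on the lock.
* Split-count importance is one of several importance notions; SHAP-based
  edge weights are a natural alternative the graph stage could adopt.
* Synthetic cohorts are linear-Gaussian under the hood; real questionnaire
  dependence is richer, so real-data performance claims are outside what
  this package can certify.
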