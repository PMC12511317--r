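# phenonet

Deep phenotyping of mixed-type patient questionnaire cohorts by
**cross-prediction**: every feature is predicted from all non-trivially
related others with tuned gradient-boosted tree models; the per-target
feature importances form a directed weighted network; a nested weighted
stochastic block model compresses that network into feature communities; and
community-level centralities quantify which groups of patient factors act as
*hubs* (pointing at much of the network) versus *authorities and
influencers* (concentrating incoming predictive weight). The package is
aimed at biostatisticians studying symptom-defined conditions — functional
bowel disorders are the motivating case — where the diagnostic label is only
one of many interacting facets of the patient's lived experience.

## The method in brief

For each eligible target feature $i$ (binary / short-ordinal features as
classifiers, long-ordinal / continuous as regressors on the z-scored value),
an xgboost model is tuned by exhaustive grid search with 5-fold
cross-validation inside a frozen 80:20 training partition — negative log
loss for classifiers, RMSE for regressors — with minority classes
oversampled by SMOTE on the training rows only and features sharing the
target's relatedness group excluded from its predictor set. Targets with
training class imbalance beyond 20:1 are gated out. The normalised
split-count importances $w_{ji}$ become edges $j \to i$ of a directed
weighted graph (incoming weights of each fitted target sum to 1).

Communities minimise a description length combining a degree-corrected
directed block-model code for the edge counts $e_{rs}$ with an exponential
likelihood for the edge weights (plug-in rate $e_{rs}/W_{rs}$, penalty
$\frac12\ln e_{rs}$ per rate), optimised by agglomeration plus simulated
annealing (inverse temperature 1 → 10, stop after 1000 proposals without a
record). Level 1 of the two-level hierarchy partitions the block
multigraph. Per node, weighted eigenvector centrality (on $W + W^\top$) and
HITS hub/authority scores are z-scored and compared across level-1
communities by one-way ANOVA with Tukey HSD.

Because the motivating cohort cannot be redistributed, a synthetic-cohort
generator with planted cross-domain latent structure, missing-at-random
masking and class imbalance stands in for it, exposing ground truth for
recovery tests. See the methods vignette
(`vignettes/phenotype-networks.Rmd`) for models, parameters and design
choices.

## Worked example

```r
library(phenonet)
state <- run_pipeline("runs/demo", config = pheno_config(seed = 7))
state$nested
#> <nested_state> L0: 4 blocks, L1: 4 blocks, joint DL 11525.971 nats
```

The run directory now holds the locked cohort, correlation maps (CSV +
Newick dendrogram), the suite report, the importance network (GraphML), the
partition, centrality tables and a manifest with per-file checksums. The
best-predicted regression targets on the held-out rows:

```r
rep <- state$suite$report
head(rep[rep$status == "fitted" & rep$task == "regression", ], 5)
#>                  target      domain performance
#>                     age demographic   0.3227332
#>           health_rating life_impact   0.6310854
#>  work_productivity_loss life_impact   0.5430882
#>  symptom_duration_years    nosology   0.5166671
#>           pain_severity        pain   0.5419428
```

`performance` is test-set R² for regressors (balanced accuracy for
classifiers): the synthetic cohort's life-impact measures are the most
predictable from the rest of the table, exactly the planted cross-domain
structure. The feature-occurrence tally counts how often each feature ranks
in the top 5 importances across all 38 fitted models:

```r
head(sort(state$suite$occurrence, decreasing = TRUE), 5)
#>                    age work_productivity_loss symptom_duration_years
#>                     30                     28                     26
#>          health_rating          pain_severity
#>                     24                     22
```

Community contrasts on the z-scored centralities (level-1 blocks):

```r
block_contrast(state$centrality, "hub")
#> <block_contrast> hub: F = 594.146, p = 1.06e-30; top block(s): 4
block_contrast(state$centrality, "eigenvector")
#> <block_contrast> eigenvector: F = 91.947, p = 6.12e-17; top block(s): 4
```

Block 4 — the community of strong continuous predictors (age, health
rating, productivity loss, pain severity) — is flagged as significantly
more hub-like and influential than every other community, with mean hub
z-score 2.45 against at most 0.03 elsewhere. On a real cohort this readout
is the headline: it says which families of patient factors organise the
predictability of everything else.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/phenonet.R`:

```sh
Rscript inst/scripts/phenonet.R all --seed 7 --outdir runs/demo
Rscript inst/scripts/phenonet.R sbm --outdir runs/demo   # re-run one stage from cache
```

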