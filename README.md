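# prednet

Confounder screening for high-dimensional categorical survey data via
**predictive networks**: every one-hot dummy variable is predicted from all
the others with a gradient-boosted tree ensemble, the per-target gain
importances become the edges of a directed weighted graph, and variables are
ranked by **hub centrality** — the principal eigenvector of $AA^{\top}$.
Variables that carry predictive information about many other variables (the
classic signature of a confounder such as gender or socioeconomic status)
surface at the top of the ranking. The whole analysis replicates over strata
(e.g. geographic regions), with cross-stratum agreement of hub scores
quantified by Pearson correlation.

It is aimed at epidemiologists and survey analysts who need to know *which
variables to adjust for* before running association analyses on
questionnaire data with hundreds of categorical items.

## The method in brief

For a survey encoded into $N$ binary dummies:

1. For each dummy $j$ (skipping constant ones), fit a boosted ensemble
   (default 100 trees, max depth 4, Bernoulli deviance, Newton leaf steps)
   on a 70% training slice, **excluding all sibling dummies of $j$'s source
   variable** from the predictor set — they jointly determine $j$ and would
   leak the answer. Test-set AUC measures each model's accuracy.
2. Set $A_{ij}$ = total squared-error reduction ("gain") from splits on
   dummy $i$ in the model for $j$; rows are outgoing links, columns
   incoming. No edge thresholds are applied.
3. Hub scores = principal eigenvector of $AA^{\top}$ (power iteration,
   max-normalized so the top hub is 1); report the top-5 by mean hub score
   across strata, plus the strata-by-strata Pearson correlation matrix.

## Worked example

Simulate a survey with a known planted structure — one binary confounder
driving 12 dependent binary items (log-odds effect 2) plus 12 independent
noise items, in 3 strata of 2,000 subjects — then run the pipeline:

```r
library(prednet)

tab <- simulate_survey(sim_config(seed = 11))
tab
#> categorical_table: 6000 subjects x 25 variables, 3 strata

report <- run_pipeline(tab, seed = 11)
report
#> replication_report: 3 strata, 50 nodes
#> top hubs by mean hub score:
#>        node     score rank
#>    conf_1=0 1.0000000    1
#>    conf_1=1 0.9131676    2
#>  noise_11=0 0.2088036    3
#>  noise_10=0 0.1989570    4
#>   noise_2=0 0.1957836    5
#> cross-stratum Pearson r: min 0.9936
```

Both dummies of the planted confounder `conf_1` dominate the hub ranking
(scores 1.00 and 0.91, against ≤ 0.21 for everything else), and the hub
vectors replicate across the three strata almost perfectly (all pairwise
Pearson r ≥ 0.99). The per-target test AUCs behave as the structure
dictates — dependent items are predictable, noise items are not:

```r
aucs <- do.call(rbind, report$auc_tables)
median(aucs$auc[grepl("^dep_",   aucs$target)], na.rm = TRUE)
#> [1] 0.7126637
median(aucs$auc[grepl("^noise_", aucs$target)], na.rm = TRUE)
#> [1] 0.4921695
```

`write_report(report, "out/")` exports per-stratum hub and AUC tables, the
mean-hub table, the correlation matrix, the top-k ranking, a run log and a
config echo as TSV/JSON.

The same analysis is available from the shell (the script installs to
`exec/prednet` inside the package):

```sh
prednet simulate --out survey.csv --seed 11
prednet run --input survey.csv --stratum stratum --out report/ --seed 11
```

with further subcommands `encode`, `fit`, `network`, `hubs`, and `report`
for running the stages separately on files.

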