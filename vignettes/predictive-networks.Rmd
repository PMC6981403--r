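---
title: "Predictive networks for confounder screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive networks for confounder screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Large categorical surveys — health questionnaires with hundreds of items —
have a covariance structure far too rich for pairwise association tests, and
association analyses on them are vulnerable to confounding by variables
(gender, socioeconomic status, broad behavioural traits) that influence many
items at once. `prednet` screens for such variables without assuming
linearity or picking outcomes in advance, by asking a symmetric question of
every variable: *how well can it be predicted from all the others, and which
variables do the predicting?*

The procedure is:

1. **One-hot encoding.** Every categorical variable with $k$ observed levels
   becomes $k$ binary dummies named `variable=level` (full one-hot, not
   $k-1$ reference coding, because each dummy must in turn serve as a
   two-class prediction target). Missing answers become an explicit
   `MISSING` level rather than dropped rows, so per-target sample sizes stay
   identical across targets; surveys routinely let respondents skip
   sensitive items, and row deletion would bias each target differently.
2. **Per-target boosted models.** For each non-degenerate dummy $j$, a
   gradient-boosted ensemble of shallow regression trees is fitted on a
   70% training slice, with every dummy from *other* source variables as a
   candidate predictor. Sibling dummies of the target's own variable are
   excluded wholesale: within a one-hot block the siblings jointly determine
   the target (the block row-sums are 1), so admitting them would leak the
   answer and the network would merely rediscover the encoding.
3. **Gain importance.** The importance of predictor $i$ for target $j$ is
   the total squared-error reduction of all tree splits on $i$ across the
   ensemble. Summing rather than averaging over trees is a per-model
   constant factor ($1/T$) and cannot change any ranking.
4. **The network.** $A_{ij}$ = importance of $i$ in the model for $j$; rows
   are outgoing links, columns incoming. No edge thresholding of any kind is
   applied. Hub scores are the principal eigenvector of $A A^{\top}$
   (Perron–Frobenius guarantees a nonnegative one), max-normalized so the
   top hub scores 1. A high hub score means the variable carries predictive
   information about many other variables — exactly the signature of a
   potential confounder.
5. **Stratified replication.** The entire analysis runs independently per
   stratum (e.g. geographic region); hub vectors are averaged across strata,
   their agreement is quantified by pairwise Pearson correlation over nodes,
   and the final ranking (top 5 by default) uses the mean hub score.

## The boosting model

The classifier is Bernoulli-deviance gradient boosting with Newton leaf
steps. With $p_i = \sigma(F(x_i))$:

- $F_0 = \log(\bar y / (1 - \bar y))$, the training base-rate log-odds;
- each iteration fits a regression tree to the residuals $y_i - p_i$; a
  split on binary feature $f$ scores
  $\mathrm{gain}(f) = \frac{n_L n_R}{n}(\bar r_L - \bar r_R)^2$,
  identically $SSE_{parent} - SSE_L - SSE_R$, maximized by exhaustive search
  over admissible features;
- each leaf takes the Newton step
  $\sum r_i / \sum p_i (1 - p_i)$, shrunk by the learning rate.

Defaults: **100 trees, maximum depth 4** (the reference setting for
survey-scale predictive networks), learning rate 0.1, minimum leaf size 10,
no row or column subsampling — the customary defaults of production GBM
implementations. With no subsampling the fit is exactly deterministic, which
is what makes byte-identical replication of whole runs possible.

Numerical choices worth knowing:

- **Tie-breaking.** Equal-gain splits go to the lowest column index. Ties
  are real, not hypothetical: the two dummies of a binary variable induce
  complementary, equally pure partitions. A strict-improvement threshold of
  $10^{-15}$ keeps the choice deterministic under floating-point noise.
- **Degenerate nodes.** A node with zero residual variance, or that cannot
  satisfy the leaf minimum, becomes a leaf; a target fitted exactly stops
  boosting early.
- **Skipped targets.** Constant dummies and targets single-class in the
  training slice are skipped (logged with a reason) and keep an all-zero
  column in $A$, so node indexing is stable across strata.

## Evaluation and the network

One 70/30 split is drawn per stratum and reused for every target, keeping
test AUCs comparable across targets; the split is simple random, not
label-stratified. AUC uses the Mann–Whitney rank form with midrank tie
handling. By default each non-zero column of $A$ is rescaled to sum to 1:
raw gain totals scale with each target's base-rate variance, which would
weight targets arbitrarily; per-target normalization lets every fitted model
contribute equal edge mass (raw mode stays available via
`normalize_columns = FALSE`). Hub scores are computed by power iteration
from the uniform positive vector with max-norm normalization (tolerance
$10^{-12}$ on successive iterates); exactly symmetric networks converge to
the symmetric eigenvector, deterministically.

## Determinism and seeds

All randomness flows from one master seed and the global RNG state is never
touched. Within a run, each stratum's rows are first put in a canonical
content order and the stratum's split seed is derived from the master seed
plus a hash of the stratum's own content. This has three consequences we
consider part of the method's contract: adding, removing or relabelling a
stratum never perturbs any other stratum; permuting the rows of the input
leaves every result identical; and two strata holding identical data produce
identical hub vectors (correlation exactly 1). Seeding by stratum *label*
would break the latter two.

## The synthetic generator

`simulate_survey()` emulates the statistical skeleton of a categorical
survey: `n_confounders` variables drawn uniformly over their levels;
`n_dependent` variables whose level probabilities follow a multinomial logit
shifted by `beta` log-odds per unit of (rescaled) confounder level, with
conditional tables shared across strata; `n_noise` independent variables;
optional uniform missingness. For binary variables the conditional law is
simply $P(X=1 \mid C=c) = \sigma(\beta c)$. The `divergence` knob flips each
dependent variable's effect sign per stratum with the given probability, for
experiments on heterogeneous strata.

The defaults are the package's reference recovery condition, used by the
validation suite and the acceptance script: **3 strata × 2,000 subjects, one
binary confounder, 12 dependent binaries at β = 2, 12 noise binaries, no
missingness**. All variables are binary by default — the structure the
method must detect lives in the dependency pattern, not the level counts —
and level counts are configurable per variable class when multi-level
fixtures are wanted. Under these conditions the planted confounder's dummy
is the top mean-hub in ≥ 9 of 10 seeds, dependent targets reach a median
test AUC above 0.7 while noise targets sit at chance, and cross-stratum hub
correlations exceed 0.9; a β = 0 null shows no persistent top hub and
chance-level AUC. The validation experiments use these sizes because they
are the smallest at which the recovery signal is stable seed over seed.

What the generator does **not** emulate: survey weights, school/cluster
sampling structure, item skip logic, ordinal level ordering, and realistic
marginal distributions. Passing the recovery experiments therefore shows the
machinery identifies broadly influential variables under known conditions;
it does not certify behaviour on any particular real survey.

## Known limitations

- Hub scores are relative within a run (max = 1); only rankings and
  correlations, not absolute values, are comparable across datasets.
- The anti-leakage rule removes *structural* leakage from sibling dummies;
  logically redundant variables (near-duplicates asked twice) will still
  predict each other and can dominate the hub ranking, which is a finding
  about the questionnaire rather than an artifact.
- With very rare levels, a target can be single-class in the training or
  test slice and is skipped; heavily skewed surveys may want a larger
  training fraction or pooled levels.
- Exact split-gain ties are broken towards lower column indices. On data
  with no dependencies at all this can hand the earliest-encoded dummies a
  slight edge in the hub ranking (visible only as a mild preference across
  many null replicates); with any genuine signal present the effect is
  negligible.
- Confounding is operationalized as predictive centrality; no causal claim
  is made or possible from observational survey data.
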