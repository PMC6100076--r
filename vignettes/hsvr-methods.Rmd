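---
title: "Hierarchical SVR for efflux-ratio QSAR: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical SVR for efflux-ratio QSAR: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsvr)
```

## The problem

P-glycoprotein (P-gp) is a promiscuous efflux transporter: it pumps a wide
range of xenobiotics out of cells and across barriers such as the
blood-brain barrier. The quantitative readout of the monolayer assay is the
efflux ratio (ER), the ratio of basolateral-to-apical over
apical-to-basolateral apparent permeability; modeling works on
`log10(ER)`. Because efflux proceeds simultaneously through active
transport and passive permeability, and P-gp itself has several binding
sites, the dependence of log ER on chemical features is strongly
nonlinear: features such as hydrogen-bond donor count or lipophilicity can
both enhance binding and hinder release, giving rise-then-fall
relationships rather than monotone ones. A single global regression tends
to smooth over these regimes; a single local model covers too little of
chemical space.

The hierarchical support vector regression (HSVR) scheme implemented here
addresses this with two levels: a small ensemble of member SVR models, each
an RBF-kernel support vector regression on its own descriptor subset
(playing the role of local models), and a second-level SVR that regresses
the observed response on the member predictions, producing one global
predictor. Member and second-level models are all epsilon- or nu-SVRs
solved by LIBSVM (through `e1071::svm`), with cost `C`, kernel width
`gamma`, and tube parameter scanned by exhaustive grid search under k-fold
cross-validation.

## Pipeline stages and their parameters

`run_pipeline()` chains the stages; every randomized stage derives its own
deterministic substream from the single `seed`, so a run is exactly
reproducible and stages can be re-run in isolation.

**Filtering** (`filter_descriptors`). Descriptors with any missing value
are dropped; "little or no discrimination" is operationalized as fewer
than two distinct values or variance below `1e-8` relative to the column's
mean square. Among any pair with squared Pearson intercorrelation above
`r2_threshold = 0.8`, one is kept: the one more correlated (in absolute
value) with the response when a response is available, otherwise the
earlier column. The threshold follows the conventional
spurious-correlation guard for small QSAR panels; the response-based
survivor rule is this package's choice where convention only says "keep
one", and it makes the filter deterministic and auditable (every removal
is recorded with its r-squared).

**Autoscaling** (`fit_normalization` / `apply_normalization`). Each
descriptor is centered on its mean and divided by its sample standard
deviation (n-1 denominator). The default policy fits these parameters on
the training set only and applies them to the test set, preventing
leakage; `normalize_policy = "all"` fits them on every sample first,
which mirrors the common practice of normalizing the pool before
partitioning. The Kennard-Stone distances (below) are always computed in
the all-sample autoscaled space: the partition is unsupervised, and a
common metric for all candidate points is a property of the design, not
of the model.

**Partitioning** (`kennard_stone_split`). The deterministic max-min
design: the first two training picks are the globally most distant pair;
each further pick maximizes its minimum Euclidean distance to the picked
set. Ties resolve to the lowest row index, making the partition a pure
function of the table. Training size is round-half-up of
`train_fraction * n`, so the conventional 4:1 split of 63 samples gives
50 training and 13 test compounds. A seeded `random_split` is provided as
an alternative for sensitivity checks.

**Subset search** (`ga_subset_search`, `rfe`). The fitness of a candidate
subset is the k-fold cross-validated RMSE of an epsilon-SVR at fixed
mid-grid parameters (`C = 32`, `gamma = 2^-6`, `epsilon = 0.1`). This is a
declared surrogate: the original genetic-function-approximation fitness of
commercial QSAR suites is proprietary, and using the downstream learner's
CV error keeps selection aligned with what the members will optimize. The
GA evolves membership bitmasks with tournament selection (size 2), uniform
crossover, per-bit mutation at rate `1/p`, elitism of one, and random
add/drop repair to the configured size range. Recursive feature
elimination then refits all leave-one-out subsets and discards the
descriptor whose removal least degrades the fitness, yielding a complete
importance ranking.

**Member pool and ensemble growth** (`build_candidate_pool`,
`grow_and_select`). The pipeline deliberately builds *partial* members:
candidate j uses the GA subset minus its j-th most important descriptor
(by the RFE ranking). Each member is therefore a local model missing one
key feature, and their errors are complementary — this is the regime in
which a second-level regression genuinely adds information rather than
merely shadowing its best member. Ensemble growth follows parsimony:
all 2-member combinations are evaluated first, then 3, then up to
`max_members = 4`; the first size class with a combination passing the
validation criteria wins, and within it the passer with the fewest
distinct descriptors. If nothing passes, the best-objective model is
returned carrying an explicit `criteria_met = FALSE` flag.

By default the selection verdict uses training-internal evidence only
(training fit plus cross-validation); `test_guided_selection = TRUE`
additionally consults test-set statistics during selection, reproducing a
widespread but leakage-prone QSAR practice. It is off by default on
purpose.

**Grids.** Full conventional LIBSVM grids (`C` in `2^(-5..15)`, `gamma`
in `2^(-15..3)`, step `2^2`; epsilon in {0.001, 0.01, 0.1, 0.5}; nu in
{0.25, 0.5, 0.75}) are the `grid_spec()` defaults for standalone use.
`run_config()` narrows them (`C` in `2^(-1..7)`, member `gamma` in
`2^(-7..1)`, epsilon in {0.01, 0.1}; a slightly wider gamma range and
epsilon down to 0.001 for the second level, whose inputs are already
near-calibrated predictions) so that a complete desk-scale run on a
200-sample table finishes in seconds. Grid searches rank by k-fold CV
RMSE with `search_folds = 5`; the reported cross-validated coefficient of
the selected model is recomputed at `folds = 10`, the conventional
choice for the headline statistic.

## The validation battery

For observed `y` and predicted `y-hat`, the package computes the
determination coefficient `r2` (training) or `q2` (external), residual
summaries (RMSE with n denominator, MAE, residual standard deviation,
maximum absolute and signed mean residual), through-origin statistics,
the Roy/Ojha modified coefficients, the external qF family, Lin's
concordance correlation (CCC), k-fold `q2cv`, and Y-scrambling.

Numerical conventions that genuinely had to be chosen:

* **Determination coefficient.** The textbook form centers the
  denominator on the observed mean; one circulating variant centers on
  the mean prediction. The package defaults to the observed-mean form —
  consistent with how the external qF2 coefficient is defined — and
  exposes `center_on_predicted = TRUE` for the variant.
* **Through-origin coefficients.** Several conventions circulate. Here
  `k` is the least-squares slope of predicted regressed on observed
  through the origin; `ro2` is the coefficient of determination of the
  points about that line, centered on the mean of the dependent axis;
  `ro2'` swaps the axes. This symmetric definition means exchanging
  observed and predicted exchanges `ro2` and `ro2'`, which is also what
  the test suite asserts.
* **Roy rm2 family.** The standard form is
  `rm2 = r2 * (1 - sqrt(|r2 - ro2|))`; a square-root-free variant also
  appears in print. Both are implemented (`variant = "sqrt"` default,
  `"nosqrt"` optional); the average `(rm2 + rm2')/2` and spread
  `|rm2 - rm2'|` used by the pass criteria are identical arithmetic in
  either case.
* **qF1 centering.** The external error is normalized by the external
  spread about the *observed* training mean (standard); a flag switches
  to the predicted-training-mean gloss.
* **Degenerate denominators** (constant vectors) propagate as `NA`
  sentinels and turn the affected criterion into `not_applicable` —
  never a silent zero and never an exception.

`check_criteria` evaluates the collected stringent battery: all
determination coefficients at least 0.70; `|r2 - q2cv| < 0.10`
(training only); `(r2 - ro2)/r2 < 0.10` with slope `k` in [0.85, 1.15];
`|ro2 - ro2'| < 0.30`; `rm2 >= 0.65`; rm2 average at least 0.65 with
spread below 0.20; CCC at least 0.85 (external only). The verdict table
marks CCC `not_applicable` in the training column and the CV gap
`not_applicable` in the test column.

**Y-scrambling** (`y_scramble`) permutes the response 25 times by
default, refits the member with unchanged descriptors and
hyperparameters, and reports the mean squared correlation of the refit
against the permuted response. A real structure-activity relationship
shows a large gap between `r2` and this chance-correlation level.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws a seven-descriptor menu — total surface area,
molecular volume, polar surface area, hydrogen-bond donor count (integer
0-10), rotatable-bond count, aromatic-ring count (integer 0-6), and
nitrogen+oxygen count — plus two deliberately collinear companions: a
molecular-weight column tracking molecular volume and a
hydrogen-bond-acceptor column tracking the N+O count (target squared
correlation 0.98 each). These mirror the intercorrelation structure that
motivates replacing MW by volume and HBA by the N+O count in efflux
modeling; the filter is expected to remove exactly one of each pair.

The response surface is additive by construction: a Gaussian bump in the
donor count peaking at 6 (rise up to the peak, fall beyond — the
desolvation-penalty story), a Gaussian bump in the aromatic-ring count as
the lipophilicity proxy, and a linear molecular-size term, plus Gaussian
noise (`noise_sd = 0.1` log units by default, against a generated
response spanning roughly 1.5 log units). Defaults are `n_samples = 200`,
chosen as a desk-scale stand-in for a small curated efflux panel: large
enough for stable cross-validation folds, small enough that the entire
20-replicate recovery battery in the test suite runs in minutes. The bump
amplitudes (1.0 and 0.6) and the donor-count distribution (binomial with
mean 4) were fixed once so that both flanks of the donor peak are
populated and the two bumps contribute on the same order as the noise
floor times ten.

What this generator does **not** emulate: real drug-like chemical space
(no fingerprints, no scaffold structure), measurement heterogeneity
across laboratories or cell lines, censored or qualitative efflux calls,
and descriptor distributions of any real compound set. Passing the
recovery battery therefore demonstrates that the machinery — filtering,
partitioning, selection, ensemble assembly, validation — behaves
correctly on data with the assumed statistical structure; it says nothing
about predictive accuracy on experimental efflux panels, which depends on
descriptors this package intentionally does not compute (the upstream
quantum-chemical and cheminformatic descriptor generation is out of
scope; descriptor tables arrive as delimited text).

## Problem sizes used by the shipped checks

The test suite and worked examples run the pipeline at `n = 200`,
`noise_sd = 0.1`, with GA population 16 over 8 generations, 5-fold CV
inside searches, 10-fold CV for the reported coefficient, 25 scrambling
permutations, and 20 seeded replicates for the recovery properties.
These sizes are the package's chosen desk-scale study conditions; all
budgets are `run_config()` fields and scale up freely.

## Known limitations

* The second level regresses on in-sample member predictions, as the
  hierarchical scheme prescribes; a stacked variant on out-of-fold member
  predictions would be less optimistic and is not implemented.
* The GA/RFE fitness is a surrogate for proprietary selection tools;
  selection results will differ from any specific commercial
  implementation.
* `grow_and_select` is exhaustive over member combinations and is meant
  for pools of at most a dozen candidates.
* No applicability-domain quantification beyond the descriptive
  chemical-space diagnostics (`chemical_space_stats`,
  `similarity_check`); no bootstrap confidence intervals.

## A compact worked example

```{r example, eval = FALSE}
library(hsvr)
ds <- generate_dataset(synthetic_spec(seed = 7))
res <- run_pipeline(ds$table, run_config(seed = 7), verbose = TRUE)
print(res)
res$verdict                 # criteria table, training and test columns
ensemble_report(res$model, res$train_table, res$test_table)$test
```
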