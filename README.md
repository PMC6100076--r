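# hsvr — hierarchical support vector regression for efflux-ratio QSAR

P-glycoprotein (P-gp) actively pumps drugs out of cells, and the
monolayer-assay **efflux ratio**
`ER = Papp(B→A) / Papp(A→B)` (modeled as `log10 ER`) quantifies how
strongly. Because efflux mixes active transport with passive
permeability, log ER depends on chemical descriptors nonlinearly —
hydrogen-bond donor count and lipophilicity both help and hurt, giving
rise-then-fall relationships. `hsvr` implements a two-level quantitative
structure–activity relationship (QSAR) scheme for this setting:

* **member SVRs** — ε- or ν-support-vector regressions with RBF kernels
  (LIBSVM via `e1071`), each on its own descriptor subset, acting as
  local models;
* a **second-level SVR** that regresses the observed response on the
  member predictions, yielding one global predictor (the HSVR model).

Around that core the package provides the full supporting pipeline:
descriptor filtering (missing values, low variance, pairwise
intercorrelation r² > 0.8), autoscaling `χ = (x − ⟨x⟩)/s`,
deterministic Kennard–Stone max–min train/test partitioning (a 4:1 split
of 63 samples gives 50/13), genetic-algorithm + recursive-feature-
elimination subset selection, exhaustive log-grid hyperparameter search
under k-fold cross-validation, and the complete external-validation
battery: r²/q², RMSE, MAE, residual statistics, through-origin r²o/r′²o
and slope k, the Roy rm² family, q²F1/q²F2/q²F3, Lin's concordance
correlation (CCC), Y-scrambling ⟨r²s⟩, and the collected stringent
pass/fail criteria (all coefficients ≥ 0.70, |r² − q²cv| < 0.10,
(r² − r²o)/r² < 0.10 with 0.85 ≤ k ≤ 1.15, |r²o − r′²o| < 0.30,
rm² ≥ 0.65, ⟨rm²⟩ ≥ 0.65 with Δrm² < 0.20, CCC ≥ 0.85).

A seeded synthetic generator (`generate_dataset`) emulates the
descriptor menu, its collinearity structure (an MW-like column tracking
molecular volume at r² ≈ 0.98, an HBA-like column tracking the N+O
count) and the inverted-U response dependencies, so every stage is
testable without external data. Real descriptor tables (e.g. from
quantum-chemical or cheminformatic pipelines) are consumed as delimited
text; descriptor computation itself is out of scope.

## Worked example

```r
library(hsvr)
ds  <- generate_dataset(synthetic_spec(seed = 7))   # 200 pseudo-molecules
res <- run_pipeline(ds$table, run_config(seed = 7), verbose = TRUE)
#> [hsvr] filter: 9 -> 7 descriptors
#> [hsvr] split (kennard_stone): 160 train / 40 test
#> [hsvr] ga: chose 3 descriptors (fitness 0.1479)
#> [hsvr] pool: 3 candidate subsets (sizes 2,2,2)
#> [hsvr] ensemble: 2 members, criteria met
#> [hsvr] y-scramble: <rs2> = 0.032 over 25 permutations
print(res)
#> pipeline_result
#>   train/test: 160/40
#>   members: 2 (2, 2 descriptors)
#>   training r2 = 0.921, q2cv = 0.915
#>   test q2 = 0.911, CCC = 0.952
#>   criteria: pass
```

Reading: the intercorrelation filter removed the two collinear companion
columns (9 → 7 descriptors); the Kennard–Stone design assigned 160/40
samples (4:1); the GA found the three generative descriptors, and the
selected ensemble pairs two deliberately partial members whose
second-level combination reaches held-out q² = 0.91 while Y-scrambling
stays near zero (⟨r²s⟩ = 0.03), the expected chance-correlation gap.
`res$verdict` prints the criteria table with pass/fail/N-A per context,
`ensemble_report(res$model, res$train_table, res$test_table)` the
member-vs-HSVR statistics tables.

A command-line front end over the same functions ships in
`inst/cli/hsvr.R`:

```sh
Rscript inst/cli/hsvr.R simulate --n 200 --seed 7 --out work
Rscript inst/cli/hsvr.R report --input work/descriptors.csv --seed 7 --out work
```

(subcommands: `simulate`, `filter`, `split`, `select`, `train`,
`validate`, `predict`, `report`).

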