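# placperm

Modeling and screening of human **placental permeability** for small
molecules — sunscreen ingredients, their environmental degradation
products, drugs, and other xenobiotics — on the **log FM** scale, the
base-10 logarithm of the fetal-to-maternal blood concentration ratio at
equilibrium. A compound with FM ≥ 0.3 is classified as crossing the
placenta (class C, score PL1); below that cutoff it is NC / PL0.

The package is aimed at computational chemists and toxicologists who
have per-compound molecular descriptor tables (SwissADME/Mordred-style:
`M_w`, `TPSA`, `iLOGP`, `Lipinski`, autocorrelation indices, …) and want
to (a) apply published fixed-coefficient permeability models, (b)
rebuild such models from their own data with the same machinery, or (c)
screen compound libraries for drug-likeness and placental transfer.

## What is inside

* **Model bank** — nine published linear models of log FM with their
  printed coefficients, e.g. the two-descriptor MLR
  `log FM = 0.14 − 0.0022·M_w + 0.0040·TPSA`, ARKA models on supervised
  aggregate descriptors (`ARKA1`, `ARKA2`) and q-RASAR PLS models mixing
  conventional descriptors with Read-Across features (`RA_function`,
  `MaxPos`, `gm`). `get_model("eq1")` … `get_model("eq9")`,
  `predict_log_fm()`, `classify_permeability()`.
* **Model-building machinery** — OLS (`fit_ols`), forward stepwise
  selection by partial-F p-values (`forward_stepwise`), NIPALS PLS with
  auto-scaling (`pls_fit`), iterative VIP-based variable reduction
  (`vip_reduce`, VIP < 1 rejected and the fit repeated), and exhaustive
  best-subset search ranked by leave-one-out Q² (`best_subset`).
* **Validation metrics** — R², adjusted R², F, Q²_LOO, 8-fold RMSECV,
  and the external statistics Q²_F1, Q²_F2, RMSEP, R²_ext
  (`validation_report`), plus the analytic forms `f_from_r2()` /
  `r2_adj_from_r2()` for checking printed statistic blocks.
* **ARKA** — min-max scaling, response-median grouping of descriptors,
  the two group-mean descriptors, and the confidence-quadrant analysis
  of the ARKA2-vs-ARKA1 plane (`arka_pipeline`).
* **Read-Across / q-RASAR** — Euclidean/Gaussian/Laplacian kernel
  similarity, weighted-mean Read-Across prediction (`ra_predict`),
  seeded grid-search hyperparameter optimization
  (`optimize_hyperparameters`), RASAR descriptor computation
  (`compute_rasar_descriptors`) and the full q-RASAR assembly with
  leave-self-out training features, pool fusion, best-subset selection
  and a final 2-LV PLS (`build_qrasar`).
* **Drug-likeness** — Lipinski (Mordred and SwissADME variants), Veber,
  Ghose (two variants), Palm, Egan and Muegge filters with printed
  thresholds (`evaluate_filters`), and hierarchical clustering of binary
  filter profiles against PL1/PL0 calls (`cluster_filter_profiles`).
* **Synthetic data** — a seeded generator whose defaults emulate the
  reference compounds' property envelope (`generate_dataset`,
  `generate_reference_like`), so the whole pipeline is testable without
  any external data.
* **Screening pipeline** — `run_screening()` orchestrates predictions,
  classification, filters and PL1-vs-PL0 group comparisons from one
  config object; a CLI lives at `inst/cli/placperm.R`.

## Worked example

Rebuild a two-descriptor permeability model on a synthetic reference-like
dataset (54 compounds, 40 train / 14 test, truth with a negative `M_w`
and positive `TPSA` effect, noise sd 0.2):

```r
library(placperm)

ds <- generate_reference_like(seed = 7)
X <- train_matrix(ds)[, c("M_w", "TPSA")]
y <- train_response(ds)

fit <- fit_ols(X, y)
fit$model
#> <ols> [MLR] log_FM = -0.0731275 -0.00200126*M_w +0.00466446*TPSA
fit$report
#> validation_report
#>   training (n=40, p=2): R2=0.835 R2_adj=0.826 F=93.477
#>   internal: Q2_LOO=0.803 RMSECV=0.191
```

The refit recovers the generating structure: the size coefficient is
negative (heavier molecules cross less readily), the polarity
coefficient positive, and Q²_LOO close to R² indicates a stable model.
Continue to a q-RASAR model — optimize the Read-Across kernel, fuse
RASAR features with the QSAR descriptors, select the best subset by
Q²_LOO and fit a 2-latent-variable PLS:

```r
opt <- optimize_hyperparameters(
  X, y, default_ra_grid(sigmas = c(0.5, 1, 2), gammas = c(0.5, 1, 2),
                        n_close = c(3, 5)), seed = 7)
opt$best_config
#> ra_config: gaussian kernel sigma=1 n_close=5

qr <- build_qrasar(ds, c("M_w", "TPSA", "iLOGP", "MLOGP"),
                   opt$best_config, max_size = 3)
qr$selected
#> [1] "M_w"   "TPSA"  "SDSim"
qr$report
#> validation_report
#>   training (n=40, p=2): R2=0.848 R2_adj=0.840 F=103.469
#>   internal: Q2_LOO=0.812 RMSECV=0.191
#>   external (n=14): Q2_F1=0.730 Q2_F2=0.715 RMSEP=0.235 R2_ext=0.786
```

The fused model keeps the two true descriptors, adds one
similarity-derived feature, and predicts the held-out test compounds
well (Q²_F1 = 0.73). Finally, apply a fixed bank model and classify:

```r
pred <- predict_log_fm(get_model("eq1"), ds$table[1:3, ])
classify_permeability(pred)
#>          log_fm        fm crossing_class pl_score
#> C001 -0.5556803 0.2781760             NC      PL0
#> C002  0.5095529 3.2326067              C      PL1
#> C003 -0.3383830 0.4587933              C      PL1
```

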