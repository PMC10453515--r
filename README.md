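# nestout

Outlier-activity detection for human-activity-recognition (HAR) sensor
streams by **nested binary elimination**.

Activity recognizers are trained on a closed set of activities
A = {a₁, …, a_k} — sitting, walking, stair climbing — but real streams
contain bouts of activities the model was never taught. A conventional
multiclass classifier absorbs those bouts into some known class. `nestout`
instead runs one binary one-vs-rest classifier per known activity, in
sequence: at level *i* the classifier for aᵢ is fitted on the training pool
(relabeled C₁ = 1 for aᵢ, C₀ = 0 otherwise) and applied to the surviving
test pool; windows predicted positive take the final label aᵢ and leave the
pool, and aᵢ's training windows retire from later levels. Whatever survives
all *k* levels is reported as the **outlier set** — segments recognized by
elimination rather than by a trained outlier class.

The package covers the full pipeline:

* **Synthetic streams** — a seeded tri-axial signal generator
  (baseline + sinusoid + Gaussian noise per axis) with scheduled activities
  and injected outlier bouts, so everything is testable without downloads.
* **Readers** — raw phone-accelerometer CSV (`user,activity,timestamp,x,y,z;`)
  with the cleaning rules for blank/malformed/duplicate rows, and processed
  fixed-width feature tables with numeric-to-text label mapping.
* **Windowing** — fixed-size overlapping windows (presets: 40 @ 50%,
  144 @ 80%, 128 @ 50%), majority labels with deterministic tie-breaks.
* **Features** — ten statistics per acceleration axis (mean, median, max,
  min, std, energy, IQR, entropy, cross-axis correlation, simple moving
  average); 3 base channels → 33 features, 12 → 42.
* **The cascade** — base classifiers knn(7), CART, SVM, Gaussian NB,
  logistic regression (500 iter), plus a test-only oracle.
* **Evaluation** — ACC/PP/SE/SP from TP/FP/TN/FN (zero denominators → 0),
  multiclass one-vs-rest reductions, and detected/over-detected outlier
  accounting.
* **Baseline** — a 6×100 rectifier feed-forward network (batch 40, early
  stopping with patience 2) trained with the outlier class labeled.

## Worked example

```r
library(nestout)

res <- run_experiment(experiment_config(base = "knn", seed = 1))
glance(res$fit)
#>   n_levels n_test n_assigned n_outliers base   seed
#> 1        4    144        138          6 knn     151
res$report
#>   n_true_outliers n_detected n_overdetected detection_pct pct_undefined
#> 1               5          5              1           100 FALSE
writeLines(render_level_table(res$fit))
#> Level  Activity        Accuracy  Precision  Sensitivity  Specificity
#> I      walking            98.61     100.00        94.44       100.00
#> II     sitting            98.18      94.59       100.00        97.33
#> III    going_up           98.63      97.14       100.00        97.44
#> IV     going_down        100.00     100.00       100.00       100.00
```

The run simulates a 480 s stream of four known activities at 20 Hz, injects
four 4 s bouts of an unknown fifth activity ("running"), windows and
enriches it (479 windows × 33 features), splits 70/30, and runs the knn(7)
cascade. Of 144 test windows, 138 are assigned across the four levels; the
6 residual windows are the outlier set, containing all 5 true outlier
windows (detection 100%) and 1 over-detected known window — the
counterbalancing "negative statistic". `tidy(res$fit)` returns the
per-level confusion counts and measures; `autoplot(res$fit)` shows the
records removed per level, and `run_mlp = TRUE` adds the feed-forward
comparator with `tidy()`/`autoplot()` learning curves.

A thin CLI over the same functions lives at `inst/cli/nestout.R`
(`simulate`, `run`, `mlp` subcommands).

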