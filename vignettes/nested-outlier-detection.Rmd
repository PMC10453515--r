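---
title: "Detecting outlier activities by nested binary elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting outlier activities by nested binary elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestout)
library(dplyr)
```

## The problem

Wearable-sensor activity recognition systems are trained on a closed set of
activities $A = \{a_1, \dots, a_k\}$ — sitting, walking, stair climbing and
the like — but deployed streams inevitably contain bouts of activities the
model was never taught: a jump on a rough road in the middle of a run, a
stumble, an unscheduled exercise. A conventional multiclass classifier must
place every window into some known class, silently absorbing these *outlier
activities*. `nestout` implements a nested binary elimination cascade that
detects them instead.

## The nested cascade

One level of the cascade is dedicated to each known activity, visited in a
random order by default (results are order-dependent, so an explicit order
can be supplied). At level $i$:

1. the current training pool is relabeled one-vs-rest: $C_1 = 1$ for
   windows of activity $a_i$, $C_0 = 0$ for everything else;
2. a binary base classifier is fitted and applied to the surviving test
   pool;
3. test windows predicted positive receive the final label $a_i$ and leave
   the pool — for the test set this is necessarily *prediction-driven*,
   since test labels are treated as unknown;
4. training windows whose true label is $a_i$ leave the training pool and
   no longer participate in later levels.

Windows that survive all $k$ levels form the residual outlier set. The
partition invariant — every test window is either assigned at exactly one
level or ends in the outlier set — holds for any base classifier, order and
seed, and is enforced by property tests.

A consequence worth spelling out: training windows whose label is *outside*
$A$ are never the positive class at any level, so they act as permanent
negative background. This mirrors how unknown-activity segments behave when
a recorded stream is split randomly into training and test portions — the
anomalous bouts land on both sides of the split, but the cascade is never
told to recognize them. It also matters numerically: the last level would
otherwise train on a single class (all earlier activities having been
removed) and could not reject anything. When a degenerate single-class pool
does occur, the level predicts that class for every record, which is stated
behavior rather than an error.

Base classifiers are the field's standard quintet, with the published
settings: $k$-nearest neighbors ($k = 7$), CART with unconstrained depth
(complexity pruning disabled, depth cap at the implementation maximum of
30), an RBF support-vector machine with library defaults, Gaussian naive
Bayes, and logistic regression capped at 500 IRLS iterations. Features are
standardized with the current training pool's mean and standard deviation
before the scale-sensitive bases (knn, svm, lr). An `oracle` base — predict
positive exactly when the true label equals the level's activity — exists
purely to test the elimination logic independently of learning quality.

## Windows and features

Streams are compressed into fixed-size overlapping windows; a window of $w$
samples advances by $\mathrm{step} = \max(1, \mathrm{round}(w(1-p)))$ for
overlap fraction $p$. The three published presets are `inertia` (40
samples, 50%), `wisdm` (144 samples, 80% — the raw step 28.8 is rounded to
29, the nearest integer to the stated overlap) and `uci` (128 samples, 50%,
i.e. 2.56 s at 50 Hz). Trailing samples that do not fill a window are
discarded. Each window takes the majority of its per-sample labels, ties
broken by the earliest-occurring label — deterministic and seed-free.
Windows spanning an activity boundary are kept and majority-labeled; they
are exactly the ambiguous segments outlier detection is meant to handle.

Each window is enriched with ten statistics per acceleration axis: mean,
median, largest and smallest observation, standard deviation, energy,
interquartile range, entropy, correlation with the partner axis, and simple
moving average. Four of these admit more than one reasonable definition,
and the choices here are:

* **energy** — mean of squared samples $\frac{1}{w}\sum x_j^2$, the common
  convention for inertial windows;
* **entropy** — Shannon entropy in bits of the 10-bin histogram of the
  samples over their own range (a constant window scores 0); a spectral
  definition was the alternative, and the histogram was chosen for
  determinism without FFT conventions;
* **correlation** — Pearson $r$ against the partner axis in the cyclic
  order $x\!\to\!y$, $y\!\to\!z$, $z\!\to\!x$, defined as 0 when either
  axis is constant;
* **simple moving average** — the mean of the trailing 5-sample
  moving-average series, reducing the named series feature to one scalar.

The standard deviation is the population form (divisor $w$), and quartiles
use linear interpolation. Base channels are represented by their per-window
mean, so the feature dimension is $n_\text{channels} + 10 \times 3$:
33 features from 3 channels, 42 from 12, matching the published counts.
This also means the acceleration-axis mean appears twice (once as a base
mean, once as a statistic) — accepted to preserve those counts. Statistics
are computed only on the first three channels, which the arithmetic of the
printed counts forces.

## The synthetic generator

Real benchmark streams are large external downloads, so the package ships a
generator that emulates their structure: each activity is a per-axis signal
model `baseline + amplitude * sin(2πft + phase) + N(0, noise_sd)`, played
out over a schedule at a uniform sampling interval. Axis phases are fixed
at $0, \pi/3, 2\pi/3$ so dynamic activities induce non-trivial cross-axis
correlation. Outlier bouts are *injected* by replacing (not inserting)
seeded-random non-overlapping spans, which keeps the stream uniformly
sampled — the "activities within other activities" scenario.

The default study conditions: four known activities (sitting, walking,
going up, going down) with baseline gaps large relative to noise
(noise 0.05–0.5 m/s², amplitude gaps of several m/s²), a 480 s stream at
20 Hz, four injected 4 s bouts of a fifth activity (running, with larger
amplitude and frequency than any known class), 40-sample windows at 50%
overlap, and a seeded 70/30 train/test split. These are deliberately
idealized: sinusoid-plus-noise signals have none of the inter-subject
variability, sensor drift, or orientation changes of real recordings, so a
clean pass here demonstrates the *mechanics* of the cascade — segmentation,
enrichment, elimination, accounting — not field performance.

## Evaluation

Binary quality is reported as accuracy, precision, sensitivity and
specificity from TP/FP/TN/FN counts; any measure with a zero denominator is
reported as 0 by convention. Multiclass results reduce to per-class
one-vs-rest counts. Outlier accounting follows the detected/over-detected
scheme: the number of true outliers found, and — as the counterbalancing
negative statistic — the number of known-activity windows wrongly flagged.
When a run contains no true outliers the detection percentage is undefined
and reported as 0 with an explicit flag. Rendered tables print percentages
with two decimals, halves rounded away from zero.

## The feed-forward comparator

The multiclass baseline is a rectangular feed-forward network: six hidden
layers of 100 rectifier units, minibatches of 40, at most 100 epochs,
early-stopped when validation loss fails to improve for two consecutive
epochs (the validation split is a seeded 10% of training). Unlike the
cascade, it requires *labeled* outlier examples at training time — the
outlier windows keep their own label and become an explicit class. This is
a genuine semantic difference between the two methods, documented rather
than reconciled. Categorical cross-entropy loss and the Adam optimizer at
its default rate are implementation choices; the published description
fixes only the architecture, epoch budget, batch size and patience. The
network is written in plain matrix arithmetic, which is entirely adequate
at these problem sizes (tens of features, hundreds of windows).

```{r mlp-demo, eval = FALSE}
res <- run_experiment(experiment_config(base = "knn", run_mlp = TRUE,
                                        seed = 1))
tidy(res$mlp)      # per-epoch loss/accuracy curves
autoplot(res$mlp)  # learning-curve plot
```

## Numerical choices and edge cases

* Window step: non-integer raw steps round to the nearest integer, with a
  floor of 1.
* Train/test sizes: `round(fraction * n)` with halves away from zero.
* knn uses $k = \min(7, n_\text{pool})$; its vote ties are impossible at
  odd $k$.
* Logistic regression predictions threshold the response at 0.5;
  separation warnings are suppressed (the fit is still usable for
  thresholded prediction).
* A level whose classifier assigns nothing is legal; an activity with no
  remaining training positives at its level is an error naming the level.
* Standardization guards zero-variance columns by leaving them unscaled.
* Raw CSV cleaning is never fatal: blank rows, rows that do not split into
  exactly six fields (which covers duplicated columns and stray
  separators), and rows with non-numeric measurements are dropped and
  counted; duplicates are exact matches of the whole normalized line, the
  most conservative key.

## Problem sizes in the test suite

The property suites run at deliberately small scales chosen to exercise the
invariants densely: oracle-equivalence over 200 random datasets of up to
1000 test records, the partition invariant over 100 random instances
cycling all six bases, the window-count law over every window size up to 64
and four overlap fractions against a brute-force enumerator, and the
statistic definitions against longhand recomputation on 200 random
windows. The end-to-end recovery check runs the full synthetic pipeline
with the knn base over five seeds and asks for ≥95% median detection with
≤5% over-detection — comfortably met under the default conditions because
test-set outlier windows lie nearest to their training-side counterparts,
which are negative at every level.

## Limitations

The generator's sinusoidal model cannot probe robustness to inter-subject
variation, gravity reorientation, or sensor noise structure; conclusions
about real deployments require the external benchmark datasets, for which
only readers and cleaning rules are provided here. The cascade's outcome
depends on the activity order; the default randomizes it, and medians over
seeds are the recommended summary. No probability calibration or
cost-sensitive thresholding is attempted, and the majority-vote
stabilization sometimes mentioned alongside cascade methods is out of
scope.
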