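---
title: "Modelling winter wheat yield from weekly weather: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling winter wheat yield from weekly weather: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`yieldcnn` predicts county-level winter wheat yield (t ha^-1^) from three
blocks of inputs per county-year: six weekly weather series over a
45-week growing season (wind speed, minimum and maximum temperature,
relative humidity, precipitation, solar radiation), four static soil
water-retention properties (LL, DUL, SAT in cm^3^ cm^-3^ and bulk density
BD in g cm^-3^), and three phenology dates (sowing, flowering, harvest
day-of-year). At the default 45 weeks this is the fixed 277-column feature
table (6 x 45 weather columns named `<Variable>_<week>`, then the seven
static columns).

Around that table the package provides: a year-wise (non-random) hold-out
protocol, a multi-branch 1-D convolutional network, eight classical
baseline learners with a cross-validated search protocol, evaluation
metrics, Kernel SHAP interpretation, a Shapley-ranked feature-selection
ablation, and a synthetic panel generator that stands in for the licensed
national data the original modelling tradition uses.

# The temporal protocol

All training years strictly precede the test year: a model evaluated on
year $T$ is fitted on years $<T$ only. Standardisation is fitted on those
training rows only and applied unchanged to the test year — the underlying
study does not state this detail, and we chose the leakage-free variant.
Standardisation is the plain z-score

$$x^{(j)}_{scaled} = \frac{x^{(j)} - \mu^{(j)}}{\sigma^{(j)}}$$

with the *population* standard deviation (divisor $n$), matching the
z-score definition as usually printed; `fit_normalizer(sd_type =
"sample")` switches to the $n-1$ convention. Columns with $\sigma = 0$ map
to 0 with a warning instead of erroring, so constant synthetic columns
cannot kill a run. Test-year columns standardised with training parameters
retain their year shift — that is the point of the protocol.

# The CNN

Each of the six weather series passes through the same stack of 1-D valid
convolutions (ReLU), then one average-pooling layer; the six branch
outputs are flattened and concatenated with a two-layer fully-connected
embedding of the seven static features, and a head of exactly three
fully-connected ReLU layers plus a linear unit produces the scalar yield.
"The same model applied to each series" is read as *shared* branch weights
(the branch parameter count is then independent of the number of weather
variables); a per-variable-weights mode exists because the phrase is
genuinely ambiguous.

Defaults: two conv layers of 8 filters (kernel 3, stride 1), pool width 2,
static branch (16, 16), head (64, 32, 16). An earlier draft used 16
filters per layer; 8 was adopted because the package must train ~40
networks inside a 25-minute single-CPU test budget, and at these panel
sizes the halved width costs no measurable test accuracy. Everything is a
`cnn_arch_config()` field.

Training (`train_config()`): mean squared error, Adam, learning rate
1e-3, 100 epochs, batch 64 by default; the acceptance suite uses the
faster desk-scale setting stated in the test file (up to 60 epochs, batch
256, lr 3e-3, early stopping on the last pre-test year). A *decoupled*
weight decay (AdamW-style, weights only, default 1e-3) is on by default:
county-year panels have an irreducible county-level noise floor, and an
unregularised network of this size memorises it — visible as training
RMSE falling far below the generative noise floor while test RMSE
worsens. Early stopping (restore the weights of the epoch with the best
validation loss, using an explicit validation year or a held-out
fraction) is available but off by default. A fixed seed reproduces
initialisation, shuffling and hence the loss history bit-for-bit. One
practical note: on panels of only a few hundred rows the CNN reliably
*loses* to the Lasso — the convolutional advantage needs the full
multi-thousand-row panel to materialise, which is why the package's
comparative claims are all made at default panel scale.

The conv branches run through compiled code on the prediction path and in
the minibatch loop (the training-path R implementation is retained and the
two are tested for equality to machine precision; gradients are verified
against central finite differences).

# Baselines

Eight comparison learners share one `fit_model()`/`predict()` contract:
KNN (Euclidean distance, prediction = mean of the k nearest training
yields), random forest, gradient-boosted trees (the "xgboost" slot), Lasso
and Ridge (glmnet), a regression tree, linear epsilon-insensitive SVR, and
a feedforward DNN. The target environment ships no tree/forest/boosting or
SVM packages, so those learners are implemented in-package: the tree is an
exhaustive SSE-minimising CART (the split minimises the summed within-child
squared deviation from the child means; growth stops at a minimum leaf
size, a depth cap, or a pure node), the forest bags those trees with
per-split feature subsampling, boosting fits trees to residuals with
shrinkage, and the SVR minimises the linear primal
$\tfrac12\lVert w\rVert^2 + C\sum_i \max(0, |y_i - f(x_i)| - \epsilon)$
by full-batch Adam on the subgradient. No kernelised SVR is provided: the
printed objective is the linear primal and the supplement with the chosen
kernels is not part of the available text.

Hyperparameter search (`tune_hyperparameters()`): grid or randomized
candidates, seeded random fold assignment, k = 3 folds, candidate scored by
mean out-of-fold RMSE, full trial log retained. The field-scale protocol
used 1000 iterations; the package default is 50 (and the harness test uses
10) — the protocol, not the candidate values, is the reproducible content,
and the supplement listing the original search spaces is not available, so
`default_search_space()` uses common-practice ranges.

# Evaluation

`compute_metrics()` reports MAE, RMSE, and the correlation metric as the
tradition prints it:

$$r = \sqrt{1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2}}$$

This is the square root of the coefficient of determination, *not* the
Pearson correlation; Pearson is reported alongside under its own name.
Two degenerate cases return a flagged `NA` rather than an exception or a
complex number: constant actuals (SST = 0) and a model worse than the mean
(negative radicand). Per-county percentage error is
$|A_i - P_i|/|A_i| \times 100$, with zero actuals flagged `NA` rather than
infinite. Residual normality uses Shapiro-Wilk (`stats`) and an in-package
Anderson-Darling test (composite case, small-sample correction, the
Stephens/D'Agostino p-value approximation) because no normality add-on
package is available; both are validated by Monte-Carlo size and power
checks in the test suite.

# Kernel SHAP

`shap_values()` is a model-agnostic Kernel SHAP estimator: coalition
$z \in \{0,1\}^M$ is evaluated as the background-averaged prediction with
masked features drawn from the background sample, weighted by the Shapley
kernel $\pi(z) = (M-1) / [\binom{M}{|z|} |z| (M-|z|)]$, and the
attributions solve the weighted least squares with the local-accuracy
constraint imposed exactly by eliminating one coefficient — so
$\text{base} + \sum_j \phi_j = f(x)$ holds to machine precision at any
sampling budget. Feature spaces small enough to enumerate are enumerated
exactly; otherwise complete coalition-size groups are enumerated from the
outside in (sizes 1 and $M-1$ first) and the remaining budget is drawn by
*paired* sampling (each sampled coalition enters together with its
complement), which materially reduces estimator variance. A small ridge
(1e-6) stabilises the solve.

Global importance is the column mean of $|\phi|$; the sign is the sign of
the Pearson correlation between feature values and contributions (the
red/blue direction of the usual importance bars); ranks are a permutation
of 1..277 with ties broken by column order. Force-plot data selects the
instances with minimum, median and maximum actual yield; the median of an
even-sized set is defined as the *lower* of the two middle yields. The
weekly weather profile aggregates mean $|\phi|$ by (variable, week) and
normalises the six per-variable totals to sum to 100 — i.e. percent of
total weather importance, our reading of "normalized Shapley values",
configurable by post-processing the returned grid.

Documented field-scale budgets (background 100, explained 200, ~2x
features coalitions) are API defaults; the acceptance tests state and use
smaller seeded sets, which changes estimator variance but not the local
accuracy property.

`ablation_retrain()` re-fits a model on the full feature set, the top
$\lceil 0.75 p \rceil = 208$ and $\lceil 0.50 p \rceil = 139$ features by
Shapley rank (ceiling rule; the source is silent on rounding), and the 270
weather columns alone. For the CNN the excluded columns are masked to 0 —
the training mean after z-scoring — because the conv branches need the
full weekly grid; tabular models drop columns outright.

# The synthetic world

The generator emulates the *structure* of the licensed panel: 271 counties
x 21 years (1999-2019) = 5691 rows by default (the original instance count
of 5692 differs by one from the county x year product; the generator
follows the product), 45 season-relative weeks per weather variable
(week 1 = first week after sowing — the source mixes season-relative and
calendar weeks, and one origin was fixed for consistent feature naming),
soil sampled once per county and constant across years (soil maps are
static), phenology jittered per county-year.

Weekly weather is seasonal cosine mean + county effect + year anomaly +
AR(1) weekly noise, truncated where physically necessary (non-negative
precipitation/wind/radiation, humidity in [0, 100]). The yield response is
documented and queryable (`truth_features()`):

* linear window terms — mean wind weeks 9-11 (-0.60 t ha^-1^ per m s^-1^),
  mean maximum temperature weeks 7-9 (+0.24 per deg C), mean radiation
  weeks 6-8 (-0.24 per MJ m^-2^ d^-1^);
* deficit hinges — weekly-mean minimum temperature below 0 deg C over
  weeks 20-23 (frost, 1.0 per deg C of deficit) and precipitation below
  14 mm week^-1^ over weeks 30-33 (drought, 0.30 per mm of deficit);
* a soil hinge — DUL below 0.27 cm^3^ cm^-3^ costs 14 t ha^-1^ per
  cm^3^ cm^-3^ of deficit, the breakpoint mirroring the field-capacity
  threshold the interpretability analyses highlight;
* county effect (SD 0.20), technology trend (+0.02 t ha^-1^ yr^-1^) and
  Gaussian noise (SD 0.20).

Defaults were chosen with two goals in tension: plausibility (mean yield
~6.5 t ha^-1^, SD ~1, matching German county statistics to first order)
and two properties the generator is explicitly required to have — the
ground-truth driver set must be *recoverable* by the interpretation stack,
and the nonlinear part of the response must stand clearly above the
panel's noise floor (otherwise a linear model is near-optimal and the
nonlinear-versus-linear comparison the package exists to exercise is
vacuous). Those two requirements were calibrated deliberately:
recoverability dictated moderate temporal correlation (AR(1) coefficient
0.25-0.30) and modest county/year weather anomalies, because with strongly
correlated weeks a convolutional model can proxy a driver week by its
neighbours and Shapley attribution spreads accordingly — a property of
attribution under collinearity, not a bug; the signal-above-floor
requirement dictated hinge effect magnitudes (frost, drought, DUL) of a
few tenths of a t ha^-1^ against a 0.28 t ha^-1^ irreducible floor. Real
weather is more correlated and real yields noisier than this default; a
green driver-recovery or model-ordering test therefore establishes that
the stack behaves correctly in a world where the assumed signal exists,
not that such signal exists in any particular real dataset.

What a green run does **not** establish: performance on real gridded
weather (spatial interpolation, land-use weighting and soil-map processing
are out of scope), behaviour under missing data (the generator emits
complete rows; assembly rejects incomplete ones by design), or the numeric
values of the original study's tables, which require the licensed dataset.

# Numerical choices and degenerate inputs

* Weekly aggregation: week k = mean of days 7(k-1)+1..7k; a trailing
  partial week of >= 1 day is averaged over its actual length (365 days ->
  52 weeks, the last over 8 days). The "365:52" reduction is silent about
  the remainder; discarding data was the alternative and was rejected.
* Constant columns: sigma = 0 maps to 0 (warned), inversion restores the
  mean.
* Eq-6 r: flagged `NA` on SST = 0 or SSE > SST; never complex.
* Percentage error at A = 0: flagged `NA`, not infinity.
* Median instance of an even set: lower-middle by yield.
* Fraction-to-count rounding in ablations: ceiling.
* Non-finite training loss aborts with a diagnostic rather than returning
  a silently broken model.
* All derived seeds stay below 2^31; every stochastic stage consumes the
  master seed through fixed offsets.

# Known limitations

* The SVR is linear; the tree-ensemble "xgboost" slot is a plain
  gradient-boosted CART without the regularised second-order objective of
  the eponymous library.
* Kernel SHAP at 277 features is an estimate; ranks of features with
  near-identical importance can swap between budgets. Local accuracy is
  exact by construction, global ranks are not.
* The CNN ablation masks rather than removes features; a model retrained
  on a truly narrower input layer could differ.
* The adapter for externally supplied panels (`read_panel()`) validates
  schema, not science: units and week alignment are the caller's
  responsibility, and it is untested against any licensed dataset.
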