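---
title: "Representative undersampling and Weibull oversampling: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representative undersampling and Weibull oversampling: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdp)
```

## The problem

Binary classifiers trained on strongly imbalanced tables — a handful of
positive (minority) cases against a large negative (majority) background, the
typical shape of clinical screening and epidemiological data — tend to
collapse onto the majority: overall accuracy looks fine while sensitivity is
near zero. `ppdp` rebalances the *training* data before any classifier sees
it, combining

1. **representative undersampling** of the majority: delete gross outliers by
   the box-whisker inner-fence rule, then keep only rows inside a fuzzy
   "representative core" estimated per feature by Mega-Trend-Diffusion (MTD);
2. **distribution-aware oversampling** of the minority: fit a two-parameter
   Weibull per feature and synthesise new minority rows by inverting the
   fitted CDF at median-rank plotting positions,

until both classes have the same training count.

## Stage 1: inner fences

For each majority feature we compute quartiles and flag values outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$. Quartiles follow the
Tukey-hinge convention (median of each half, halves including the overall
median at odd sizes) — the convention of the original box plot, and the one
all worked examples in the test suite use. An interpolation-based alternative
(`convention = "interpolation"`, type-7 quantiles) is available because
software traditions differ and the flagged counts can shift slightly at small
n. A row is deleted when *any* of its features is flagged (the union rule);
only row-level deletion yields a single removal count $S_{box}$.

## Stage 2: Mega-Trend-Diffusion and the α-cut

MTD estimates, per feature of the *cleaned* majority, a plausible domain
$[a, b]$ around the data. With $u_{set} = (\min + \max)/2$, $N_L$ and $N_U$
the counts strictly below and above $u_{set}$ (ties count in neither — they
sit exactly at the peak), skewness weights $S_L = N_L/(N_L+N_U)$,
$S_U = N_U/(N_L+N_U)$ and sample variance $s_x^2$:

$$a = u_{set} - S_L\sqrt{-2\,(s_x^2/N_L)\ln 10^{-20}}, \qquad
  b = u_{set} + S_U\sqrt{-2\,(s_x^2/N_U)\ln 10^{-20}},$$

with fallbacks $a = \min/5$ when $N_L = 0$ and $b = 5\max$ when $N_U = 0$
(hence constant features hit both). Membership is triangular — 1 at
$u_{set}$, 0 at $a$ and $b$ — and the α-cut
$A_\alpha = [(u_{set}-a)\alpha + a,\; b - (b-u_{set})\alpha]$ retains the
points with membership at least α. Rows with any feature outside its
feature's $A_\alpha$ are deleted (count $S_{mtd}$), again a union rule.

Choices worth knowing:

* **No clipping.** The bounds are applied literally; $a$ may be negative for
  nonnegative data. Conversely, for a lopsided sample with many points on one
  side and small variance the literal $a$ can exceed the observed minimum; the
  model warns, because those observed points get membership 0 and are removed
  at any α.
* **Zero-variance features** produce a domain that is meaningless as a filter,
  so the resampler skips the α-cut for them rather than deleting everything
  not exactly equal to $u_{set}$.
* **Width shrinks with sample size.** The diffusion term scales like
  $1/\sqrt{N_L}$: MTD was conceived for small samples, and on a Gaussian-like
  majority of n ≈ 50–300 the α = 0.5 cut retains roughly the central third of
  each feature, compounding across features under the union rule. This is the
  method as defined; practically it means the procedure is best suited to the
  small, heavily imbalanced training sets it targets, with few features or a
  lower α when many features are in play.
* **Default α = 0.5**, the recommended operating point: smaller α keeps
  unrepresentative tails (and forces more synthesis), larger α shrinks the
  training set towards the midpoint and invites overfitting. Overridable per
  run.

## Stage 3: Weibull fit by the Gini maximal-p-value test

The minority sample per feature (all rows — no outlier removal on the class
of interest) is assumed two-parameter Weibull with scale λ and shape β, a
family spanning exponential (β = 1), Rayleigh (β = 2) and near-normal
(β ≈ 3–4) shapes. The fit is *shape first*:

* For a candidate shape $\beta_0$, the normalised spacings
  $W_i = (N-i+1)(x_{(i)}^{\beta_0} - x_{(i-1)}^{\beta_0})$, $x_{(0)} \equiv 0$,
  are i.i.d. exponential exactly under $H_0\!: \beta = \beta_0$, whatever λ.
  The Gini statistic on those spacings,
  $G_N = \sum_{i<N} i\,W_{i+1} \big/ (N-1)\sum_i W_i \in [0,1]$, is
  scale-free with null mean ≈ 1/2 and a closed-form null CDF for
  $3 \le N \le 20$; beyond 20, $\sqrt{12(N-1)}(G_N - \tfrac12)$ is treated
  as standard normal. Two-sided p-values are $2\min(F(g), 1-F(g))$,
  mirroring the $|Z|$ form of the large-sample branch.
* $\hat\beta$ is the candidate with the **largest p-value** — a hypothesis
  test run in reverse, as an estimator. The search grid is 0.05–10 in steps
  of 0.05 with one refinement pass at step 0.005 around the maximiser; the
  grid generously brackets the shapes above, and p-value plateaus are broken
  by smaller median-rank SSE, then smaller β (deterministic, biased towards
  parsimonious exponential-like shapes).
* Given $\hat\beta$, the scale has a closed form: on the log-log scale the
  Weibull CDF is linear, the median-rank least-squares objective
  $\sum_i [\ln(-\ln(1-\hat F_i)) - \beta\ln x_{(i)} + \beta\ln\lambda]^2$
  (Bernard positions $\hat F_i = (i-0.3)/(N+0.4)$) is quadratic in
  $\ln\lambda$, and $\hat\lambda$ is its exact minimiser — a property the
  test suite verifies against a numeric one-dimensional optimiser.
* The Weibull needs positive support. Strictly positive input is fitted as
  is (shift 0); otherwise the data are shifted by
  $\min - 0.01\,\mathrm{range}$ (or $\min - 1$ for constant input) and the
  shift is added back on generation.

Synthetic values invert the fitted CDF at the Bernard positions of the
*target* sample size:
$\hat x_i = \hat\lambda\{-\ln[1 - (i-0.3)/(n'+0.4)]\}^{1/\hat\beta} + \text{shift}$.
Applied verbatim to every feature this would make all synthetic features
comonotone (each row a joint quantile), contradicting the independent-feature
picture, so the default `generation_mode = "permuted"` permutes the quantile
multiset independently per feature with the run's seeded generator;
`"median_rank"` keeps the literal increasing order. One global seed governs
every stochastic choice, so a run is bit-reproducible.

The fit requires at least three minority rows — both the exact Gini CDF and
any meaningful spacing structure need $N \ge 3$ — and the scenario harness
enforces the same floor.

## Metrics

Accuracy, G-mean $\sqrt{TPR \times TNR}$ and F-measure $2RP/(R+P)$ are
computed from confusion counts with the minority as positive. Ratios of the
form 0/0 (no predicted positives, no actual negatives) are taken as 0 to
keep the metrics total, matching common imbalanced-learning practice; a test
set with no actual positives is rejected outright since sensitivity is then
undefined.

## The synthetic-data generator and the harness

`make_synthetic_imbalanced()` draws Gaussian majority features and Weibull
minority features (so the oversampler's distributional assumption holds by
construction and parameter recovery is directly testable), optionally
displacing one feature of a fraction of majority rows by 12 IQRs to emulate
gross outliers. Defaults — 400 majority / 100 minority rows, four features,
majority means near 10 with unit-to-double spread, minority shapes 1.5–2.5
shifted into the lower majority tail, 2% outliers — sketch a mid-sized
clinical-like table with partial class overlap. What the generator does *not*
emulate: correlated features, heavy-tailed or multimodal majorities,
categorical columns, label noise. Green tests on these fixtures therefore
demonstrate the pipeline's contracts and the estimators' statistical
behaviour, not performance on any particular real data set.

`scenario_spec(r, n_train)` sizes a training set with an r% minority,
rounded half-up and floored at 3 — the only rounding consistent with the
quadruple (57,3), (76,4), (95,5), (142,8) at r = 5 for n_train = 60, 80,
100, 150 — and `run_experiment()` redraws train/test splits per repetition
(both sets redrawn each time), scoring a pluggable classifier hook on raw
versus rebalanced training. The reference hook is an SVM with polynomial
kernel of degree 2 and cost 1; any `function(train, test)` returning
predicted labels can be substituted.

## Numerical choices

* The exact Gini CDF is evaluated in double precision with the per-term
  products computed pairwise; for $N \le 20$ the computation is
  well-conditioned, and a 200,000-replicate Monte Carlo oracle built from
  unit-exponential spacings (independent of the package's spacing code)
  serves as the regression test, agreeing within 0.01 at the deciles.
* `gini_statistic` rescales by the sample maximum before powering — the
  statistic is scale-free, and this guards $x^\beta$ against overflow at
  large β.
* Ties at $u_{set}$, p-value plateaus, and equal class sizes each have a
  deterministic documented rule (count in neither side; smaller SSE then
  smaller β; declared positive label is the minority, with a warning).

Test problem sizes were chosen to make each statistical check sharp but
quick: 50,000 replicates for null-mean checks, 200,000 for CDF agreement,
5,000 for test calibration, 200 replicates of n = 100 for parameter
recovery, and 50 harness repetitions at the (57, 3) scenario.

## Limitations

* Two classes, numeric features only; no categorical or missing-data
  handling.
* The Weibull assumption is per feature and marginal; dependence between
  features is neither modelled nor preserved beyond the permutation device.
* The α-cut's sample-size behaviour (above) can empty the majority at high α
  or many features; the resampler then stops with an instructive error
  rather than returning an empty class.
* Comparison resamplers (one-sided selection, SMOTE variants, ensembles) are
  out of scope; the harness exists so any of them could be slotted in as a
  hook.
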