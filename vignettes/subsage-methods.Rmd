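---
title: "Sub-SAGE: loss-based feature importance with uncertainty for tree ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-SAGE: loss-based feature importance with uncertainty for tree ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

A fitted prediction model — here a gradient-boosted ensemble of shallow
regression trees, as commonly used for SNP-based risk prediction — tells us
what the *model* uses, not what matters in the *data*.  SHAP values
decompose individual predictions and therefore inherit every quirk of the
fit: a noise feature the booster latched onto will show a confident SHAP
trend.  A loss-based Shapley decomposition instead asks, for each feature
$k$, how much the expected loss on fresh data drops when the feature's
value becomes available to the model.  Positive values mean the feature
carries information about the response that the model actually exploits;
values near zero or negative mean the model's use of the feature does not
generalize.

The full loss-based Shapley value (SAGE) for feature $k$ averages the loss
difference $w(S \cup \{k\}) - w(S)$ over all $2^{M-1}$ coalitions $S$ of
the other features, where

$$ w(S) = E\left[\ell(Y, V(\emptyset))\right] - E\left[\ell(Y, V(S))\right],
\qquad V(S) = E_{X_{\bar S}}[\hat y(X) \mid X_S = x_S], $$

which is hopeless for hundreds of features.  **Sub-SAGE** keeps three
informative layers of coalitions only: the empty set (the marginal effect
of $k$), every other singleton $\{m\}$ (pairwise interactions), and the set
of all features except $k$ (the effect of $k$ on top of everything else):

$$ \psi_k = \sum_{S \in Q_k} \frac{|S|!\,(M-|S|-1)!}{3\,(M-1)!}
   \left[ w(S \cup \{k\}) - w(S) \right]. $$

The weights reduce to the closed forms $1/3$ for the empty set,
$1/(3(M-1))$ per singleton and $1/3$ for the all-but-$k$ set — each subset
size carries a third of the total weight, and the weights sum to one.  The
package never evaluates a factorial, so $M$ in the hundreds is exact.
Dummy, symmetry and monotonicity survive the restriction; efficiency does
not, which is acceptable because the goal is to screen a handful of
candidate features, not to decompose the total loss.

`coalition_family()` refuses $M < 3$: with two features the singleton and
all-but-$k$ layers collide and the three-size construction degenerates.

## Tree ensembles make the estimate exact

For an additive ensemble $\hat y(x) = c + \sum_\tau f_\tau(x)$ the
conditional expectation $V(S)$ splits over trees, and a single recursive
pass per tree computes $E[f_\tau \mid X_S = x_S]$: at a node whose split
feature is in $S$, follow the branch the instance dictates; otherwise
average both children with the node's traversal probabilities
(`cond_exp_tree()`).  The traversal probability of a node splitting
feature $f$ at threshold $t$ is estimated as the empirical fraction of
data rows whose $f$ value falls in the half-open interval implied by
ancestor splits *on the same feature*; splits on other features impose no
constraint because features are assumed independent.  All supplied rows
are counted at every node, whatever leaf they would actually reach.

Two numerical conventions matter here:

* **Routing is "left iff $x < t$"**, exactly as in XGBoost JSON dumps.
  The recursion is sometimes written with $\le$; the two differ only when
  a threshold coincides with a data value.  XGBoost places thresholds
  strictly between observed float32 values (for genotype dosages, between
  integers), so no tie is reachable in the intended use.  The reader also
  snaps dump thresholds and leaf values to the nearest float32, because
  the dump prints single-precision parameters in decimal and re-reading
  them as doubles would otherwise shift them off the float32 grid.
* **Zero-count intervals**: under bootstrap resampling an
  ancestor-restricted interval can lose all its rows.  The node then falls
  back to the unconditional marginal fraction for its threshold, and to
  probability $1/2$ per child in the (unreachable in practice) case of no
  rows at all.  Fallbacks are counted and reported as a warning, never an
  error, so that resampling loops are total.

Only the trees that split on $k$ (the group $\tau_k$) react when $k$
enters a coalition.  Expanding the squared-error difference gives the
decomposed estimator actually computed, per test row:

$$ 2\,y\,\Delta A + A_S^2 - A_{S\cup k}^2 - 2\,(C_S + c)\,\Delta A, $$

with $A$ the sum over $\tau_k$ trees, $C$ the sum over the rest, $c$ the
ensemble's base offset and $\Delta A = A_{S \cup k} - A_S$.  Note that the
offset does not cancel: it rides along with $C$ in the cross term, and
dropping it would break the algebraic identity with the direct
loss-difference estimator.  The package keeps both paths — the naive
direct estimator (`naive_delta_loss()`) as an oracle and the decomposition
(`delta_loss_squared()`, `delta_loss_xent()`) as the workhorse — and the
test suite holds them to $10^{-9}$ agreement on random ensembles.

For binary classification the loss is cross-entropy evaluated on the
margin (logit) scale, where the conditional expectation lives inside the
loss: the linear term involves only $\tau_k$ trees, while the
log-partition term needs the full margins under $S$ and $S \cup \{k\}$.
The $\log(1+e^{-m})$ terms are evaluated branch-wise with `log1p`, which
is finite and accurate for any margin; no clipping is applied, because the
exact branch-wise form makes saturation a non-issue rather than something
to guard with a threshold.

### Cost, caching and exactness

A tree's value under coalition $S$ depends only on $S$ intersected with
the tree's own split features and on the row's branch decisions at its
internal nodes.  For the depth-2 trees this package targets, both are tiny
enumerations, so per-row values are lookups into per-tree tables; the
branch decisions are computed once per data set and reused across all
bootstrap replicates.  This caching is observationally equivalent to
calling the recursion directly — the tests compare the two — and keeps a
full $B = 1000$ bootstrap of a 260-tree, 100-feature model on 3200 test
rows around two minutes on one core.  Trees with more than 12 distinct split
features are refused (the enumeration would no longer be small); the
models this method is designed for have depth ≤ 2.

## Why independent test data is non-negotiable

A boosted model fits its training data by construction, including its
noise.  Sub-SAGE estimates computed on training rows systematically
overstate importance and understate uncertainty — the benchmark shows a
pure-noise feature acquiring a confidently positive training-data
estimate.  The `subsage_data` container therefore carries an explicit
`test_independent` flag, and `subsage_estimate()` / `paired_bootstrap()`
refuse to run without it.  The flag is the caller's assertion; the package
cannot verify provenance, only insist that the question was answered.

For a *linear* model the whole construction collapses to a closed form on
independent test data:

$$ \psi_k = 2\hat\beta_k\,\mathrm{Cov}(Y, X_k) - \hat\beta_k^2\,\mathrm{Var}(X_k), $$

identical for every coalition (`linear_subsage_closed_form()`).  The first
term measures how much of the fitted effect reappears in fresh data; the
second is the variance cost of carrying the feature.  A spuriously fitted
feature has $\mathrm{Cov} \approx 0$ and pays the variance penalty, which
is what drives null features slightly negative and is the quantitative
content of the bias–variance trade-off in this setting.

## Uncertainty: the paired bootstrap

The plug-in estimator is a complicated functional of the empirical test
distribution, so its sampling uncertainty is estimated by the
nonparametric paired bootstrap with the **model held fixed**: resample the
$N_I$ test rows (features and response jointly) with replacement,
re-estimate every node probability on the resample — the probabilities
are part of the estimator, so they must follow the bootstrap measure —
and recompute $\psi^*_k$.  Refitting the model per replicate is a
different (and far costlier) inferential target and is deliberately out
of scope.

Intervals come from order statistics: the $(1-2\alpha)$ percentile
interval takes the $\lceil B\alpha\rceil$-th and
$\lceil B(1-\alpha)\rceil$-th smallest replicates.  The ceiling convention
is a deliberate choice for non-integer $B\alpha$; at the benchmark's
$B = 1000$, $\alpha = 0.025$ it selects exactly the 25th and 975th values.
The BCa variant corrects for median bias ($z_0$, the normal quantile of
the fraction of replicates below the point estimate; if every replicate
falls on one side the correction is undefined and the function says so
rather than extrapolating) and for skewness via the acceleration $a$,
estimated by the jackknife over test rows — each leave-one-out sample
re-estimates probabilities and the full $\psi_k$.  The jackknife costs
$N_I$ estimate recomputations, so zero acceleration is the sensible
default once $N_I$ reaches the tens of thousands; for the benchmark's
3200 rows the full jackknife runs in about a minute.

Reproducibility: replicate $b$ draws its indices from a counter-derived
substream of the root seed (a splitmix64 stream keyed by $(\text{seed},
b)$), so any replicate can be recomputed in isolation and results do not
depend on execution order.

A one-sided importance decision (`one_sided_importance_test()`) rejects
"$\psi_k \le 0$" when the one-sided $(1-\alpha)$ lower percentile bound is
positive.  No multiple-testing adjustment is applied; screening many
features requires external control.

## SHAP and ERFC

`tree_shap_exact()` computes interventional SHAP values exactly by
per-tree enumeration of the tree's own feature subsets (Shapley linearity
over the additive ensemble), which is exact and fast for depth-2 trees and
refuses trees wider than 12 distinct features.  The ERFC score
$\kappa_k$ is the per-instance mean of $|\phi_{ik}| / (|\phi_0| + \sum_j
|\phi_{ij}|)$ — the *mean* convention keeps $\kappa \in [0,1]$ and matches
the benchmark's reported magnitudes (the dominant feature scores about
0.48, not a sum growing with $N$).  ERFC describes the model alone, so it
may be computed on training data; it is the cheap pre-ranking step that
selects candidates for the expensive Sub-SAGE + bootstrap treatment.

## The synthetic benchmark and its oracles

`generate_synthetic()` draws 16000 samples (by default) from a known
response
$f(x) = a_0 + a_1 x_1 + a_2 x_2 + a_{21} x_1 e^{x_2} + a_3 x_3^2 +
a_4 \sin x_4 + a_5 \log(1 + x_5) - x_5\,\mathbb{1}(x_6 > 7) + \varepsilon$
with binomial, gamma, uniform, Poisson and normal feature laws,
$\varepsilon \sim N(0, 2)$, and 94 noise features (41 normal, 53
binomial) whose parameters are drawn once per seed from
$\mu \sim U(-3,3)$, $\sigma \sim U(0.5,3)$, $p \sim U(0.05,0.5)$.  Those
ranges are a modelling choice of this package: the noise features are
null players, so no true importance value depends on them; they are
recorded in the dataset's attributes.  The indicator uses the strict
inequality $x_6 > 7$.  Rows are split 50/30/20 into train/validation/test
before any model sees them.  `train_demo_model()` fits the benchmark
booster (depth 2, $\eta = 0.05$, subsample 0.7, column subsample 0.8,
$\lambda = 1$, $\gamma = 0$, early stopping after 20 stale rounds on the
validation split, squared-error loss); a typical
seed yields 200–270 trees using about 60 of the 100 features.

Because the generating process is known, true values exist:

* `true_model_value()` estimates $E[f \mid X_S = x_S]$ by Monte Carlo over
  the excluded coordinates.
* `true_subsage_mc()` and `true_sage_mc()` evaluate the Sub-SAGE and SAGE
  definitions with the fitted model replaced by $f$ itself.  Inside the
  squared losses, the conditional means factor over the independent
  features, so each excluded term contributes its exact 1-D moment
  ($E[e^{X_2}] = (1-p+pe)^2$, $E[X_3^2] = 27.5$, $E[\sin X_4] = 2/\pi$, a
  truncated Poisson sum for $E[\log(1+X_5)]$, $15\,P(X_6 > 7)$ for the
  interaction); the outer expectation over $(X, \varepsilon)$ is the Monte
  Carlo part, and each oracle reports its standard error.  The additive
  response noise inflates both loss terms of every delta equally and
  cancels in expectation — the tests verify the estimates agree with the
  noise turned off.  Noise features are returned as exact zeros (dummy
  axiom), and the SAGE oracle needs only the $2^6$ subsets of the six
  influential features for the same reason, with the subset weighting
  delegated to `sage_bruteforce()`.
* `true_shap_point_mc()` brute-forces the pointwise Shapley value of the
  true $f$ at an instance from one shared set of marginal draws.

At $10^6$ draws the oracle standard errors are ~0.07 (dominant feature)
down to ~0.001 (weak features); comparisons in the test suite always use
3-standard-error bands rather than point equality.

## What passing tests do and do not show

The generator emulates independent features with clean marginal laws and
a known sparse signal.  Real genotype data violate independence (linkage
disequilibrium), which is why the intended workflow prunes correlated
SNPs before modelling; the conditional-expectation machinery here is
explicitly *interventional* (marginal), and all guarantees are under
independence.  Passing the benchmark therefore shows the estimator,
bootstrap and oracles are internally correct and well calibrated under
the stated assumptions — not that importance estimates on strongly
dependent features are trustworthy.  Dependent-feature value functions,
SHAP/SAGE interaction values and multiple-testing control are out of
scope.

Problem sizes in the test suite are chosen to keep the full run at a few
minutes: the end-to-end benchmark uses $B = 200$ bootstrap replicates
(the acceptance script uses the full $B = 1000$), the calibration study
uses 20 reduced generators (n = 1200, 16 features) × 5 null features at
$B = 200$, and oracle reproductions use $10^6$ draws.

## Worked example

```{r, eval = FALSE}
library(subsage)

data <- generate_synthetic(seed = 1)          # 16000 x 100, roles assigned
model <- train_demo_model(data, seed = 1)     # depth-2 boosted ensemble

# model-side screening (training data is fine here)
xtr <- data_matrix(data, c("train", "valid"))
model_tr <- estimate_node_probabilities(model, xtr)
head(erfc_scores(tree_shap_exact(model_tr, xtr)))

# data-side importance with uncertainty (held-out rows only)
model <- estimate_node_probabilities(model, data_matrix(data, "test"))
est <- subsage_estimate(model, data, k = 6)
boot <- paired_bootstrap(model, data, k = 6, B = 1000, seed = 1)
boot$percentile
bca_interval(boot, "jackknife", ensemble = model, data = data)
one_sided_importance_test(boot, alpha = 0.05)
```

The same functions drive the command-line interface
(`inst/cli/subsage`): `simulate` writes the benchmark dataset and model,
`estimate`, `bootstrap` and `erfc` consume any XGBoost JSON dump plus a
CSV with a role column, and every run writes a manifest of its effective
parameters and seeds.
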