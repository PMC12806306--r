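---
title: "Joint denoising-autoencoder deep survival regression: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint denoising-autoencoder deep survival regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daesurv)
```

## The problem

Clinical-trial registries describe each trial by a wide, mostly one-hot
covariate vector (design features such as randomization, allocation scheme,
blinding, sponsor class, development index of the study countries, planned
sample size quartile), plus an observed duration in days and an indicator of
whether the trial reached normal completion. Trials still ongoing at the
last registry update are right-censored. The feature space is sparse: with
~30 one-hot columns most cells are zero, and a deep Cox network fitted
directly to such features memorizes the training set — training concordance
far above test concordance.

`daesurv` addresses this by learning the risk score on a compressed, robust
representation. A denoising autoencoder and a deep Cox
proportional-hazards head are trained *jointly*: the encoder must produce a
bottleneck representation that simultaneously reconstructs the (clean)
input from a noise-corrupted copy and ranks event times well.

## Model

Covariates $x \in \mathbb{R}^p$ are corrupted with additive Gaussian noise,
$\tilde x = x + \varepsilon$, $\varepsilon \sim N(0, \sigma^2 I)$. The
encoder $f_\theta$ maps $\tilde x$ through a 32-unit rectified layer to a
16-dimensional linear bottleneck $y$; the decoder $g_\theta$ mirrors it
(16 → 32 → $p$, linear output). The survival head $h_\theta$ is a
single-hidden-layer MLP on $y$ (16 units, rectifier, batch normalization,
dropout 0.1, one linear output) producing a log-hazard score under
proportional hazards, $\lambda(t \mid x) = \lambda_0(t)\, e^{h(x)}$.

The training objective is the weighted sum

$$
\ell \;=\; \alpha\, \ell_{\text{surv}} \;+\; \gamma\, \ell_{\text{recon}},
\qquad \gamma = 1 - \alpha,\ \alpha = 0.6 \text{ by default,}
$$

where $\ell_{\text{recon}} = \tfrac1n \sum_i \lVert x_i -
g_\theta(f_\theta(\tilde x_i)) \rVert^2$ targets the **clean** input
(the denoising objective), and $\ell_{\text{surv}}$ is the negative Cox
partial log-likelihood under the Breslow tie convention,

$$
\ell_{\text{surv}} = -\frac{1}{d}\sum_{i:\,E_i=1}\Big[h_i -
\log\!\!\sum_{j:\,T_j \ge T_i}\!\! e^{h_j}\Big],
$$

normalized by the event count $d$ so that $\alpha$ keeps a consistent
meaning across batch sizes (a configuration flag disables this). Risk sets
are formed within each minibatch (batch 256 against ~650 training rows),
the established deep-survival practice; full-batch training is available
by raising `batch_size`. Optimization is Adam at learning rate 0.01, up to
200 epochs. Survival curves come from the Breslow cumulative baseline
hazard $\hat H_0$ fitted on the training scores:
$\hat S(t\mid x) = \exp\{-\hat H_0(t)\, e^{h(x)}\}$.

Two baselines share the evaluation path verbatim: a linear Cox model
maximized by our own Newton–Raphson on the same Breslow partial likelihood
(it doubles as an independent oracle for the loss code), and a plain deep
Cox network ("DeepSurv") with two hidden layers (32, 16) on the raw
covariates — no encoder, no corruption.

## Design choices where the design was genuinely open

**Model selection monitors the survival loss, not the joint loss.**
Early stopping (patience 20) watches a validation split carved 8:2 from
the training rows. We select the best epoch by the validation *survival*
loss rather than the joint loss: the reconstruction term keeps improving
for many epochs after the risk ranking has started to overfit, so a
joint-loss monitor systematically stops too late and forfeits exactly the
generalization benefit the autoencoder exists to provide. This is the
standard treatment of auxiliary losses: train on the composite objective,
select on the task objective. (An `alpha = 0` run, which has no survival
term, monitors the reconstruction loss.)

**Corruption.** $\sigma$ defaults to 0.1 — a mild perturbation for inputs
that are z-scored or in $\{0,1\}$ — and is applied to *all* columns,
binary included, as additive Gaussian noise; a masking-noise variant was
considered and rejected as the architecture names Gaussian corruption.
Corruption is active only during training; inference encodes clean inputs.

**Two-stage option.** `fit_daedsr(two_stage = TRUE)` first trains the
autoencoder alone, then freezes the encoder and trains the head — the
sequential reading of the same architecture. Joint training is the
default because the weighted loss is only meaningful when both terms see
gradients together.

**Normalization.** Z-score per numeric column, with the *population*
standard deviation (denominator $n$); min-max is available by
configuration. Statistics are learned on training rows and applied
unchanged to test rows.

**SMOTE on survival data.** Class balancing interpolates minority-class
rows: $x_{\text{new}} = x_i + u (x_{nn} - x_i)$, $u \sim U(0,1)$, with
$x_{nn}$ one of the $k = 5$ nearest minority neighbours. Survival labels
have no canonical SMOTE treatment; we interpolate the observed time with
the *same* $u$ and assign the minority event label, keeping $(x, T)$
jointly plausible under smoothness of the hazard in $x$. The minority
class is determined from the data, not hard-coded. SMOTE runs on training
rows only, after the split — the leakage-free order
(duplicates → column filter → imputation → split → normalization fitted on
train → SMOTE on train) is fixed and asserted by tests. Training
concordance is reported on the original training rows, excluding the
synthetic ones.

**Concordance orientation.** A pair is comparable when the earlier
subject's event was observed ($T_i < T_j$, $E_i = 1$); it is concordant
when that subject carries the *higher* risk score, making $C = 1$ optimal.
Tied risk scores earn half credit (Harrell convention); tied times are not
comparable.

**IPCW weights.** The censoring survival $\hat G$ is the Kaplan–Meier
estimator with censorings as events. Weights are evaluated at
$\hat G(T_i)$ (right-continuous); a flag offers the left-limit
$\hat G(T_i^-)$ convention. The Brier grid defaults to 100 points from 0
to the 90th percentile of the observed times, avoiding the
$\hat G \to 0$ tail, and the integrated Brier score is the trapezoid
integral normalized by the grid span.

**Survival head width.** One hidden layer of 16 units on the
16-dimensional bottleneck; the DeepSurv baseline uses two hidden layers
(32, 16) on the full input, mirroring the architecture it reproduces.

## The synthetic registry generator

No registry extract ships with the package, so every experiment runs on a
generator with known proportional-hazards ground truth:

* `n_trials = 819` rows; 28 binary covariates, i.i.d. Bernoulli with
  $P(0) = 0.85$ (`sparsity`), and 5 standard-normal numeric covariates —
  the shape of the registry data the package targets.
* True log-hazard $\eta = x^\top \beta + \epsilon$,
  $\epsilon \sim N(0, \texttt{noise\_sd}^2)$ with `noise_sd = 0.5` by
  default; $\beta$ defaults to a handful of strong effects
  ($\pm 0.8, \pm 0.6, 0.4$ on the first binaries; $\pm 0.5, 0.3$ on the
  first numerics) and zeros elsewhere, emulating a registry where a few
  design features dominate. The latent noise controls the Bayes
  concordance ceiling, computable exactly via `true_risk()`.
* Event times from an exponential baseline ($\lambda_0 = 10^{-3}$ per
  day, median ~693 days at zero risk; a Weibull shape parameter
  generalizes it). Administrative censoring is Uniform(0, 3000 days),
  giving roughly one third censored — the class imbalance the SMOTE step
  exists for. Times are continuous to avoid artificial ties; a
  `round_days` flag creates ties deliberately for tie stress-testing.
* Missing cells are injected completely at random (5% by default), never
  on time or event; the pre-missingness matrix is retained so oracles
  stay computable.

What the generator does **not** emulate: dependence between covariates
(one-hot groups from a shared categorical, development-index/country
correlation), informative censoring, calendar-time effects, and any
non-proportional hazard. Tests passing on this generator therefore show
the pipeline is correct and that the regularization behaves as designed
under proportional hazards — not that the same ranking accuracy would be
achieved on real registry extracts.

## Numerical choices

The partial likelihood uses a shifted log-sum-exp over descending-time
cumulative sums, with tied times sharing the full risk set; its gradient
is analytic and is checked against central finite differences and an
$O(n^2)$ brute-force implementation. Newton–Raphson for the linear model
adds a ridge of $10^{-6}$ to the information matrix (and warns when the
unpenalized matrix is near-singular, e.g. duplicated columns), halves
steps when the objective fails to decrease, and stops at gradient
max-norm $10^{-8}$. Batch normalization uses batch statistics in
training (rejecting batches of size one) and running statistics at
evaluation; dropout is inverted. Weight initialization is uniform
fan-in. All randomness — initialization, the validation carve, batch
shuffling, dropout masks, corruption draws — flows from one seed, so a
fitted model is bit-reproducible on the same platform.

KNN imputation measures distance over mutually observed coordinates,
rescaled by $\sqrt{p / p_{\text{obs}}}$, takes the $k = 5$ nearest donor
rows that observe the target column, and rounds binary imputations to
$\{0, 1\}$; it is idempotent and keeps imputed values within each
column's observed range.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the registry scale it targets
(n = 819, 33 covariates) and smaller: oracle comparisons use 200–500
random instances of $n \le 60$; parameter recovery uses $n = 2000$ with a
single binary covariate; Bayes-ceiling tracking uses an easy scenario
($n = 800$, 20 covariates, three strong effects, no latent noise, light
censoring); the generalization-gap comparison runs the default sparse
scenario over seven seeds. These sizes make the entire suite run in
about a minute on one core while keeping every statistical check at a
scale where its expected behaviour is unambiguous.

## Known limitations

* Proportional hazards is assumed end to end; no time-varying effects,
  competing risks, or Cox-Time/Cox-CC style alternatives.
* The Breslow tie convention only (no Efron); with continuous simulated
  times the difference is immaterial, with heavily rounded times it is not.
* Minibatch risk sets are an approximation to the full-batch partial
  likelihood; at batch 256 against ~650 training rows the approximation
  is mild, and full-batch mode is one parameter away.
* Single-run neural results are seed-sensitive; the experiment runner
  aggregates medians across seeds, and headline comparisons should be
  read at that aggregation level, not per seed.
* Feature importance by retrain-without-column measures a feature's
  marginal contribution under re-optimization; correlated one-hot groups
  should be removed as named groups (supported) or the attribution
  fragments across the group.
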