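---
title: "Z-LDA: a z-score decision rule for heteroscedastic linear discriminants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Z-LDA: a z-score decision rule for heteroscedastic linear discriminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zlda)
```

## The model

A binary linear discriminant projects a feature vector $x \in \mathbb{R}^d$
to a scalar weight sum

$$y = w_0 + w^\top x,$$

where $(w_0, w)$ is fitted by least squares on the augmented system: a
dummy input 1 is prepended to every sample and the squared error between
the outputs and the numeric class codes ($t = -1$ for class $\omega_1$,
$t = +1$ for $\omega_2$) is minimised. With this coding the least-squares
solution is equivalent to the Fisher-criterion discriminant direction, so
only the least-squares route is implemented (`fit_least_squares()`).

The conventional LDA decision thresholds $y$ at the midpoint of the
codes, 0 for $\pm 1$ coding (`lda_predict()`). That midpoint is the
optimal boundary only under homoscedasticity: when both classes project
to score distributions with equal variance. EEG band-power features
violate this routinely — one motor-imagery task often produces markedly
more variable features than the other — and then the midpoint rule gives
away probability mass of the wider class.

Z-LDA keeps the projection and repairs the rule. The training weight
sums of each class are summarised by a Gaussian, $\mu_i$ and $\sigma_i$
estimated per class (`estimate_score_distributions()`), and a new sample
with weight sum $y$ is assigned by comparing

$$z_i = \frac{|y - \mu_i|}{\sigma_i}, \qquad
  \text{choose } \omega_1 \iff z_1 \le z_2 .$$

Between the class means the rule is equivalent to thresholding at the
closed form

$$b = \frac{\sigma_2 \mu_1 + \sigma_1 \mu_2}{\sigma_1 + \sigma_2},$$

which always lies strictly between $\mu_1$ and $\mu_2$, equals their
midpoint when $\sigma_1 = \sigma_2$, and moves toward the class with the
smaller SD otherwise. Conventional LDA is thus the homoscedastic special
case of Z-LDA, and the package asserts this reduction exactly in its
tests.

### The literal rule, not the threshold

`zlda_predict()` applies the z-comparison literally rather than
thresholding at $b$. The distinction matters: when
$\sigma_1 \ne \sigma_2$ the locus $z_1 = z_2$ has *two* crossings, and in
the far tail on the small-SD side the wide class wins again (at
$y = \mu_1 - 3$ SD-units in the example below, the sample is further from
the tight class 1, in SD units, than from the wide class 2):

```{r two-crossings}
set.seed(1)
m <- fit_zlda(rbind(matrix(rnorm(60, -1, 0.3), 30),
                    matrix(rnorm(60, 1, 1.0), 30)),
              rep(c("left", "right"), each = 30))
zlda_boundary(m)                      # the inner crossing, a diagnostic
predict(m, matrix(c(-0.9, 0, -5), ncol = 1))[1:3]
```

$b$ is therefore exposed by `zlda_boundary()` as a diagnostic and
plotting value only. Note also that $b$ is the *z-equality* point, which
is not the exact equal-density intersection of the two Gaussians when
$\sigma_1 \ne \sigma_2$ (the density intersection carries an extra
$\log(\sigma_2/\sigma_1)$ term); the implementation follows the z-score
definition throughout.

### Classification reliability

A by-product of the z-scores is a per-decision reliability,

$$r_i = \frac{\phi(z_i)}{\phi(z_1) + \phi(z_2)}, \qquad r_1 + r_2 = 1,$$

with $\phi$ the standard normal density. This density-ratio form is one
reasonable reading of deriving "how reliable the classification is" from
the z-scores; it is not a calibrated posterior probability (it ignores
class priors and the unequal widths), and it is computed in the log
domain (`plogis((z_2^2 - z_1^2)/2)`) so extreme scores cannot underflow.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `coding` | `fit_zlda()` | $(-1, +1)$ | classical coding; all boundary formulas use the actual codes, never hard-coded $\pm 1$ |
| `sd_denom` | `fit_zlda()` | `"n-1"` | sample SD; switchable to `"n"` for the population convention |
| `ridge` | `fit_least_squares()` | 0 | optional stabiliser; CSP log-variance features can be nearly collinear |
| `sigma_floor` | `fit_zlda()` | 0 (off) | a zero class SD is an error by default so constant features cannot misbehave silently |
| `threshold` | `reject_artifacts()` | 300 µV | conventional ocular-artifact amplitude screen |
| `band` | `bandpass_filter()` | 8–30 Hz | the classical motor-imagery (mu + beta) band; subject-specific band optimisation is out of scope |
| `n_pairs` | `select_filter_pairs()` | 3 | 3 pairs = 6 log-variance features, the standard CSP dimensionality |
| `shrinkage` | `fit_csp()` | 0 | scalar shrinkage toward the identity for rank-deficient covariances |

Numerical choices: ties $z_1 = z_2$ (and scores exactly at the midpoint
in `lda_predict()`) resolve deterministically to $\omega_1$ — a
measure-zero event that must still be reproducible. Rank-deficient
normal equations fall back to the minimum-norm pseudo-inverse
(`MASS::ginv`); set `pseudo_inverse = FALSE` to get an error instead.
Model JSON is written with 17 significant digits so a save/load
round-trip reproduces predictions bit for bit.

## The simulation study

`run_study()` regenerates the heteroscedastic comparison that motivates
the rule. Class 1 is a bivariate Gaussian with mean $(-1, -0.6)$ and
per-dimension SD 0.3; class 2 has mean $(1, 0.6)$ and per-dimension SD
$0.3 + \delta$. For each level $\delta$, 100 train and 100 test samples
per class are drawn, both rules are fitted on the training set and scored
on the test set, and the procedure is repeated 100 times; the table
reports mean ± SD of accuracy over repetitions and a two-sided paired
t-test between the two accuracy vectors.

Levels are expressed as the per-dimension SD increment
$\delta = 0.0, 0.1, \ldots, 0.9$. Because both dimensions are
incremented equally, the norm of the SD-*difference vector* between the
classes is $\delta\sqrt{2}$ — the natural unit in which to read the level
axis if one prefers vector norms; the configuration with class-2 SD
$(1.0, 1.0)$ sits at $\delta = 0.7$.

Per-repetition seeds are drawn once from the master seed, so the full
study is deterministic and any single repetition can be replayed in
isolation (`run_single_repetition(cfg, seed)`). At $\delta = 0$ the
projected class separation is $\approx 7.8$ SDs, so the Gaussian error
rate is $\approx 5\times 10^{-5}$ and both rules sit at $\approx 99.99\%$;
the tests check a single repetition against this closed-form error-rate
oracle. Accuracies are displayed in percent with two decimals; stored
values keep full precision.

```{r study, eval = FALSE}
run_study(sim_config(), seed = 1)   # ~10 s: 10 levels x 100 repetitions
```

## The CSP front-end

For multichannel trials the features are produced by the standard
common-spatial-patterns recipe: per-trial channel covariance normalised
by its trace, averaged within class; the two class means $\bar C_1,
\bar C_2$ are jointly diagonalised by whitening $\bar C_1 + \bar C_2$ and
eigen-decomposing the whitened $\bar C_1$. Each row of the resulting
filter matrix maximises projected variance under one class while
minimising it under the other; eigenvalue $k$ is the class-1 variance
fraction of filter $k$ (class-2 fraction $1 - \lambda_k$), so
"discriminative" means $|\lambda - 0.5|$ large and the 3 + 3 spectrum
extremes are selected. Features are $\log(\mathrm{var})$ of each
surrogate channel. The band-pass is a 4th-order Butterworth applied
forward–backward: zero phase, so filter latency cannot distort the
variance features.

## The synthetic trial generator

`generate_synthetic_trials()` emulates the class-dependent band-power
structure that CSP exploits: latent Gaussian sources, two of which swap
variances between classes (defaults 4 vs. 1 and 1 vs. 4, a 4:1 power
ratio each way, mirroring lateralised event-related desynchronisation),
plus unit-variance background sources, mixed into 15 channels through a
fixed random mixing matrix, with additive sensor noise (SD 0.25, small
against the unit background sources — a good-SNR laboratory recording in
which the configured variance ratio is identifiable as a top CSP
eigenvalue near $4/(4+1) = 0.8$). Trials are 500 samples at 250 Hz and
scaled to tens of microvolts so the 300 µV artifact screen passes clean
data untouched.

What the generator does *not* emulate: 1/f spectra and band-limited
rhythms (sources are white), non-stationarity across trials, volume-
conduction structure of a real montage, eye/muscle artifacts, or
session-to-session covariate shift. Passing the end-to-end test
(synthetic trials → rejection → band-pass → CSP → log-variance → Z-LDA
above 90% test accuracy) therefore shows the pipeline is wired correctly
and learnable on data with the assumed structure — not that any
particular accuracy will be reached on recorded EEG.

## Problem sizes used by the test suite

The suite favours sizes that make each property sharp: the full
10-level × 100-repetition study for the accuracy table; $10^4$ samples
per class for score-distribution parameter recovery (mean within
$3\sigma/\sqrt{n}$, SD within 5%); 1000 random $(\mu, \sigma)$
configurations for the boundary-vs-brute-force oracle at $10^{-6}$; 100
trials per class for CSP eigenvalue recovery ($0.8 \pm 0.05$).

## Known limitations

Binary classification only; no multiclass z-rule. The score summaries
are Gaussian by assumption — heavy-tailed projections will misplace the
boundary. The reliability output is uncalibrated (see above). CSP is
fitted without frequency-band optimisation, and the trial container
assumes epoching happened upstream. HLDA-style covariance-aware
boundaries in the original feature space are deliberately out of scope:
the contribution implemented here is precisely that the one-dimensional
projected distributions suffice.
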