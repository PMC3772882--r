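# zlda

Z-score linear discriminant analysis (Z-LDA) for binary classification
under heteroscedastic class distributions, with the EEG motor-imagery
front-end it was designed for: a common-spatial-patterns (CSP) feature
pipeline and a Monte-Carlo harness that quantifies when the z-score rule
beats the conventional LDA rule.

## The problem and the method

Linear discriminant analysis projects a feature vector `x` to a scalar
weight sum

    y = w0 + w'x

with `(w0, w)` the least-squares solution of the augmented linear system
that maps training samples to their class codes (−1 for class ω1, +1 for
ω2). Conventional LDA then thresholds `y` at the midpoint of the codes
(0 for ±1 coding). That threshold is optimal only when the two classes
have equal covariance — an assumption routinely violated by EEG features,
where one imagery task often produces far more variable band power than
the other.

Z-LDA keeps the projection but replaces the decision rule. The training
weight sums of each class are summarised by a Gaussian `N(mu_i, sigma_i²)`,
and a new sample is assigned to the class whose distribution it is closer
to in SD units:

    z_i = |y − mu_i| / sigma_i,      choose ω1 iff z1 ≤ z2.

Between the class means this rule is equivalent to thresholding at

    b = (sigma2·mu1 + sigma1·mu2) / (sigma1 + sigma2),

which reduces to the midpoint when `sigma1 = sigma2` (so conventional LDA
is the homoscedastic special case) and otherwise shifts the boundary
toward the class with the smaller spread — exactly where the extra
probability mass of the wider class lies. The z-scores also yield a
per-class reliability `r_i = φ(z_i)/(φ(z1)+φ(z2))` for each decision.

Around the classifier the package provides the standard motor-imagery
front-end: amplitude-based artifact rejection (300 µV), zero-phase
Butterworth band-pass filtering (default 8–30 Hz), CSP spatial filtering
with selection of the 3 most discriminative filter pairs, and
log-variance features; plus a synthetic multichannel trial generator so
the whole pipeline runs without recorded data.

## Worked example

```r
library(zlda)

# Heteroscedastic 2-D Gaussians: class 2 three times as spread as class 1
cfg <- sim_config(sd_delta = 0.6)            # class-1 SD 0.3, class-2 SD 0.9
train <- generate_gaussian_2class(cfg, seed = 2)
test  <- generate_gaussian_2class(cfg, n_per_class = 100, seed = 102)

model <- fit_zlda(train$x, train$class_ids)
model
#> Z-LDA model (z-score linear discriminant)
#>   features: 2
#>   class class1 -> code -1: mu = -0.7762, sigma = 0.191 (n = 100)
#>   class class2 -> code 1: mu = 0.7762, sigma = 0.5608 (n = 100)
#>   boundary b = -0.3819 (label midpoint 0)

scores <- predict(model, test$x, type = "score")
mean(predict(model, test$x) == test$class_ids) * 100          # Z-LDA
#> [1] 98
mean(lda_predict(scores) == encode_labels(test$class_ids)) * 100  # LDA
#> [1] 93.5
```

The fitted class-2 score SD is about three times the class-1 SD, so the
Z-LDA boundary sits at −0.38 instead of 0, and on this split the z-rule
recovers 4.5 percentage points of accuracy that the midpoint rule loses
to the wide class. The full comparison over increasing SD differences,
with paired t-tests over 100 repetitions, is one call:

```r
run_study(sim_config(), seed = 1)
#> Accuracy study: 100 repetitions per level (master seed 1)
#>  level         LDA       Z-LDA        p
#>    0.0 100.00±0.00 100.00±0.00        -
#>    0.1  99.92±0.18  99.96±0.14   0.0517
#>    0.2  99.44±0.55  99.80±0.30 1.57e-09
#>    0.3  98.72±0.91  99.37±0.57 1.44e-11
#>    0.4  97.50±1.01  98.80±0.85 4.83e-20
#>    0.5  96.52±1.42  98.20±1.04 5.29e-20
#>    0.6  94.92±1.61  97.27±1.27 1.31e-22
#>    0.7  93.90±1.59  96.35±1.30 6.32e-25
#>    0.8  92.89±1.80  94.88±1.73 3.44e-15
#>    0.9  91.81±2.06  93.80±2.03 8.89e-12
```

A command-line wrapper (`system.file("cli", "zlda", package = "zlda")`)
exposes `fit`, `predict`, `simulate` and `csp-pipeline` subcommands over
the same functions.

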