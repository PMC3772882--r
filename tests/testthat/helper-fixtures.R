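# Shared fixtures, all generated in code.

# Two well-separated Gaussian clouds in d dimensions.
make_separable_fixture <- function(n_per_class = 20, d = 2, seed = 101,
                                   sd1 = 0.3, sd2 = 0.3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d, -1, sd1), n_per_class),
             matrix(rnorm(n_per_class * d, 1, sd2), n_per_class))
  list(x = x, class_ids = rep(c("a", "b"), each = n_per_class),
       codes = rep(c(-1, 1), each = n_per_class))
}

# Residual sum of squares of the augmented least-squares problem.
rss_of <- function(bias, weights, x, codes) {
  sum((bias + drop(as.matrix(x) %*% weights) - codes)^2)
}

# Hand-build a zlda model from explicit score-distribution parameters,
# bypassing the fit (for rule-level tests).
manual_zlda <- function(mu1, sigma1, mu2, sigma2, coding = c(-1, 1)) {
  structure(list(
    weights = structure(list(bias = 0, weights = 1),
                        class = "augmented_weights"),
    dist1 = score_distribution(mu1, sigma1, 10L),
    dist2 = score_distribution(mu2, sigma2, 10L),
    coding = coding, classes = c("class1", "class2"), sd_denom = "n-1"),
    class = "zlda")
}

# Deterministic 2-channel trials whose channel covariance is exactly
# diagonal: orthogonal sinusoid rows scaled to the requested SDs.
make_diag_cov_trials <- function(sds_class1 = c(2, 1), sds_class2 = c(1, 2),
                                 n_samples = 64, n_per_class = 2, fs = 250) {
  t_idx <- seq_len(n_samples)
  u1 <- sqrt(2) * cos(2 * pi * 3 * t_idx / n_samples)
  u2 <- sqrt(2) * sin(2 * pi * 3 * t_idx / n_samples)
  mk <- function(sds) rbind(sds[1] * u1, sds[2] * u2)
  data <- array(0, dim = c(2 * n_per_class, 2, n_samples))
  for (i in seq_len(n_per_class)) data[i, , ] <- mk(sds_class1)
  for (i in seq_len(n_per_class)) data[n_per_class + i, , ] <- mk(sds_class2)
  trial_array(data, fs, rep(c("class1", "class2"), each = n_per_class))
}

# Channel covariance matching the estimator used by the CSP fit
# (independent small re-implementation for cross-checks).
trial_avg_cov <- function(trials, label) {
  idx <- which(trials$labels == label)
  mats <- lapply(idx, function(i) {
    x <- trials$data[i, , ]
    x <- sweep(x, 1, rowMeans(x))
    cc <- x %*% t(x) / ncol(x)
    cc / sum(diag(cc))
  })
  Reduce(`+`, mats) / length(mats)
}
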