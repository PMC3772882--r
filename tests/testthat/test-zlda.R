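test_that("score distributions use per-class mean and n-1 SD", {
  dists <- estimate_score_distributions(c(0, 2, 4, 6), c(-1, -1, 1, 1))
  expect_equal(dists[[1]]$mu, 1)
  expect_equal(dists[[1]]$sigma, sqrt(2))
  expect_equal(dists[[1]]$n, 2L)
  expect_equal(dists[[2]]$mu, 5)

  # population denominator option
  pop <- estimate_score_distributions(c(0, 2, 4, 6), c(-1, -1, 1, 1),
                                      sd_denom = "n")
  expect_equal(pop[[1]]$sigma, 1)

  expect_error(estimate_score_distributions(c(1, 1, 0, 2), c(-1, -1, 1, 1)),
               "degenerate class distribution")
  expect_error(estimate_score_distributions(c(0, 1, 2), c(-1, 1, 1)),
               "insufficient samples for SD")
})

test_that("z-scores measure distance in class-SD units", {
  d <- score_distribution(1, 0.5, 10)
  expect_equal(zscore(0.5, d), 1)
  expect_equal(zscore(1, d), 0)
  expect_equal(zscore(1 + 3 * 0.5, d), 3)
  expect_equal(zscore(c(0.5, 1.5), d), c(1, 1))  # symmetric around mu
  expect_error(zscore(1, score_distribution(0, 0, 10)),
               "degenerate class distribution")
})

test_that("z-rule assigns by the smaller z-score, including the far tail", {
  m <- manual_zlda(mu1 = -1, sigma1 = 0.3, mu2 = 1, sigma2 = 1.0)
  # near the small-SD mean: z1 = 0.333 < z2 = 1.9
  expect_equal(zlda_predict(-0.9, m), -1)
  # between the means but > 3 SDs from class 1: z1 = 3.33 > z2 = 1
  expect_equal(zlda_predict(0, m), 1)
  # outer left tail: the z-equality locus has a second crossing, so the
  # far tail on the small-SD side belongs to the large-SD class
  expect_equal(zlda_predict(-3, m), 1)
  # exact tie goes to class 1
  tie <- manual_zlda(-1, 0.5, 1, 0.5)
  expect_equal(zlda_predict(0, tie), -1)
})

test_that("closed-form boundary matches hand-evaluated cases and limits", {
  expect_equal(zlda_boundary(manual_zlda(-1, 0.4, 1, 0.4)), 0)
  expect_equal(zlda_boundary(manual_zlda(-1, 0.2, 1, 0.6)), -0.5)
  # sigma1 -> 0 pulls the boundary onto the small-SD class mean
  expect_equal(zlda_boundary(manual_zlda(-1, 1e-12, 1, 0.5)), -1,
               tolerance = 1e-9)
  expect_error(zlda_boundary(manual_zlda(-1, 0, 1, 0)
                             ), "degenerate")
})

test_that("boundary brackets the means and is monotone in the SD ratio", {
  set.seed(42)
  for (k in 1:200) {
    mu <- sort(rnorm(2, sd = 3))
    s <- runif(2, 0.05, 3)
    b <- zlda_boundary(manual_zlda(mu[1], s[1], mu[2], s[2]))
    expect_gt(b, mu[1]); expect_lt(b, mu[2])
  }
  # b increases as sigma1 grows relative to sigma2
  bs <- vapply(seq(0.1, 2, by = 0.1),
               function(s1) zlda_boundary(manual_zlda(-1, s1, 1, 1)),
               numeric(1))
  expect_true(all(diff(bs) > 0))
})

test_that("predictions are invariant under a common positive rescaling", {
  m <- manual_zlda(-1, 0.3, 1, 0.9)
  # offset grid so no point sits exactly on a z-equality crossing (ties
  # are measure-zero and their rounding is not scale-stable)
  y <- seq(-4, 4, length.out = 101) + 0.0137
  for (c_scale in c(0.2, 3, 17)) {
    ms <- manual_zlda(-c_scale, 0.3 * c_scale, c_scale, 0.9 * c_scale)
    expect_equal(zlda_predict(c_scale * y, ms), zlda_predict(y, m))
  }
})

test_that("equal class SDs reduce the z-rule to the midpoint rule", {
  set.seed(13)
  for (k in 1:20) {
    mu <- sort(rnorm(2, sd = 2))
    s <- runif(1, 0.1, 2)
    m <- manual_zlda(mu[1], s, mu[2], s)
    y <- runif(200, mu[1] - 4, mu[2] + 4)
    # midpoint rule recentred on the score means rather than the codes
    midpoint <- mean(mu)
    expect_equal(zlda_predict(y, m),
                 ifelse(y > midpoint, 1, -1))
    expect_equal(zlda_boundary(m), midpoint)
  }
})

test_that("confidence is a density ratio: symmetric at b, monotone in z1", {
  m <- manual_zlda(-1, 0.5, 1, 0.5)
  r <- classification_confidence(zlda_boundary(m), m)
  expect_equal(as.numeric(r), c(0.5, 0.5))

  # at the class-1 mean with class 2 far away, class-1 reliability wins
  far <- manual_zlda(-1, 0.2, 5, 0.2)
  expect_gt(classification_confidence(-1, far)[, 1], 0.5)

  # rows always sum to one, even for extreme z-scores
  wide <- classification_confidence(seq(-50, 50, length.out = 21), m)
  expect_equal(rowSums(wide), rep(1, 21))

  # r1 strictly decreases as z1 grows with z2 held fixed: sweep y over a
  # grid where the class-2 distribution is so wide that z2 is ~ constant
  sweep_m <- manual_zlda(0, 1, 0, 1e6)
  grid <- seq(0, 4, by = 0.25)
  r1 <- classification_confidence(grid, sweep_m)[, 1]
  expect_true(all(diff(r1) < 0))
})

test_that("fit_zlda composes fit, projection and distribution estimation", {
  fx <- make_separable_fixture(n_per_class = 30, seed = 3, sd2 = 0.9)
  m <- fit_zlda(fx$x, fx$class_ids)
  expect_s3_class(m, "zlda")
  expect_equal(m$classes, c("a", "b"))
  expect_gt(m$dist2$sigma, m$dist1$sigma)          # heteroscedastic fit
  expect_lt(zlda_boundary(m), mean(m$coding))      # shifted toward class 1

  # determinism: refit on identical data gives an identical model
  expect_identical(fit_zlda(fx$x, fx$class_ids), m)

  # training predictions available immediately and mostly correct
  acc <- mean(predict(m, fx$x) == fx$class_ids)
  expect_gt(acc, 0.95)

  expect_error(fit_zlda(fx$x, rep("a", nrow(fx$x))), "single-class input")
})

test_that("sigma floor substitutes for the degenerate-distribution error only when enabled", {
  x <- matrix(c(0, 0, 1, 2), ncol = 1)
  ids <- c("a", "a", "b", "b")
  expect_error(fit_zlda(x, ids), "degenerate class distribution")
  m <- fit_zlda(x, ids, sigma_floor = 1e-6)
  expect_equal(m$dist1$sigma, 1e-6)
  expect_equal(predict(m, matrix(c(0, 2))), c("a", "b"))
})

test_that("predict() returns classes, codes, scores and confidences consistently", {
  fx <- make_separable_fixture(n_per_class = 20, seed = 21)
  m <- fit_zlda(fx$x, fx$class_ids)
  new_x <- fx$x[c(1, 39), ]
  codes <- predict(m, new_x, type = "code")
  cls <- predict(m, new_x, type = "class")
  expect_equal(cls, ifelse(codes == -1, "a", "b"))
  conf <- predict(m, new_x, type = "confidence")
  expect_equal(dim(conf), c(2, 2))
  expect_equal(colnames(conf), c("a", "b"))
  # the predicted class carries the larger reliability
  expect_equal(colnames(conf)[apply(conf, 1, which.max)], cls)
})
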