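#' Per-class Gaussian summary of a score distribution
#'
#' @param mu class mean of the weight sums.
#' @param sigma class standard deviation of the weight sums (>= 0).
#' @param n class sample count.
#' @return object of class \code{score_distribution}.
#' @export
score_distribution <- function(mu, sigma, n) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0, n >= 1)
  structure(list(mu = mu, sigma = sigma, n = as.integer(n)),
            class = "score_distribution")
}

#' Estimate per-class Gaussian parameters of the training weight sums
#'
#' Computes the mean and standard deviation of the projected weight sums
#' within each class.  These two Gaussians summarise how the fitted
#' discriminant separates the training classes and are the sole inputs to
#' the z-score decision rule.
#'
#' @param scores numeric vector of training weight sums.
#' @param codes numeric vector of class codes, same length.
#' @param coding code pair giving class order; defaults to the
#'   \code{coding} attribute of \code{codes} or the sorted unique codes.
#' @param sd_denom \code{"n-1"} (default, sample SD) or \code{"n"}
#'   (population SD).
#' @return list of two \code{score_distribution} objects, one per class in
#'   coding order.
#' @examples
#' estimate_score_distributions(c(0, 2, 4, 6), c(-1, -1, 1, 1))
#' @export
estimate_score_distributions <- function(scores, codes, coding = NULL,
                                         sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  if (is.null(coding)) coding <- attr(codes, "coding")
  if (is.null(coding)) coding <- sort(unique(codes))
  stopifnot(length(coding) == 2, length(scores) == length(codes))
  lapply(coding, function(code) {
    y <- scores[codes == code]
    n <- length(y)
    if (n < 2L) stop("insufficient samples for SD")
    s <- stats::sd(y)
    if (sd_denom == "n") s <- s * sqrt((n - 1) / n)
    if (s == 0) stop("degenerate class distribution")
    score_distribution(mean(y), s, n)
  })
}

#' z-score of a weight sum against a class distribution
#'
#' Measures how far a weight sum lies from a class's projected mean, in
#' units of that class's projected SD: \eqn{z = |y - \mu| / \sigma}.
#'
#' @param y numeric vector of weight sums.
#' @param dist a \code{score_distribution}.
#' @return nonnegative numeric vector of z-scores.
#' @export
zscore <- function(y, dist) {
  stopifnot(inherits(dist, "score_distribution"))
  if (dist$sigma <= 0) stop("degenerate class distribution")
  abs(y - dist$mu) / dist$sigma
}

#' Fit a z-score linear discriminant (Z-LDA) model
#'
#' Fits the least-squares linear discriminant, projects the training
#' samples to weight sums, and summarises each class's weight sums by a
#' Gaussian (mean, SD).  Prediction compares the per-class z-scores of a
#' new sample's weight sum, so the effective decision boundary shifts
#' toward the class with the smaller projected SD — the behaviour that
#' makes the rule robust to heteroscedastic class distributions.
#'
#' @param x numeric feature matrix, one row per trial/sample.
#' @param class_ids per-sample class identifiers (exactly two classes).
#' @param coding numeric code pair, default \code{c(-1, 1)}.
#' @param classes optional ordered pair fixing the class-to-code mapping.
#' @param sd_denom SD denominator, \code{"n-1"} (default) or \code{"n"}.
#' @param ridge ridge penalty passed to [fit_least_squares()].
#' @param sigma_floor optional lower bound applied to the estimated class
#'   SDs.  Default 0, i.e. off: a class with zero score variance is an
#'   error rather than silently floored.
#' @return an object of class \code{zlda}: list with \code{weights}
#'   (\code{augmented_weights}), \code{dist1}, \code{dist2}
#'   (\code{score_distribution}), \code{coding}, \code{classes},
#'   \code{sd_denom}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -1, 0.3), 20), matrix(rnorm(40, 1, 0.9), 20))
#' fit <- fit_zlda(x, rep(c("left", "right"), each = 20))
#' predict(fit, x[1:3, , drop = FALSE])
#' @export
fit_zlda <- function(x, class_ids, coding = c(-1, 1), classes = NULL,
                     sd_denom = c("n-1", "n"), ridge = 0, sigma_floor = 0) {
  sd_denom <- match.arg(sd_denom)
  codes <- encode_labels(class_ids, coding = coding, classes = classes)
  w <- fit_least_squares(x, codes, ridge = ridge)
  scores <- project_scores(w, x)
  dists <- if (sigma_floor > 0) {
    floor_one <- function(code) {
      y <- scores[codes == code]
      if (length(y) < 2L) stop("insufficient samples for SD")
      s <- stats::sd(y)
      if (sd_denom == "n") s <- s * sqrt((length(y) - 1) / length(y))
      score_distribution(mean(y), max(s, sigma_floor), length(y))
    }
    lapply(coding, floor_one)
  } else {
    estimate_score_distributions(scores, codes, coding = coding,
                                 sd_denom = sd_denom)
  }
  structure(list(weights = w, dist1 = dists[[1]], dist2 = dists[[2]],
                 coding = coding, classes = attr(codes, "classes"),
                 sd_denom = sd_denom),
            class = "zlda")
}

#' Z-score decision rule
#'
#' Classifies weight sums by comparing z-scores against the two class
#' distributions: the sample is assigned to the class whose projected
#' distribution it is closer to in SD units.  Ties go to the first class.
#' Note the rule is applied literally, not as a single threshold: when the
#' SDs differ the locus \eqn{z_1 = z_2} has two crossings, and the far tail
#' on the small-SD side belongs to the large-SD class (see
#' [zlda_boundary()]).
#'
#' @param scores numeric vector of weight sums.
#' @param model a fitted \code{zlda} object.
#' @return numeric vector of predicted class codes.
#' @export
zlda_predict <- function(scores, model) {
  stopifnot(inherits(model, "zlda"))
  z1 <- zscore(scores, model$dist1)
  z2 <- zscore(scores, model$dist2)
  ifelse(z1 <= z2, model$coding[1], model$coding[2])
}

#' Closed-form heteroscedastic decision boundary
#'
#' The score value at which the two z-scores are equal between the class
#' means: \deqn{b = (\sigma_2 \mu_1 + \sigma_1 \mu_2) / (\sigma_1 +
#' \sigma_2).} It lies strictly between the class means, reduces to their
#' midpoint when the SDs are equal, and moves toward the class with the
#' smaller SD otherwise.  Exposed as a diagnostic / plotting value; the
#' operative classifier is [zlda_predict()].
#'
#' @param model a fitted \code{zlda} object, or a list with elements
#'   \code{dist1} and \code{dist2}.
#' @return the boundary score \code{b}.
#' @export
zlda_boundary <- function(model) {
  d1 <- model$dist1; d2 <- model$dist2
  if (d1$sigma + d2$sigma <= 0) stop("degenerate class distribution")
  (d2$sigma * d1$mu + d1$sigma * d2$mu) / (d1$sigma + d2$sigma)
}

#' Classification reliability from z-scores
#'
#' Converts the two z-scores of a weight sum into a pair of per-class
#' reliabilities summing to one, by normalising the standard normal
#' density at each z-score:
#' \eqn{r_i = \phi(z_i) / (\phi(z_1) + \phi(z_2))}.
#' Computed in the log domain so extreme z-scores do not underflow.
#'
#' @param y numeric vector of weight sums.
#' @param model a fitted \code{zlda} object.
#' @return numeric matrix with one row per score and columns named after
#'   the two classes; rows sum to 1.
#' @export
classification_confidence <- function(y, model) {
  stopifnot(inherits(model, "zlda"))
  z1 <- zscore(y, model$dist1)
  z2 <- zscore(y, model$dist2)
  # phi(z1)/(phi(z1)+phi(z2)) = logistic((z2^2 - z1^2)/2)
  r1 <- stats::plogis((z2^2 - z1^2) / 2)
  out <- cbind(r1, 1 - r1)
  colnames(out) <- if (!is.null(model$classes)) model$classes else
    as.character(model$coding)
  out
}

#' @export
predict.zlda <- function(object, newdata,
                         type = c("class", "code", "score", "confidence"),
                         ...) {
  type <- match.arg(type)
  scores <- project_scores(object$weights, newdata)
  switch(type,
    score = scores,
    code = zlda_predict(scores, object),
    class = {
      codes <- zlda_predict(scores, object)
      object$classes[ifelse(codes == object$coding[1], 1L, 2L)]
    },
    confidence = classification_confidence(scores, object)
  )
}

#' @export
print.zlda <- function(x, ...) {
  cat("Z-LDA model (z-score linear discriminant)\n")
  cat(sprintf("  features: %d\n", length(x$weights$weights)))
  cat(sprintf("  class %s -> code %g: mu = %.4g, sigma = %.4g (n = %d)\n",
              x$classes[1], x$coding[1], x$dist1$mu, x$dist1$sigma, x$dist1$n))
  cat(sprintf("  class %s -> code %g: mu = %.4g, sigma = %.4g (n = %d)\n",
              x$classes[2], x$coding[2], x$dist2$mu, x$dist2$sigma, x$dist2$n))
  cat(sprintf("  boundary b = %.4g (label midpoint %.4g)\n",
              zlda_boundary(x), mean(x$coding)))
  invisible(x)
}
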