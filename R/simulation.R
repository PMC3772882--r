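#' Configuration for the two-Gaussian simulation study
#'
#' Defaults reproduce the study conditions of the heteroscedastic
#' comparison: class 1 is a bivariate Gaussian with mean (-1, -0.6) and
#' per-dimension SD 0.3; class 2 has mean (1, 0.6) and per-dimension SD
#' 0.3 + \code{sd_delta}; 100 training and 100 test samples per class.
#'
#' @param mean1,mean2 class mean vectors (any common dimension; default 2-D).
#' @param sd1 class-1 per-dimension SD vector.
#' @param sd_delta nonnegative increment added to every component of the
#'   class-2 SD (class-2 SD = \code{sd1 + sd_delta}); the norm of the
#'   SD-difference vector is then \code{sd_delta * sqrt(length(sd1))}.
#' @param n_per_class_train,n_per_class_test samples per class.
#' @param n_reps Monte-Carlo repetitions for [run_study()].
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(mean1 = c(-1, -0.6), mean2 = c(1, 0.6),
                       sd1 = c(0.3, 0.3), sd_delta = 0,
                       n_per_class_train = 100, n_per_class_test = 100,
                       n_reps = 100) {
  stopifnot(length(mean1) == length(mean2), length(sd1) == length(mean1),
            all(sd1 > 0), sd_delta >= 0,
            n_per_class_train >= 1, n_per_class_test >= 1, n_reps >= 1)
  structure(list(mean1 = mean1, mean2 = mean2, sd1 = sd1,
                 sd2 = sd1 + sd_delta, sd_delta = sd_delta,
                 n_per_class_train = as.integer(n_per_class_train),
                 n_per_class_test = as.integer(n_per_class_test),
                 n_reps = as.integer(n_reps)),
            class = "sim_config")
}

#' Draw one two-class Gaussian dataset
#'
#' Each class is sampled with independent per-dimension Gaussians at the
#' configured means and SDs.
#'
#' @param cfg a [sim_config()].
#' @param n_per_class samples per class (defaults to the training size).
#' @param seed optional integer; if given, the RNG is seeded first.
#'   Leave \code{NULL} to draw from the current RNG stream.
#' @return list with \code{x} (numeric matrix, class-1 rows first) and
#'   \code{class_ids} (character, \code{"class1"} / \code{"class2"}).
#' @export
generate_gaussian_2class <- function(cfg, n_per_class = cfg$n_per_class_train,
                                     seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n_per_class >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- length(cfg$mean1)
  draw <- function(mu, sd) {
    vapply(seq_len(d),
           function(j) stats::rnorm(n_per_class, mu[j], sd[j]),
           numeric(n_per_class))
  }
  x <- rbind(draw(cfg$mean1, cfg$sd1), draw(cfg$mean2, cfg$sd2))
  list(x = x, class_ids = rep(c("class1", "class2"), each = n_per_class))
}

#' One train/test repetition of the LDA vs. Z-LDA comparison
#'
#' Generates fresh training and test sets, fits the least-squares
#' discriminant once, classifies the test set with both the conventional
#' midpoint rule and the z-score rule, and returns the two test accuracies
#' in percent.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed making the repetition reproducible in
#'   isolation.
#' @return named numeric vector \code{c(lda = , zlda = )}, accuracies in
#'   percent.
#' @export
run_single_repetition <- function(cfg, seed) {
  set.seed(seed)
  train <- generate_gaussian_2class(cfg, cfg$n_per_class_train)
  test <- generate_gaussian_2class(cfg, cfg$n_per_class_test)
  model <- fit_zlda(train$x, train$class_ids)
  truth <- encode_labels(test$class_ids, coding = model$coding,
                         classes = model$classes)
  scores <- project_scores(model$weights, test$x)
  acc <- function(pred) 100 * mean(pred == truth)
  c(lda = acc(lda_predict(scores, model$coding)),
    zlda = acc(zlda_predict(scores, model)))
}

#' Paired t-test between two accuracy vectors
#'
#' Two-sided paired t-test on the per-repetition differences
#' (\code{df = n - 1}).
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @return list with \code{t}, \code{p} and \code{df}.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need two vectors of equal length >= 2")
  d <- a - b
  if (stats::sd(d) == 0) stop("degenerate t")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Monte-Carlo accuracy study over heteroscedasticity levels
#'
#' For each SD-increment level, runs \code{cfg$n_reps} independent
#' train/test repetitions of [run_single_repetition()], and reports the
#' mean and SD over repetitions of each classifier's test accuracy plus a
#' paired t-test between the two accuracy vectors.  Per-repetition seeds
#' are drawn once from the master seed, so the whole study is
#' deterministic and any single repetition can be replayed from its seed.
#'
#' @param cfg a [sim_config()]; \code{cfg$sd_delta} is overridden by each
#'   level in turn.
#' @param levels numeric vector of SD increments (default 0 to 0.9 by 0.1).
#' @param seed master seed.
#' @return data frame of class \code{study_table} with columns
#'   \code{level}, \code{lda_mean}, \code{lda_sd}, \code{zlda_mean},
#'   \code{zlda_sd}, \code{t}, \code{p}.  The t-test columns are \code{NA}
#'   when the accuracy differences are all zero (degenerate t).
#' @examples
#' run_study(sim_config(n_reps = 3), levels = c(0, 0.5), seed = 1)
#' @export
run_study <- function(cfg = sim_config(), levels = seq(0, 0.9, by = 0.1),
                      seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), length(levels) >= 1)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max,
                                 cfg$n_reps * length(levels)),
                      nrow = cfg$n_reps)
  rows <- lapply(seq_along(levels), function(i) {
    lv_cfg <- sim_config(mean1 = cfg$mean1, mean2 = cfg$mean2, sd1 = cfg$sd1,
                         sd_delta = levels[i],
                         n_per_class_train = cfg$n_per_class_train,
                         n_per_class_test = cfg$n_per_class_test,
                         n_reps = cfg$n_reps)
    acc <- vapply(seq_len(cfg$n_reps),
                  function(r) run_single_repetition(lv_cfg, rep_seeds[r, i]),
                  numeric(2))
    tt <- tryCatch(paired_t_test(acc["zlda", ], acc["lda", ]),
                   error = function(e) list(t = NA_real_, p = NA_real_))
    data.frame(level = levels[i],
               lda_mean = mean(acc["lda", ]), lda_sd = stats::sd(acc["lda", ]),
               zlda_mean = mean(acc["zlda", ]),
               zlda_sd = stats::sd(acc["zlda", ]),
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "n_reps") <- cfg$n_reps
  class(out) <- c("study_table", "data.frame")
  out
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("Accuracy study: %d repetitions per level (master seed %s)\n",
              attr(x, "n_reps"), attr(x, "seed")))
  df <- data.frame(
    level = sprintf("%.1f", x$level),
    LDA = sprintf("%.2f±%.2f", x$lda_mean, x$lda_sd),
    `Z-LDA` = sprintf("%.2f±%.2f", x$zlda_mean, x$zlda_sd),
    p = ifelse(is.na(x$p), "-", sprintf("%.3g", x$p)),
    check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
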