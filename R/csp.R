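#' Multichannel EEG trial container
#'
#' @param data numeric 3-D array, trials x channels x samples, in
#'   microvolts.
#' @param fs sampling rate in Hz.
#' @param labels per-trial class identifiers.
#' @return object of class \code{trial_array}.
#' @export
trial_array <- function(data, fs, labels) {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  if (dim(data)[2] < 2L) stop("need at least 2 channels")
  if (length(labels) != dim(data)[1]) stop("one label per trial required")
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "trial_array")
}

#' @export
print.trial_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trial_array: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  print(table(x$labels))
  invisible(x)
}

#' Amplitude-based artifact rejection
#'
#' Removes trials whose maximum absolute amplitude exceeds the threshold
#' (default 300 microvolts), the conventional screen for strong ocular
#' artifacts.  Trial order is preserved.
#'
#' @param trials a [trial_array()].
#' @param threshold rejection threshold in microvolts (> 0).
#' @return a \code{trial_array} containing the surviving trials.
#' @export
reject_artifacts <- function(trials, threshold = 300) {
  stopifnot(inherits(trials, "trial_array"), threshold > 0)
  peak <- apply(abs(trials$data), 1, max)
  keep <- peak <= threshold
  if (!any(keep)) stop("no trials survive rejection")
  trial_array(trials$data[keep, , , drop = FALSE], trials$fs,
              trials$labels[keep])
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase) to every channel of every trial, so the variance features
#' downstream are not distorted by filter latency.
#'
#' @param trials a [trial_array()].
#' @param band numeric pair \code{c(lo, hi)} in Hz; must satisfy
#'   \code{0 < lo < hi < fs/2}.
#' @param order filter order (default 4).
#' @return the filtered \code{trial_array}.
#' @export
bandpass_filter <- function(trials, band = c(8, 30), order = 4) {
  stopifnot(inherits(trials, "trial_array"), length(band) == 2)
  nyq <- trials$fs / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq))
    stop("band outside Nyquist range")
  bf <- signal::butter(order, band / nyq, type = "pass")
  d <- trials$data
  for (i in seq_len(dim(d)[1]))
    for (ch in seq_len(dim(d)[2]))
      d[i, ch, ] <- signal::filtfilt(bf, d[i, ch, ])
  trial_array(d, trials$fs, trials$labels)
}

# Average trace-normalized channel covariance of one class.
class_covariance <- function(data, idx) {
  covs <- lapply(idx, function(i) {
    x <- data[i, , ]
    x <- x - rowMeans(x)
    c0 <- tcrossprod(x) / ncol(x)
    c0 / sum(diag(c0))
  })
  Reduce(`+`, covs) / length(covs)
}

#' Fit common spatial patterns (CSP)
#'
#' Estimates spatial filters that jointly diagonalize the two average
#' trace-normalized class covariance matrices: each filter maximizes the
#' projected variance under one class while minimizing it under the
#' other.  Eigenvalue k is the class-1 fraction of the projected variance
#' of filter k (the class-2 fraction is its complement), sorted
#' descending, so the most class-1-discriminative filters come first and
#' the most class-2-discriminative last.
#'
#' @param trials a [trial_array()] with exactly two classes.
#' @param shrinkage scalar in \[0, 1\]: shrinkage of each class covariance
#'   toward a scaled identity, for rank-deficient data.  Default 0.
#' @param classes optional ordered pair fixing which label is class 1.
#' @return object of class \code{csp}: \code{filters} (channels x
#'   channels, rows are spatial filters), \code{eigenvalues} (descending,
#'   in \[0, 1\]), \code{classes}.
#' @export
fit_csp <- function(trials, shrinkage = 0, classes = NULL) {
  stopifnot(inherits(trials, "trial_array"), shrinkage >= 0, shrinkage <= 1)
  if (is.null(classes)) classes <- sort(unique(trials$labels))
  if (length(classes) != 2 || !all(trials$labels %in% classes))
    stop("not binary")
  n_ch <- dim(trials$data)[2]
  shrink <- function(cc) {
    if (shrinkage == 0) return(cc)
    (1 - shrinkage) * cc + shrinkage * mean(diag(cc)) * diag(n_ch)
  }
  c1 <- shrink(class_covariance(trials$data, which(trials$labels == classes[1])))
  c2 <- shrink(class_covariance(trials$data, which(trials$labels == classes[2])))
  comp <- c1 + c2
  ec <- eigen(comp, symmetric = TRUE)
  if (min(ec$values) <= max(ec$values) * 1e-10)
    stop("singular covariance (enable shrinkage)")
  whiten <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  es <- eigen(whiten %*% c1 %*% t(whiten), symmetric = TRUE)
  filters <- t(es$vectors) %*% whiten   # rows: filters, eigenvalues descending
  rownames(filters) <- NULL
  structure(list(filters = filters,
                 eigenvalues = pmin(pmax(es$values, 0), 1),
                 classes = classes),
            class = "csp")
}

#' @export
print.csp <- function(x, ...) {
  cat(sprintf("CSP filter bank: %d filters (classes %s vs %s)\n",
              nrow(x$filters), x$classes[1], x$classes[2]))
  cat("eigenvalues:", sprintf("%.3f", x$eigenvalues), "\n")
  invisible(x)
}

#' Select the most discriminative CSP filter pairs
#'
#' Takes the \code{n_pairs} filters with the largest eigenvalues and the
#' \code{n_pairs} with the smallest — the extremes of the spectrum,
#' equivalently the largest \code{|eigenvalue - 0.5|} on each side.
#'
#' @param bank a \code{csp} object from [fit_csp()].
#' @param n_pairs number of pairs (default 3, giving 6 filters).
#' @return matrix of selected filters (rows), with the retained
#'   eigenvalues as attribute \code{eigenvalues}.
#' @export
select_filter_pairs <- function(bank, n_pairs = 3) {
  stopifnot(inherits(bank, "csp"), n_pairs >= 1)
  n <- nrow(bank$filters)
  if (2 * n_pairs > n) stop("n_pairs too large for channel count")
  idx <- c(seq_len(n_pairs), seq(n - n_pairs + 1, n))
  out <- bank$filters[idx, , drop = FALSE]
  attr(out, "eigenvalues") <- bank$eigenvalues[idx]
  out
}

#' Log-variance features of spatially filtered trials
#'
#' Projects every trial through each spatial filter and takes the
#' logarithm of the variance of the resulting surrogate-channel signal —
#' the standard band-power feature of motor-imagery pipelines.
#'
#' @param trials a [trial_array()].
#' @param filters matrix of spatial filters (rows), e.g. from
#'   [select_filter_pairs()].
#' @return numeric matrix, trials x filters.
#' @export
log_variance_features <- function(trials, filters) {
  stopifnot(inherits(trials, "trial_array"))
  filters <- as.matrix(filters)
  if (ncol(filters) != dim(trials$data)[2]) stop("feature dimension mismatch")
  n_s <- dim(trials$data)[3]
  feats <- t(vapply(seq_len(dim(trials$data)[1]), function(i) {
    y <- filters %*% trials$data[i, , ]
    v <- rowMeans((y - rowMeans(y))^2)   # population variance
    if (any(v <= 0)) stop("log of zero variance")
    log(v)
  }, numeric(nrow(filters))))
  if (nrow(filters) == 1L) feats <- matrix(feats, ncol = 1L)
  feats
}

#' Configuration for the synthetic EEG trial generator
#'
#' Describes latent-source trials: a small set of discriminative sources
#' whose variance depends on the class (emulating lateralized
#' event-related desynchronization of sensorimotor rhythms), plus
#' background sources of equal variance in both classes, mixed into the
#' channels through a fixed random mixing matrix with additive sensor
#' noise.
#'
#' @param n_channels number of channels (default 15, a sensorimotor
#'   montage).
#' @param n_samples samples per trial (default 500, i.e. 2 s at 250 Hz).
#' @param n_trials_per_class trials per class (default 50).
#' @param fs sampling rate in Hz (default 250).
#' @param var_class1,var_class2 variances of the discriminative sources
#'   under class 1 and class 2 (same length; default \code{c(4, 1)} vs.
#'   \code{c(1, 4)}, a 4:1 power ratio in each direction).
#' @param n_background number of non-discriminative unit-variance sources
#'   (default \code{n_channels - length(var_class1)}).
#' @param noise_sd sensor noise SD in source units (default 0.25, small
#'   relative to the unit background sources, emulating a good-SNR lab
#'   recording in which the configured variance ratio is identifiable).
#' @param amplitude microvolt scale applied to the mixed signals
#'   (default 10).
#' @param mixing_seed seed fixing the mixing matrix across datasets.
#' @return object of class \code{synth_eeg_config}.
#' @export
synth_eeg_config <- function(n_channels = 15, n_samples = 500,
                             n_trials_per_class = 50, fs = 250,
                             var_class1 = c(4, 1), var_class2 = c(1, 4),
                             n_background = n_channels - length(var_class1),
                             noise_sd = 0.25, amplitude = 10,
                             mixing_seed = 42) {
  stopifnot(length(var_class1) == length(var_class2),
            all(var_class1 > 0), all(var_class2 > 0),
            n_channels >= 2, n_samples >= 2, n_trials_per_class >= 2,
            fs > 0, n_background >= 0, noise_sd >= 0, amplitude > 0)
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_trials_per_class = as.integer(n_trials_per_class),
                 fs = fs, var_class1 = var_class1, var_class2 = var_class2,
                 n_background = as.integer(n_background),
                 noise_sd = noise_sd, amplitude = amplitude,
                 mixing_seed = as.integer(mixing_seed)),
            class = "synth_eeg_config")
}

#' Generate synthetic multichannel EEG trials
#'
#' Latent Gaussian sources with class-dependent variances are mixed
#' through a fixed random mixing matrix (determined by
#' \code{cfg$mixing_seed}) and sensor noise is added; everything is
#' deterministic given \code{seed}.
#'
#' @param cfg a [synth_eeg_config()].
#' @param seed integer seed for the trial noise (the mixing matrix uses
#'   \code{cfg$mixing_seed} so train and test sets share it).
#' @return a [trial_array()] with labels \code{"class1"} / \code{"class2"},
#'   class-1 trials first.
#' @export
generate_synthetic_trials <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synth_eeg_config"))
  n_src <- length(cfg$var_class1) + cfg$n_background
  set.seed(cfg$mixing_seed)
  mixing <- matrix(stats::rnorm(cfg$n_channels * n_src), cfg$n_channels,
                   n_src) / sqrt(cfg$n_channels)
  set.seed(seed)
  n_tr <- 2L * cfg$n_trials_per_class
  data <- array(0, dim = c(n_tr, cfg$n_channels, cfg$n_samples))
  src_var <- rbind(c(cfg$var_class1, rep(1, cfg$n_background)),
                   c(cfg$var_class2, rep(1, cfg$n_background)))
  labels <- rep(c("class1", "class2"), each = cfg$n_trials_per_class)
  for (i in seq_len(n_tr)) {
    v <- src_var[if (labels[i] == "class1") 1L else 2L, ]
    s <- matrix(stats::rnorm(n_src * cfg$n_samples), n_src) * sqrt(v)
    x <- mixing %*% s
    if (cfg$noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = cfg$noise_sd), nrow(x))
    data[i, , ] <- cfg$amplitude * x
  }
  trial_array(data, cfg$fs, labels)
}
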