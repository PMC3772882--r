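#' Encode binary class labels as numeric codes
#'
#' Maps a vector of class identifiers (two distinct values) onto a numeric
#' code pair, by default \code{-1} for the first class and \code{+1} for the
#' second.  The first class is the first element of \code{classes}, which
#' defaults to the sorted unique values of \code{class_ids}.
#'
#' @param class_ids vector (character, factor or otherwise coercible) of
#'   per-sample class identifiers; exactly two distinct values must occur.
#' @param coding numeric pair \code{c(code1, code2)}; defaults to
#'   \code{c(-1, 1)}.
#' @param classes optional ordered pair naming which identifier maps to
#'   \code{coding[1]} and which to \code{coding[2]}.
#' @return numeric vector of codes with attributes \code{classes} and
#'   \code{coding}.
#' @examples
#' encode_labels(c("A", "B", "A"))
#' @export
encode_labels <- function(class_ids, coding = c(-1, 1), classes = NULL) {
  stopifnot(length(coding) == 2, is.numeric(coding))
  if (coding[1] == coding[2]) stop("label codes must be distinct")
  ids <- as.character(class_ids)
  present <- unique(ids)
  if (length(present) > 2) stop("not binary")
  if (length(present) < 2) stop("single-class input")
  if (is.null(classes)) {
    classes <- sort(present)
  } else {
    classes <- as.character(classes)
    if (length(classes) != 2 || !all(present %in% classes)) stop("not binary")
  }
  codes <- ifelse(ids == classes[1], coding[1], coding[2])
  structure(codes, classes = classes, coding = coding)
}

#' Fit the least-squares linear discriminant
#'
#' Solves the augmented least-squares problem: a dummy input 1 is prepended
#' to every sample and the weight vector minimising the squared error
#' between the linear outputs and the numeric class codes is returned.
#' With the default \code{+/-1} coding this is the classical least-squares
#' derivation of the binary linear discriminant.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param codes numeric vector of class codes (see [encode_labels()]).
#' @param ridge nonnegative ridge penalty added to the normal matrix
#'   diagonal for numerical stability; default 0.
#' @param pseudo_inverse if \code{TRUE} (default) a rank-deficient normal
#'   matrix falls back to the minimum-norm pseudo-inverse solution;
#'   if \code{FALSE} it is an error.
#' @return an object of class \code{augmented_weights}: list with
#'   \code{bias} (scalar) and \code{weights} (length-d vector).
#' @examples
#' w <- fit_least_squares(matrix(c(-1, 1)), c(-1, 1))
#' w$bias     # 0
#' w$weights  # 1
#' @export
fit_least_squares <- function(x, codes, ridge = 0, pseudo_inverse = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 1L) stop("need at least 2 samples and 1 feature")
  if (!all(is.finite(x))) stop("non-finite values in feature matrix")
  if (length(codes) != nrow(x)) stop("length of codes must match rows of x")
  if (length(unique(codes)) < 2L) stop("single-class input")
  stopifnot(ridge >= 0)
  a <- cbind(1, x)
  g <- crossprod(a)
  if (ridge > 0) g <- g + diag(ridge, ncol(g))
  w <- tryCatch(
    solve(g, crossprod(a, codes)),
    error = function(e) {
      if (!pseudo_inverse) stop("rank-deficient design", call. = FALSE)
      MASS::ginv(a) %*% codes
    }
  )
  w <- drop(w)
  structure(list(bias = w[1], weights = unname(w[-1])),
            class = "augmented_weights")
}

#' Project samples to scalar weight sums
#'
#' Evaluates the fitted linear discriminant \eqn{y = w_0 + w \cdot x} for
#' every row of \code{x}.
#'
#' @param w an \code{augmented_weights} object from [fit_least_squares()].
#' @param x numeric matrix or vector of samples (features in columns).
#' @return numeric vector of weight sums, one per sample.
#' @export
project_scores <- function(w, x) {
  stopifnot(inherits(w, "augmented_weights"))
  x <- as.matrix(x)
  if (ncol(x) != length(w$weights)) stop("feature dimension mismatch")
  drop(x %*% w$weights) + w$bias
}

#' Conventional LDA decision rule
#'
#' Classifies weight sums against the midpoint of the two label codes
#' (0 for the default \code{+/-1} coding): scores above the midpoint take
#' the second code, scores below take the first.  Exact ties go to the
#' first class (deterministic convention).
#'
#' @param scores numeric vector of weight sums.
#' @param coding numeric code pair; default \code{c(-1, 1)}.
#' @return numeric vector of predicted codes.
#' @export
lda_predict <- function(scores, coding = c(-1, 1)) {
  stopifnot(all(is.finite(scores)), length(coding) == 2)
  threshold <- mean(coding)
  ifelse(scores > threshold, coding[2], coding[1])
}
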