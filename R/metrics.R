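# Performance measures for multiclass classification: per-class accuracy,
# overall accuracy, and the multiclass Matthews correlation coefficient in
# its covariance form over one-hot label matrices.

#' One-hot encode class labels
#'
#' @param labels a factor, or an integer vector with values in `1..C`.
#' @param C number of classes; defaults to `nlevels(labels)` for factors.
#' @return an `n x C` 0/1 matrix with a single 1 per row.
#' @export
one_hot <- function(labels, C = NULL) {
  if (is.factor(labels)) {
    C <- C %||% nlevels(labels)
    idx <- as.integer(labels)
  } else {
    idx <- as.integer(labels)
    C <- C %||% max(idx)
  }
  if (anyNA(idx) || any(idx < 1L) || any(idx > C))
    stop("labels must lie in 1..C", call. = FALSE)
  m <- matrix(0L, nrow = length(idx), ncol = C)
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Multiclass Matthews correlation coefficient
#'
#' The correlation between the one-hot predicted-label matrix `X` and the
#' one-hot actual-label matrix `Y`:
#' \deqn{MCC = \frac{\sum_{ij}(x_{ij}-\bar x_j)(y_{ij}-\bar y_j)}
#'   {\sqrt{\sum_{ij}(x_{ij}-\bar x_j)^2 \sum_{ij}(y_{ij}-\bar y_j)^2}}}
#' with column means taken over all n rows. For two classes this is
#' algebraically identical to the classical binary MCC. When either variance
#' term is zero (e.g. a constant prediction) the value is defined as 0, with
#' a warning.
#'
#' @param X n x C 0/1 matrix of predicted labels (one 1 per row).
#' @param Y n x C 0/1 matrix of actual labels, same shape.
#' @return a number in `[-1, 1]`.
#' @export
multiclass_mcc <- function(X, Y) {
  if (!is.matrix(X) || !is.matrix(Y) || !all(dim(X) == dim(Y)))
    stop("X and Y must be matrices of identical dimensions", call. = FALSE)
  if (any(rowSums(X) != 1) || any(rowSums(Y) != 1) ||
      !all(X %in% c(0, 1)) || !all(Y %in% c(0, 1)))
    stop("X and Y must be one-hot indicator matrices (rows sum to 1)",
         call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  den <- sqrt(sum(Xc^2) * sum(Yc^2))
  if (den == 0) {
    warning("zero variance in predicted or actual labels; MCC defined as 0")
    return(0)
  }
  sum(Xc * Yc) / den
}

#' MCC from label vectors
#'
#' Convenience wrapper: one-hot encodes predicted and actual labels (over
#' the union of factor levels) and calls [multiclass_mcc()].
#'
#' @param predicted,actual factors (same levels) or integer vectors in 1..C.
#' @param C number of classes (optional for factors).
#' @return a number in `[-1, 1]`.
#' @export
mcc_score <- function(predicted, actual, C = NULL) {
  if (is.factor(actual) && is.factor(predicted)) {
    stopifnot(identical(levels(predicted), levels(actual)))
    C <- C %||% nlevels(actual)
  }
  multiclass_mcc(one_hot(predicted, C), one_hot(actual, C))
}

#' Per-class and overall accuracy
#'
#' `per_class_accuracy` returns \eqn{n_i / N_i} per class; `overall_accuracy`
#' returns \eqn{\sum_i n_i / \sum_i N_i}, the pooled fraction of correctly
#' predicted samples.
#'
#' @param n_correct per-class counts of correctly predicted samples.
#' @param N per-class sample counts (all positive for `per_class_accuracy`).
#' @return a vector of per-class accuracies, or a single pooled accuracy.
#' @export
per_class_accuracy <- function(n_correct, N) {
  if (length(n_correct) != length(N))
    stop("n_correct and N must have equal length", call. = FALSE)
  if (any(N == 0)) stop("class with zero samples: accuracy undefined",
                        call. = FALSE)
  if (any(n_correct < 0) || any(n_correct > N))
    stop("n_correct must lie in [0, N] per class", call. = FALSE)
  as.numeric(n_correct) / as.numeric(N)
}

#' @rdname per_class_accuracy
#' @export
overall_accuracy <- function(n_correct, N) {
  if (sum(N) <= 0) stop("no samples", call. = FALSE)
  sum(n_correct) / sum(N)
}

# Per-class (N, n_correct) counts from prediction/actual factors.
class_counts <- function(predicted, actual) {
  stopifnot(is.factor(predicted), is.factor(actual),
            identical(levels(predicted), levels(actual)))
  N <- tabulate(actual, nbins = nlevels(actual))
  ok <- predicted == actual
  n_correct <- vapply(seq_len(nlevels(actual)),
                      function(c) sum(ok & as.integer(actual) == c), integer(1))
  list(N = stats::setNames(N, levels(actual)),
       n_correct = stats::setNames(n_correct, levels(actual)))
}
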