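# Stratified cross-validation folds and SMOTE oversampling, the resampling
# machinery used inside IFS evaluation.

#' Stratified K-fold assignment
#'
#' Partitions samples into K folds preserving class proportions: within each
#' class the per-fold counts differ by at most one. Classes smaller than K
#' are spread over as many folds as they have samples.
#'
#' @param labels factor of class labels.
#' @param K number of folds (>= 2).
#' @param seed integer RNG seed; the assignment is deterministic given it.
#' @return an object of class `fold_assignment`: list with `fold_of`
#'   (per-sample fold index in `1..K`) and `K`.
#' @export
stratified_folds <- function(labels, K, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (!is.numeric(K) || length(K) != 1L || K < 2L || K != round(K))
    stop("K must be an integer >= 2", call. = FALSE)
  K <- as.integer(K)
  if (K > n) stop("K exceeds the number of samples", call. = FALSE)
  fold_of <- integer(n)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(K), length(idx))
    }
  })
  structure(list(fold_of = fold_of, K = K), class = "fold_assignment")
}

#' SMOTE class balancing
#'
#' Oversamples every minority class up to the majority-class count by linear
#' interpolation: each synthetic sample is `x + u * (z - x)` with
#' `u ~ Uniform(0, 1)`, `x` a randomly chosen real minority sample and `z`
#' one of its `k_neighbors` nearest same-class neighbors (Euclidean
#' distance in the supplied feature space). Original rows are preserved
#' verbatim and come first in the output.
#'
#' @param values numeric matrix, samples as rows (the feature space in which
#'   neighbors are found — typically the feature subset under evaluation).
#' @param labels factor of class labels.
#' @param k_neighbors number of nearest neighbors to draw from (default 5);
#'   capped at class size minus one.
#' @param seed integer RNG seed.
#' @return list with `values` (original rows then synthetic rows) and
#'   `labels` (factor, same levels).
#' @export
smote_balance <- function(values, labels, k_neighbors = 5L, seed = 1L) {
  stopifnot(is.matrix(values), is.numeric(values))
  labels <- as.factor(labels)
  if (length(labels) != nrow(values))
    stop("length(labels) must equal nrow(values)", call. = FALSE)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1", call. = FALSE)
  counts <- table(droplevels(labels))
  maj <- max(counts)
  deficits <- maj - counts
  if (all(deficits == 0L)) return(list(values = values, labels = labels))

  new_rows <- list()
  new_labs <- character(0)
  with_seed(seed, {
    for (cl in names(counts)[deficits > 0]) {
      n_c <- counts[[cl]]
      if (n_c < 2L)
        stop(sprintf("class '%s' has a single sample: no neighbor exists for SMOTE",
                     cl), call. = FALSE)
      n_new <- maj - n_c
      k <- min(k_neighbors, n_c - 1L)
      Xc <- values[labels == cl, , drop = FALSE]
      d <- as.matrix(stats::dist(Xc))
      diag(d) <- Inf
      # n_c x k matrix of nearest-neighbor row indices
      nn <- matrix(0L, nrow = n_c, ncol = k)
      for (i in seq_len(n_c)) nn[i, ] <- order(d[i, ])[seq_len(k)]
      base <- sample.int(n_c, n_new, replace = TRUE)
      pick <- sample.int(k, n_new, replace = TRUE)
      nb <- nn[cbind(base, pick)]
      u <- stats::runif(n_new)
      synth <- Xc[base, , drop = FALSE] +
        u * (Xc[nb, , drop = FALSE] - Xc[base, , drop = FALSE])
      rownames(synth) <- sprintf("synth_%s_%04d", cl, seq_len(n_new))
      new_rows[[cl]] <- synth
      new_labs <- c(new_labs, rep(cl, n_new))
    }
  })
  synth_all <- do.call(rbind, new_rows)
  out <- rbind(values, synth_all)
  # rbind coerces absent rownames to ""; restore the originals verbatim
  if (is.null(rownames(values))) rownames(out) <- NULL
  else rownames(out) <- c(rownames(values), rownames(synth_all))
  list(values = out,
       labels = factor(c(as.character(labels), new_labs),
                       levels = levels(labels)))
}
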