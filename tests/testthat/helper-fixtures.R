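# Shared fixture builders and independent oracles. The oracles are written
# from the definitions (joint histograms, the classical binary MCC formula,
# exhaustive greedy search) and never call the implementation paths they
# check.

# small labeled dataset straight from a matrix
make_dataset <- function(values, labels, scale = "log2") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("G%03d", seq_len(ncol(values)))
  expression_dataset(values, labels, scale = scale)
}

# oracle MI: direct sum over the joint table, in bits
oracle_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (pj[i, j] > 0) s <- s + pj[i, j] * log2(pj[i, j] / (pa[i] * pb[j]))
  as.numeric(s)
}

# oracle classical binary MCC from a 2x2 confusion matrix (TP FN / FP TN)
oracle_binary_mcc <- function(tp, fn, fp, tn) {
  num <- tp * tn - fp * fn
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  num / den
}

# oracle greedy mRMR: exhaustive criterion evaluation at every step over
# 0-based integer code matrices; first argmax wins ties
oracle_mrmr <- function(codes, ycodes, n_bins_x, n_bins_y, criterion) {
  p <- ncol(codes)
  mi_pair <- function(a, Ba, b, Bb) oracle_mi(factor(a, levels = 0:(Ba - 1)),
                                              factor(b, levels = 0:(Bb - 1)))
  rel <- vapply(seq_len(p),
                function(j) mi_pair(codes[, j], n_bins_x, ycodes, n_bins_y),
                numeric(1))
  selected <- integer(0)
  for (step in seq_len(p)) {
    best <- -Inf; pick <- NA_integer_
    for (j in seq_len(p)) {
      if (j %in% selected) next
      if (length(selected) == 0L) {
        sc <- rel[j]
      } else {
        red <- mean(vapply(selected, function(s)
          mi_pair(codes[, j], n_bins_x, codes[, s], n_bins_x), numeric(1)))
        sc <- if (criterion == "MID") rel[j] - red
              else rel[j] / max(red, .Machine$double.eps)
      }
      if (sc > best) { best <- sc; pick <- j }
    }
    selected <- c(selected, pick)
  }
  selected
}

# random tree-training problem for fidelity fuzzing
random_tree_problem <- function(n = 40, m = 5, C = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), nrow = n,
              dimnames = list(NULL, sprintf("g%02d", seq_len(m))))
  y <- factor(sample(LETTERS[seq_len(C)], n, replace = TRUE))
  list(x = x, y = y)
}
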