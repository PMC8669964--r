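# Shadow-feature relevance filtering (Boruta). Each iteration appends a
# permuted "shadow" copy of every undecided feature, scores the augmented
# matrix with a random forest, counts a hit for every feature whose
# importance beats the best shadow, and decides feature status with an
# exact binomial test against the coin-flip null.

#' Append shadow features to a matrix
#'
#' Returns `cbind(values, shadows)` where each shadow column is an
#' independently permuted copy of the corresponding original column; by
#' construction a shadow preserves its source's marginal distribution while
#' destroying any association with the labels. Uses the current RNG state.
#'
#' @param values numeric matrix, n x m, with `n >= 2`.
#' @return an n x 2m matrix; shadow columns are named `shadow_<original>`.
#' @export
make_shadow_features <- function(values) {
  if (!is.matrix(values) || nrow(values) < 2L || ncol(values) < 1L)
    stop("'values' must be a matrix with at least 2 rows and 1 column",
         call. = FALSE)
  shadows <- apply(values, 2L, sample)
  colnames(shadows) <- paste0("shadow_", colnames(values))
  cbind(values, shadows)
}

#' Decide feature status from shadow-beating hit counts
#'
#' Exact two-sided binomial test of `hits` successes in `trials` iterations
#' against p = 0.5 (a feature no better than noise beats the best shadow
#' with probability at most 1/2). The upper tail confirms, the lower tail
#' rejects; both p-values are Bonferroni-corrected by `n_features`.
#'
#' @param hits number of iterations the feature beat the best shadow.
#' @param trials number of iterations the feature was undecided.
#' @param alpha significance level in (0, 1).
#' @param n_features Bonferroni correction factor (number of features tested
#'   simultaneously).
#' @return `"confirmed"`, `"rejected"`, or `"tentative"` (vectorized over
#'   `hits`).
#' @export
binomial_decision <- function(hits, trials, alpha = 0.05, n_features = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  stopifnot(trials >= 1L, all(hits >= 0L), all(hits <= trials),
            n_features >= 1L)
  p_up <- stats::pbinom(hits - 1L, trials, 0.5, lower.tail = FALSE)
  p_lo <- stats::pbinom(hits, trials, 0.5)
  status <- rep("tentative", length(hits))
  status[pmin(1, p_up * n_features) < alpha] <- "confirmed"
  status[pmin(1, p_lo * n_features) < alpha] <- "rejected"
  status
}

#' Run the Boruta relevance filter
#'
#' Iterates the shadow procedure until every feature is confirmed or
#' rejected, or `max_iter` is reached. The retained set is the confirmed
#' features; features still tentative at `max_iter` are reported as such
#' (they are not retained), matching the reference implementation's
#' semantics. With `rough_fix = TRUE` leftover tentatives are instead
#' resolved by the median "rough fix": confirmed if the median of their
#' importance history exceeds the median of the per-iteration maximum
#' shadow importances, rejected otherwise. On permutation-null data the
#' rough fix flips lingering chance-correlated features to confirmed about
#' half the time, which is why it is off by default.
#'
#' @param dataset an [expression_dataset()] with at least two classes.
#' @param max_iter maximum number of shadow iterations (default 100).
#' @param alpha binomial-test significance level (default 0.05), Bonferroni
#'   corrected across all input features (as in the original Boruta).
#' @param num_trees random-forest size for the importance scorer
#'   (default 500). Importance is the Z-score of permutation importance
#'   (mean decrease in out-of-bag accuracy scaled by its standard error),
#'   the classic Boruta statistic; it is far less sensitive to in-sample
#'   chance correlations than impurity importance.
#' @param seed integer seed; the run is fully deterministic given it.
#' @param rough_fix resolve remaining tentative features by the median
#'   comparison (default FALSE: tentatives stay tentative).
#' @return an object of class `boruta_result`: list with character vectors
#'   `confirmed`, `rejected`, `tentative` (a partition of the gene set),
#'   `hit_counts` (named integer), `n_iterations`, `decision_iteration`
#'   (named integer, NA for rough-fixed features), and
#'   `shadow_max_history`.
#' @export
run_boruta <- function(dataset, max_iter = 100L, alpha = 0.05,
                       num_trees = 500L, seed = 1L, rough_fix = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"), max_iter >= 1L)
  if (nlevels(droplevels(dataset$labels)) < 2L)
    stop("dataset has a single class: feature importance is undefined",
         call. = FALSE)
  x <- classifier_matrix(dataset)
  genes <- colnames(x)
  m <- length(genes)
  status <- stats::setNames(rep("tentative", m), genes)
  hits <- stats::setNames(integer(m), genes)
  trials <- stats::setNames(integer(m), genes)
  decision_iter <- stats::setNames(rep(NA_integer_, m), genes)
  imp_history <- list()
  shadow_max_history <- numeric(0)
  y <- droplevels(dataset$labels)

  iter <- 0L
  with_seed(seed, {
    while (iter < max_iter && any(status == "tentative")) {
      iter <- iter + 1L
      und <- names(status)[status == "tentative"]
      # the whole dataset is copied and shuffled every iteration, so the
      # shadow threshold (max over all m shadows) never weakens as features
      # get decided — decisions are only ever applied to undecided features
      aug <- make_shadow_features(x)
      rf <- ranger::ranger(
        x = aug, y = y,
        num.trees = num_trees, importance = "permutation",
        scale.permutation.importance = TRUE,
        seed = sample.int(.Machine$integer.max, 1L),
        num.threads = 1L)
      imp <- rf$variable.importance
      shadow_max <- max(imp[startsWith(names(imp), "shadow_")])
      shadow_max_history[iter] <- shadow_max
      orig_imp <- imp[und]
      imp_history[[iter]] <- orig_imp
      beat <- und[orig_imp > shadow_max]
      hits[beat] <- hits[beat] + 1L
      trials[und] <- iter
      dec <- binomial_decision(hits[und], iter, alpha, n_features = m)
      decided <- und[dec != "tentative"]
      status[decided] <- dec[dec != "tentative"]
      decision_iter[decided] <- iter
    }
  })

  if (rough_fix && any(status == "tentative") && iter > 0L) {
    shadow_med <- stats::median(shadow_max_history)
    for (g in names(status)[status == "tentative"]) {
      imps <- vapply(imp_history,
                     function(h) if (g %in% names(h)) h[[g]] else NA_real_,
                     numeric(1))
      med <- stats::median(imps, na.rm = TRUE)
      status[g] <- if (is.finite(med) && med > shadow_med) "confirmed"
                   else "rejected"
    }
  }

  structure(list(confirmed = genes[status == "confirmed"],
                 rejected = genes[status == "rejected"],
                 tentative = genes[status == "tentative"],
                 hit_counts = hits, n_iterations = iter,
                 decision_iteration = decision_iter,
                 shadow_max_history = shadow_max_history),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d iterations: %d confirmed, %d rejected, %d tentative\n",
              x$n_iterations, length(x$confirmed), length(x$rejected),
              length(x$tentative)))
  invisible(x)
}
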