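# Incremental feature selection: evaluate nested top-k prefixes of a ranked
# gene list with a classifier under stratified cross-validation (optionally
# SMOTE-balancing each training fold), score each prefix by multiclass MCC
# and accuracy, and select the optimal and compact subset sizes from the
# resulting curve.

#' Subset sizes visited by IFS
#'
#' Sizes `step, 2*step, ...` up to `min(n_ranked, max_k)`; when the cap is
#' not a multiple of the step it is appended as the final size, so the cap
#' is always evaluated.
#'
#' @param n_ranked length of the ranked feature list.
#' @param step step size (default 10).
#' @param max_k optional cap on the largest subset size.
#' @return increasing integer vector of subset sizes.
#' @export
subset_sizes <- function(n_ranked, step = 10L, max_k = NULL) {
  stopifnot(step >= 1L, n_ranked >= 1L)
  cap <- min(n_ranked, max_k %||% n_ranked)
  sizes <- if (cap >= step) seq.int(step, cap, by = step) else integer(0)
  if (length(sizes) == 0L || sizes[length(sizes)] != cap)
    sizes <- c(sizes, cap)
  as.integer(sizes)
}

#' Evaluate one feature-subset size under cross-validation
#'
#' For each fold: restrict the data to the top-`k` ranked genes, optionally
#' SMOTE-balance the training part (in the k-gene feature space), fit the
#' classifier, and predict the held-out part. All held-out predictions are
#' pooled and scored by per-class accuracy, overall accuracy and multiclass
#' MCC.
#'
#' @param dataset an [expression_dataset()].
#' @param ranked a [ranked_features()] list (rank 1 first).
#' @param k subset size (`<= nrow(ranked)`).
#' @param classifier a [classifier_spec()].
#' @param folds a [stratified_folds()] assignment for the dataset.
#' @param smote list with `apply` (logical, default TRUE), `k_neighbors`
#'   (default 5) and `scope` (`"fold"` to balance each training fold,
#'   `"none"` to disable; `"global"` balancing is handled by [run_ifs()]).
#' @param seed base seed for the per-fold SMOTE draws.
#' @return an `ifs_record`: list with `k`, `per_class_accuracy` (named),
#'   `overall_accuracy`, `mcc`.
#' @export
evaluate_subset <- function(dataset, ranked, k, classifier, folds,
                            smote = list(apply = TRUE, k_neighbors = 5L),
                            seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(ranked, "ranked_features"),
            inherits(classifier, "classifier_spec"),
            inherits(folds, "fold_assignment"))
  if (k < 1L || k > nrow(ranked))
    stop("k must lie in 1..", nrow(ranked), call. = FALSE)
  genes <- ranked$gene_id[seq_len(k)]
  x <- classifier_matrix(dataset)[, genes, drop = FALSE]
  y <- dataset$labels
  do_smote <- isTRUE(smote$apply %||% TRUE) &&
    !identical(smote$scope %||% "fold", "none")
  k_nb <- smote$k_neighbors %||% 5L

  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds$K)) {
    test <- folds$fold_of == f
    if (!any(test)) next
    xtr <- x[!test, , drop = FALSE]
    ytr <- y[!test]
    if (do_smote) {
      bal <- tryCatch(
        smote_balance(xtr, ytr, k_neighbors = k_nb,
                      seed = stage_seed(seed, sprintf("smote_f%d", f))),
        error = function(e)
          stop(sprintf("fold %d, k = %d: %s", f, k, conditionMessage(e)),
               call. = FALSE))
      xtr <- bal$values
      ytr <- bal$labels
    }
    model <- tryCatch(fit_classifier(classifier, xtr, ytr),
                      error = function(e)
                        stop(sprintf("classifier failed on fold %d at k = %d: %s",
                                     f, k, conditionMessage(e)), call. = FALSE))
    pred[test] <- predict_classifier(model, x[test, , drop = FALSE])
  }

  cc <- class_counts(pred, y)
  structure(list(k = as.integer(k),
                 per_class_accuracy = per_class_accuracy(cc$n_correct, cc$N),
                 overall_accuracy = overall_accuracy(cc$n_correct, cc$N),
                 mcc = mcc_score(pred, y)),
            class = "ifs_record")
}

#' Run incremental feature selection
#'
#' Evaluates every subset size from [subset_sizes()] with one shared fold
#' assignment (so records are paired across k) and returns the IFS curve.
#'
#' @inheritParams evaluate_subset
#' @param step step size between subset sizes (default 10).
#' @param max_k optional cap on the largest subset size.
#' @param K_folds number of cross-validation folds (default 10).
#' @param seed seed for fold assignment and SMOTE draws.
#' @return an object of class `ifs_curve`: list with `records` (data.frame
#'   with columns `k`, `overall_accuracy`, `mcc`, `acc.<class>`...),
#'   `class_names`, `classifier`, `seed`, `smote_scope`.
#' @export
run_ifs <- function(dataset, ranked, classifier, step = 10L, max_k = NULL,
                    K_folds = 10L, seed = 1L,
                    smote = list(apply = TRUE, k_neighbors = 5L,
                                 scope = "fold")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (nlevels(droplevels(dataset$labels)) < 2L)
    stop("IFS needs at least two classes", call. = FALSE)
  scope <- smote$scope %||% "fold"
  if (!scope %in% c("fold", "global", "none"))
    stop("smote scope must be 'fold', 'global' or 'none'", call. = FALSE)
  eval_data <- dataset
  eval_smote <- smote
  if (scope == "global") {
    # preprocessing-style balancing: oversample once on all genes, then
    # cross-validate the balanced dataset without fold-internal SMOTE
    bal <- smote_balance(classifier_matrix(dataset), dataset$labels,
                         k_neighbors = smote$k_neighbors %||% 5L,
                         seed = stage_seed(seed, "smote_global"))
    eval_data <- expression_dataset(bal$values, bal$labels, scale = "log2")
    eval_smote <- list(apply = FALSE, scope = "none")
  } else if (scope == "none") {
    eval_smote <- list(apply = FALSE, scope = "none")
  }
  folds <- stratified_folds(eval_data$labels, K_folds,
                            seed = stage_seed(seed, "folds"))
  sizes <- subset_sizes(nrow(ranked), step, max_k)
  recs <- lapply(sizes, function(k)
    evaluate_subset(eval_data, ranked, k, classifier, folds,
                    smote = eval_smote, seed = seed))
  acc <- do.call(rbind, lapply(recs, function(r) r$per_class_accuracy))
  colnames(acc) <- paste0("acc.", levels(eval_data$labels))
  records <- data.frame(
    k = vapply(recs, `[[`, integer(1), "k"),
    overall_accuracy = vapply(recs, `[[`, numeric(1), "overall_accuracy"),
    mcc = vapply(recs, `[[`, numeric(1), "mcc"))
  records <- cbind(records, as.data.frame(acc))
  structure(list(records = records,
                 class_names = levels(eval_data$labels),
                 classifier = classifier, seed = as.integer(seed),
                 smote_scope = scope),
            class = "ifs_curve")
}

#' Select the optimal and compact records from an IFS curve
#'
#' `select_optimal` returns the record with the maximum MCC (ties go to the
#' smallest k). `select_compact` returns the smallest k whose MCC is within
#' `tolerance` of the maximum — the classifier that trades a slight
#' performance drop for a much smaller gene panel.
#'
#' @param curve an `ifs_curve`.
#' @param tolerance allowed MCC drop below the maximum (default 0.025).
#' @return one row of `curve$records`.
#' @export
select_optimal <- function(curve) {
  stopifnot(inherits(curve, "ifs_curve"), nrow(curve$records) >= 1L)
  curve$records[which.max(curve$records$mcc), , drop = FALSE]
}

#' @rdname select_optimal
#' @export
select_compact <- function(curve, tolerance = 0.025) {
  stopifnot(inherits(curve, "ifs_curve"), tolerance >= 0)
  mcc <- curve$records$mcc
  idx <- which(mcc >= max(mcc) - tolerance)[1L]
  curve$records[idx, , drop = FALSE]
}

#' Plot an IFS curve (subset size vs MCC)
#'
#' @param x an `ifs_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ifs_curve <- function(x, ...) {
  graphics::plot(x$records$k, x$records$mcc, type = "b", pch = 19,
                 xlab = "number of features", ylab = "MCC",
                 main = sprintf("IFS curve (%s classifier)",
                                x$classifier$kind), ...)
  best <- select_optimal(x)
  graphics::abline(v = best$k, lty = 2, col = "grey50")
  invisible(x)
}
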