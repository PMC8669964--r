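# Pluggable classifiers behind a common contract for the IFS engine:
# "tree" is the in-package CART (shared with rule extraction), "margin" is
# a one-vs-rest polynomial-kernel maximum-margin model (one binary SVM per
# class; a sample is assigned the class whose machine gives the largest
# decision value).

#' Specify a classifier for IFS evaluation
#'
#' @param kind `"tree"` (CART, see [train_tree()]) or `"margin"`
#'   (one-vs-rest polynomial-kernel SVM).
#' @param params kind-specific hyperparameters. Tree: `max_depth`,
#'   `min_samples_split`, `min_samples_leaf`. Margin: `degree` (polynomial
#'   exponent, default 1), `cost` (regularization constant, default 1),
#'   `coef0` (default 0).
#' @param seed integer seed recorded with the spec.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("tree", "margin"), params = list(),
                            seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    tree = list(max_depth = Inf, min_samples_split = 2L,
                min_samples_leaf = 1L),
    margin = list(degree = 1, cost = 1, coef0 = 0))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown ", kind, " hyperparameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  params <- utils::modifyList(defaults, params)
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "classifier_spec")
}

# Fit a classifier per the spec; y is a factor (levels fixed by the
# dataset), x a numeric matrix. Returns an object predict_classifier()
# understands.
fit_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$kind == "tree") {
    p <- spec$params
    model <- train_tree(x, y, max_depth = p$max_depth,
                        min_samples_split = p$min_samples_split,
                        min_samples_leaf = p$min_samples_leaf,
                        seed = spec$seed)
    return(structure(list(kind = "tree", model = model,
                          levels = levels(y)), class = "panelifs_classifier"))
  }
  p <- spec$params
  machines <- list()
  for (cl in levels(y)) {
    pos <- y == cl
    if (!any(pos)) { machines[[cl]] <- NULL; next }
    ybin <- factor(ifelse(pos, "pos", "neg"), levels = c("pos", "neg"))
    machines[[cl]] <- e1071::svm(
      x = x, y = ybin, kernel = "polynomial", degree = p$degree,
      gamma = 1, coef0 = p$coef0, cost = p$cost, scale = FALSE)
  }
  structure(list(kind = "margin", machines = machines, levels = levels(y)),
            class = "panelifs_classifier")
}

predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "panelifs_classifier"))
  if (model$kind == "tree")
    return(predict(model$model, x))
  dec <- matrix(-Inf, nrow = nrow(x), ncol = length(model$levels),
                dimnames = list(NULL, model$levels))
  for (cl in names(model$machines)) {
    m <- model$machines[[cl]]
    if (is.null(m)) next
    d <- attr(predict(m, x, decision.values = TRUE), "decision.values")
    # decision values are oriented toward the first level ("pos")
    dec[, cl] <- if (colnames(d)[1L] == "pos/neg") d[, 1L] else -d[, 1L]
  }
  factor(model$levels[max.col(dec, ties.method = "first")],
         levels = model$levels)
}
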