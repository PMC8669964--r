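# CART classification tree with Gini impurity. Implemented in-package so
# that IFS evaluation and rule extraction share one tree whose behavior is
# fully specified: split thresholds are midpoints between adjacent sorted
# values, and ties in impurity gain are broken by lowest feature index then
# lowest threshold, making training deterministic without any RNG.

#' Train a CART classification tree
#'
#' Grows a binary tree by exhaustive best-split search: at each node every
#' (feature, midpoint-threshold) pair is scored by the weighted Gini
#' impurity of the two children and the best strict improvement is taken.
#' Growth stops at pure nodes, at `max_depth`, when a node has fewer than
#' `min_samples_split` samples, or when no split separates the node.
#'
#' @param x numeric matrix, samples as rows, named feature columns.
#' @param y factor of class labels (length `nrow(x)`).
#' @param max_depth maximum tree depth (default `Inf`: grow to pure leaves).
#' @param min_samples_split minimum node size to attempt a split (default 2).
#' @param min_samples_leaf minimum samples in each child (default 1).
#' @param seed recorded in the model metadata for provenance; training
#'   itself is deterministic.
#' @return an object of class `cart_tree`. Internal nodes carry
#'   `(feature, threshold)` with left = "<= threshold"; leaves carry
#'   per-class training counts and the majority class.
#' @export
train_tree <- function(x, y, max_depth = Inf, min_samples_split = 2L,
                       min_samples_leaf = 1L, seed = 1L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix", call. = FALSE)
  if (ncol(x) < 1L) stop("empty feature set", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.factor(y)
  stopifnot(length(y) == nrow(x), nrow(x) >= 1L)
  C <- nlevels(y)
  yi <- as.integer(y)

  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }

  grow <- function(idx, depth) {
    counts <- tabulate(yi[idx], nbins = C)
    id <- new_node(list(is_leaf = TRUE, counts = counts,
                        pred = which.max(counts)))
    n_i <- length(idx)
    if (sum(counts > 0L) <= 1L || n_i < min_samples_split ||
        depth >= max_depth)
      return(id)
    sp <- best_split(x, yi, idx, C, min_samples_leaf)
    if (is.null(sp)) return(id)
    left_idx <- idx[x[idx, sp$feature] <= sp$threshold]
    right_idx <- idx[x[idx, sp$feature] > sp$threshold]
    left <- grow(left_idx, depth + 1L)
    right <- grow(right_idx, depth + 1L)
    nodes[[id]] <<- list(is_leaf = FALSE, feature = sp$feature,
                         threshold = sp$threshold, left = left,
                         right = right, counts = counts)
    id
  }
  root <- grow(seq_len(nrow(x)), 0L)

  structure(list(nodes = nodes, root = root,
                 feature_names = colnames(x), class_names = levels(y),
                 params = list(max_depth = max_depth,
                               min_samples_split = min_samples_split,
                               min_samples_leaf = min_samples_leaf,
                               split_criterion = "gini", seed = seed)),
            class = "cart_tree")
}

# Exhaustive (feature, midpoint) search minimizing total weighted child
# Gini impurity, expressed as sum_child (n_child - sum_c count_c^2/n_child).
# Strict-improvement acceptance (> 1e-12) gives the documented tie-breaks.
best_split <- function(x, yi, idx, C, min_samples_leaf) {
  n_i <- length(idx)
  counts <- tabulate(yi[idx], nbins = C)
  node_score <- n_i - sum(counts^2) / n_i
  best <- NULL
  best_score <- node_score - 1e-12
  for (j in seq_len(ncol(x))) {
    v <- x[idx, j]
    o <- order(v)
    vs <- v[o]
    if (vs[1L] == vs[n_i]) next
    cls <- yi[idx][o]
    cum <- matrix(0, nrow = n_i, ncol = C)
    for (c in seq_len(C)) cum[, c] <- cumsum(cls == c)
    nL <- seq_len(n_i - 1L)
    valid <- vs[nL] < vs[nL + 1L] & nL >= min_samples_leaf &
      (n_i - nL) >= min_samples_leaf
    if (!any(valid)) next
    sl <- rowSums(cum[nL, , drop = FALSE]^2)
    tot <- matrix(counts, nrow = n_i - 1L, ncol = C, byrow = TRUE)
    sr <- rowSums((tot - cum[nL, , drop = FALSE])^2)
    score <- (nL - sl / nL) + ((n_i - nL) - sr / (n_i - nL))
    score[!valid] <- Inf
    k <- which.min(score)   # first minimum = lowest threshold
    if (score[k] < best_score) {
      best_score <- score[k]
      best <- list(feature = j,
                   threshold = unname((vs[k] + vs[k + 1L]) / 2))
    }
  }
  best
}

#' Predict classes with a CART tree
#'
#' @param object a `cart_tree`.
#' @param newdata numeric matrix with (at least) the tree's feature columns.
#' @param ... unused.
#' @return factor of predicted classes with the training levels.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  if (ncol(newdata) != length(object$feature_names))
    stop("newdata lacks the tree's feature columns", call. = FALSE)
  pred <- integer(nrow(newdata))
  route <- function(node_id, rows) {
    if (length(rows) == 0L) return(invisible())
    node <- object$nodes[[node_id]]
    if (node$is_leaf) {
      pred[rows] <<- node$pred
      return(invisible())
    }
    go_left <- newdata[rows, node$feature] <= node$threshold
    route(node$left, rows[go_left])
    route(node$right, rows[!go_left])
  }
  route(object$root, seq_len(nrow(newdata)))
  factor(object$class_names[pred], levels = object$class_names)
}

#' @export
print.cart_tree <- function(x, ...) {
  n_leaves <- sum(vapply(x$nodes, `[[`, logical(1), "is_leaf"))
  cat(sprintf("<cart_tree> %d nodes (%d leaves), %d features, %d classes\n",
              length(x$nodes), n_leaves, length(x$feature_names),
              length(x$class_names)))
  invisible(x)
}

#' Extract IF-THEN decision rules from a CART tree
#'
#' One rule per leaf: the criteria are the root-to-leaf path conditions in
#' order (`gene <= t` for a left branch, `gene > t` for a right branch) and
#' the rule's class is the leaf's majority class. The rules are mutually
#' exclusive and exhaustive, so as a classifier they reproduce the tree
#' exactly.
#'
#' @param tree a `cart_tree`.
#' @return an object of class `rule_set`: list with `rules` (each a list
#'   with `class`, `support` = leaf training-sample count, and a `criteria`
#'   data.frame with columns `gene_id`, `comparator`, `threshold`) and
#'   `class_names`.
#' @export
extract_rules <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  rules <- list()
  walk <- function(node_id, gene_id, comparator, threshold) {
    node <- tree$nodes[[node_id]]
    if (node$is_leaf) {
      rules[[length(rules) + 1L]] <<- list(
        class = tree$class_names[node$pred],
        support = sum(node$counts),
        criteria = data.frame(gene_id = gene_id, comparator = comparator,
                              threshold = threshold))
      return(invisible())
    }
    g <- tree$feature_names[node$feature]
    walk(node$left, c(gene_id, g), c(comparator, "<="),
         c(threshold, node$threshold))
    walk(node$right, c(gene_id, g), c(comparator, ">"),
         c(threshold, node$threshold))
  }
  walk(tree$root, character(0), character(0), numeric(0))
  structure(list(rules = rules, class_names = tree$class_names),
            class = "rule_set")
}

#' Classify samples with a rule set
#'
#' Applies each rule's conjunction of criteria; because rules extracted from
#' a tree partition the feature space, exactly one rule fires per sample.
#'
#' @param rules a `rule_set`.
#' @param newdata numeric matrix with named columns covering the rule genes.
#' @return factor of predicted classes.
#' @export
predict_rules <- function(rules, newdata) {
  stopifnot(inherits(rules, "rule_set"))
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  pred <- rep(NA_character_, n)
  for (r in rules$rules) {
    mask <- rep(TRUE, n)
    for (i in seq_len(nrow(r$criteria))) {
      v <- newdata[, r$criteria$gene_id[i]]
      mask <- mask & if (r$criteria$comparator[i] == "<=")
        v <= r$criteria$threshold[i] else v > r$criteria$threshold[i]
    }
    pred[mask & is.na(pred)] <- r$class
  }
  if (anyNA(pred)) stop("rule set does not cover some samples", call. = FALSE)
  factor(pred, levels = rules$class_names)
}

#' Summarize a rule set per class
#'
#' The per-class panel summary: number of rules, total number of criteria
#' over those rules, and number of distinct genes involved. Classes with no
#' rules are reported with zeros.
#'
#' @param rules a `rule_set`.
#' @return a data.frame with columns `class`, `n_rules`, `n_criteria`,
#'   `n_genes`.
#' @export
summarize_rules <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  cls <- rules$class_names
  out <- data.frame(class = cls, n_rules = 0L, n_criteria = 0L,
                    n_genes = 0L)
  genes_by_class <- stats::setNames(vector("list", length(cls)), cls)
  for (r in rules$rules) {
    i <- match(r$class, cls)
    out$n_rules[i] <- out$n_rules[i] + 1L
    out$n_criteria[i] <- out$n_criteria[i] + nrow(r$criteria)
    genes_by_class[[r$class]] <- union(genes_by_class[[r$class]],
                                       r$criteria$gene_id)
  }
  out$n_genes <- vapply(genes_by_class, length, integer(1))
  out
}
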