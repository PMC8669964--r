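test_that("degenerate training sets give single-leaf trees", {
  x <- matrix(rnorm(10), ncol = 2, dimnames = list(NULL, c("a", "b")))
  tr <- train_tree(x, factor(rep("A", 5)))
  expect_length(tr$nodes, 1L)
  expect_true(tr$nodes[[1]]$is_leaf)
  expect_equal(as.character(predict(tr, x)), rep("A", 5))
  expect_error(train_tree(x[, 0, drop = FALSE], factor(rep("A", 5))),
               "empty feature")
})

test_that("a perfectly separating gene yields a depth-1 tree at the midpoint", {
  x <- cbind(g1 = c(1, 2, 1.5, 5, 6, 5.5), g2 = rnorm(6))
  y <- factor(rep(c("lo", "hi"), each = 3))
  tr <- train_tree(x, y)
  expect_length(tr$nodes, 3L)
  root <- tr$nodes[[tr$root]]
  expect_false(root$is_leaf)
  expect_equal(tr$feature_names[root$feature], "g1")
  expect_equal(root$threshold, (2 + 5) / 2)
  expect_equal(as.character(predict(tr, x)), as.character(y))
})

test_that("training is deterministic and ties break toward the lowest feature", {
  p <- random_tree_problem(n = 50, m = 6, C = 3, seed = 10)
  t1 <- train_tree(p$x, p$y)
  t2 <- train_tree(p$x, p$y)
  expect_identical(t1$nodes, t2$nodes)
  # duplicated separating feature: the copy (higher index) must not be used
  x <- cbind(g1 = c(1, 1, 8, 8), g2 = c(1, 1, 8, 8))
  tr <- train_tree(x, factor(c("A", "A", "B", "B")))
  expect_equal(tr$feature_names[tr$nodes[[tr$root]]$feature], "g1")
})

test_that("one rule per leaf, with root-to-leaf path criteria", {
  p <- random_tree_problem(n = 60, m = 4, C = 3, seed = 11)
  tr <- train_tree(p$x, p$y)
  rl <- extract_rules(tr)
  n_leaves <- sum(vapply(tr$nodes, `[[`, logical(1), "is_leaf"))
  expect_length(rl$rules, n_leaves)
  expect_true(all(vapply(rl$rules, function(r) r$support >= 1L, logical(1))))
  expect_true(all(unlist(lapply(rl$rules, function(r) r$criteria$gene_id))
                  %in% tr$feature_names))
  # depth-1 tree: two rules with one criterion each
  x <- cbind(g1 = c(1, 2, 8, 9))
  tr1 <- train_tree(x, factor(c("A", "A", "B", "B")))
  rl1 <- extract_rules(tr1)
  expect_length(rl1$rules, 2L)
  expect_equal(vapply(rl1$rules, function(r) nrow(r$criteria), integer(1)),
               c(1L, 1L))
})

test_that("rules reproduce the tree exactly on training and novel samples", {
  for (s in 1:20) {
    p <- random_tree_problem(n = 40, m = 5, C = 3, seed = 100 + s)
    tr <- train_tree(p$x, p$y)
    rl <- extract_rules(tr)
    expect_identical(predict_rules(rl, p$x), predict(tr, p$x))
    q <- matrix(rnorm(50 * 5, sd = 2), ncol = 5,
                dimnames = list(NULL, colnames(p$x)))
    expect_identical(predict_rules(rl, q), predict(tr, q))
  }
})

test_that("rule summaries count rules, criteria and distinct genes per class", {
  crit <- function(genes) data.frame(gene_id = genes,
                                     comparator = rep("<=", length(genes)),
                                     threshold = seq_along(genes))
  rl <- structure(list(
    rules = list(list(class = "A", support = 3L,
                      criteria = crit(c("g1", "g2", "g2"))),
                 list(class = "A", support = 2L,
                      criteria = crit(c("g2", "g3", "g3", "g1"))),
                 list(class = "B", support = 5L, criteria = crit("g4"))),
    class_names = c("A", "B", "C")), class = "rule_set")
  s <- summarize_rules(rl)
  expect_equal(s$n_rules, c(2L, 1L, 0L))
  expect_equal(s$n_criteria, c(7L, 1L, 0L))
  expect_equal(s$n_genes, c(3L, 1L, 0L))
  expect_equal(sum(s$n_rules), length(rl$rules))
  expect_true(all(s$n_genes <= s$n_criteria))
})
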