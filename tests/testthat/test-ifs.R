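test_that("subset sizes follow the step rule and always include the cap", {
  expect_equal(subset_sizes(25, 10), c(10L, 20L, 25L))
  expect_equal(subset_sizes(1000, 10, max_k = 400), seq(10L, 400L, by = 10L))
  expect_equal(subset_sizes(5, 1), 1:5)
  expect_equal(subset_sizes(7, 10), 7L)
  expect_equal(subset_sizes(30, 10), c(10L, 20L, 30L))
})

make_curve <- function(k, mcc) {
  rec <- data.frame(k = k, overall_accuracy = mcc, mcc = mcc,
                    acc.A = mcc, acc.B = mcc)
  structure(list(records = rec, class_names = c("A", "B"),
                 classifier = list(kind = "tree"), seed = 1L,
                 smote_scope = "fold"), class = "ifs_curve")
}

test_that("optimal and compact selection follow the stated tie and tolerance rules", {
  cur <- make_curve(c(10, 20, 30), c(0.5, 0.9, 0.9))
  expect_equal(select_optimal(cur)$k, 20)
  single <- make_curve(15, 0.7)
  expect_equal(select_optimal(single)$k, 15)
  cur2 <- make_curve(c(10, 20, 30), c(0.90, 0.955, 0.976))
  expect_equal(select_compact(cur2, 0.025)$k, 20)
  expect_equal(select_compact(cur2, 0)$k, select_optimal(cur2)$k)
  # compact k never exceeds optimal k
  set.seed(1)
  for (i in 1:50) {
    cur3 <- make_curve(seq(10, 60, 10), runif(6))
    expect_lte(select_compact(cur3, runif(1, 0, 0.2))$k,
               select_optimal(cur3)$k)
  }
})

test_that("a decisive gene in the subset gives a perfect held-out MCC", {
  set.seed(2)
  y <- rep(c("A", "B"), each = 20)
  v <- cbind(g1 = ifelse(y == "A", 1, 9) + rnorm(40, 0, 0.2),
             matrix(rnorm(40 * 4), nrow = 40,
                    dimnames = list(NULL, sprintf("n%d", 1:4))))
  d <- make_dataset(v, y)
  rk <- ranked_features(colnames(v), seq(1, 0.2, length.out = 5))
  folds <- stratified_folds(d$labels, 5, seed = 3)
  rec <- evaluate_subset(d, rk, k = 2, classifier_spec("tree"), folds,
                         seed = 4)
  expect_equal(rec$k, 2L)
  expect_equal(rec$mcc, 1.0)
  expect_equal(rec$overall_accuracy, 1.0)
})

test_that("permuted labels give held-out MCC near zero", {
  set.seed(5)
  mccs <- replicate(5, {
    v <- matrix(rnorm(60 * 6), nrow = 60,
                dimnames = list(NULL, sprintf("g%d", 1:6)))
    d <- make_dataset(v, sample(rep(c("A", "B"), each = 30)))
    rk <- ranked_features(colnames(v), 6:1)
    folds <- stratified_folds(d$labels, 5, seed = 6)
    evaluate_subset(d, rk, 4, classifier_spec("tree"), folds, seed = 7)$mcc
  })
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("the IFS curve visits the right sizes, reuses folds and is deterministic", {
  g <- generate_dataset(synthetic_spec(3, c(15, 15, 15), 6, 0, 24, seed = 8))
  rk <- rank_mrmr(g$dataset)
  cur1 <- run_ifs(g$dataset, rk, classifier_spec("tree"), step = 10,
                  K_folds = 5, seed = 9)
  expect_equal(cur1$records$k, c(10L, 20L, 30L))
  cur2 <- run_ifs(g$dataset, rk, classifier_spec("tree"), step = 10,
                  K_folds = 5, seed = 9)
  expect_identical(cur1$records, cur2$records)
  # permuting ranks beyond the evaluated prefix leaves records unchanged
  rk_tail <- ranked_features(c(rk$gene_id[1:20], rev(rk$gene_id[21:30])),
                             rk$score)
  cur3 <- run_ifs(g$dataset, rk_tail, classifier_spec("tree"), step = 10,
                  max_k = 20, K_folds = 5, seed = 9)
  expect_identical(cur3$records, cur1$records[1:2, ])
})

test_that("MCC does not drop while informative genes accrue along the ranking", {
  ok <- 0
  for (s in 1:5) {
    g <- generate_dataset(synthetic_spec(4, rep(15, 4), 20, 0, 40,
                                         effect_size = 2, seed = 20 + s))
    rk <- rank_mrmr(g$dataset, n_select = 20)
    cur <- run_ifs(g$dataset, rk, classifier_spec("tree"), step = 10,
                   K_folds = 5, seed = 30 + s)
    if (cur$records$mcc[2] >= cur$records$mcc[1] - 0.02) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("the margin classifier separates an easy multiclass problem", {
  g <- generate_dataset(synthetic_spec(3, c(15, 15, 15), 6, 0, 10,
                                       effect_size = 3, noise_sd = 0.3,
                                       seed = 12))
  rk <- rank_mrmr(g$dataset)
  cur <- run_ifs(g$dataset, rk, classifier_spec("margin"), step = 8,
                 K_folds = 5, seed = 13)
  expect_gte(max(cur$records$mcc), 0.9)
})

test_that("global-scope SMOTE balances once and then cross-validates cleanly", {
  g <- generate_dataset(synthetic_spec(2, c(24, 12), 4, 0, 12,
                                       effect_size = 2.5, seed = 14))
  rk <- rank_mrmr(g$dataset)
  cur <- run_ifs(g$dataset, rk, classifier_spec("tree"), step = 8,
                 K_folds = 4, seed = 15,
                 smote = list(apply = TRUE, k_neighbors = 3,
                              scope = "global"))
  expect_equal(cur$smote_scope, "global")
  expect_true(all(cur$records$mcc >= -1 & cur$records$mcc <= 1))
})
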