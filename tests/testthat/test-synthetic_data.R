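test_that("generated datasets have the dimensions and labels the spec forces", {
  spec <- synthetic_spec(3, c(20, 20, 20), 10, 0, 90, seed = 1)
  g <- generate_dataset(spec)
  expect_equal(dim(g$dataset$values), c(60, 100))
  expect_equal(unname(tabulate(g$dataset$labels)), c(20, 20, 20))
  expect_length(g$truth$informative, 10)
  expect_length(g$truth$noise, 90)
  # the three gene sets partition the gene universe
  all_ids <- c(g$truth$informative, g$truth$redundant, g$truth$noise)
  expect_setequal(all_ids, colnames(g$dataset$values))
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("identical spec + seed reproduces the dataset bit for bit", {
  spec <- synthetic_spec(3, c(20, 20, 20), 10, 5, 85, seed = 42)
  g1 <- generate_dataset(spec)
  g2 <- generate_dataset(spec)
  expect_identical(g1$dataset$values, g2$dataset$values)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_dataset(synthetic_spec(3, c(20, 20, 20), 10, 5, 85, seed = 43))
  expect_false(identical(g1$dataset$values, g3$dataset$values))
})

test_that("invalid specs fail naming the offending field", {
  expect_error(synthetic_spec(1, c(5), 1), "n_classes")
  expect_error(synthetic_spec(2, c(5, 1), 1), "class_sizes")
  expect_error(synthetic_spec(2, c(5, 5, 5), 1), "class_sizes")
  expect_error(synthetic_spec(2, c(5, 5), -1), "n_informative")
  expect_error(synthetic_spec(2, c(5, 5), 0, 3, 10), "n_redundant")
  expect_error(synthetic_spec(2, c(5, 5), 0, 0, 0), "n_informative")
})

test_that("informative genes carry the specified log2 effect size", {
  # n = 200/class so the standard error of a mean difference is small
  spec <- synthetic_spec(3, c(200, 200, 200), 10, 0, 10,
                         effect_size = 2, noise_sd = 0.5, seed = 7)
  g <- generate_dataset(spec)
  lab <- g$dataset$labels
  for (gene in g$truth$informative) {
    on_classes <- g$truth$signal_classes[[gene]]
    v <- g$dataset$values[, gene]
    on <- lab %in% on_classes
    diff <- mean(v[on]) - mean(v[!on])
    se <- 0.5 * sqrt(1 / sum(on) + 1 / sum(!on))
    expect_lt(abs(diff - 2), 3 * se)
  }
})

test_that("zero effect size produces no class-informative genes", {
  spec <- synthetic_spec(3, c(40, 40, 40), 30, 0, 170,
                         effect_size = 0, noise_sd = 0.5, seed = 11)
  g <- generate_dataset(spec)
  p <- apply(g$dataset$values, 2L, function(v)
    stats::anova(stats::lm(v ~ g$dataset$labels))[["Pr(>F)"]][1L])
  # p-values should be uniform: the 5%-level rejection rate over 200 genes
  # stays within a generous binomial band around 0.05
  expect_lt(sum(p < 0.05), 25)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

test_that("redundant genes correlate strongly with their parents", {
  spec <- synthetic_spec(3, c(30, 30, 30), 5, 10, 5,
                         noise_sd = 0.5, redundancy_sd = 0.25, seed = 3)
  g <- generate_dataset(spec)
  for (r in g$truth$redundant) {
    parent <- g$truth$redundant_parent[[r]]
    expect_gt(stats::cor(g$dataset$values[, r], g$dataset$values[, parent]),
              0.5)
  }
})

test_that("raw-scale output is the exponentiated log2 matrix", {
  spec <- synthetic_spec(2, c(10, 10), 2, 0, 8, seed = 5)
  g_log <- generate_dataset(spec, scale = "log2")
  g_raw <- generate_dataset(spec, scale = "raw")
  expect_true(all(g_raw$dataset$values >= 0))
  expect_equal(g_raw$dataset$values, 2^g_log$dataset$values)
})
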