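test_that("expression matrix + labels round-trip losslessly", {
  g <- generate_dataset(synthetic_spec(2, c(12, 14), 3, 0, 7, seed = 2))
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(g$dataset, mp, lp)
  back <- read_expression(mp, lp, min_class_size = 2, scale = "log2")
  expect_equal(back$values, g$dataset$values, tolerance = 1e-12)
  expect_identical(back$labels, g$dataset$labels)
})

test_that("classes below min_class_size are dropped with their samples", {
  v <- matrix(runif(21 * 3), nrow = 21,
              dimnames = list(sprintf("S%02d", 1:21), c("g1", "g2", "g3")))
  labs <- c(rep("A", 12), rep("B", 9))
  d <- make_dataset(v, labs, scale = "raw")
  mp <- withr::local_tempfile(); lp <- withr::local_tempfile()
  write_expression(d, mp, lp)
  kept <- read_expression(mp, lp, min_class_size = 10)
  expect_equal(nrow(kept$values), 12)
  expect_equal(levels(kept$labels), "A")
  expect_error(read_expression(mp, lp, min_class_size = 15), "min_class_size")
})

test_that("a matrix sample missing from the labels file is an error naming it", {
  v <- matrix(1:6, nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("g1", "g2")))
  mp <- withr::local_tempfile(); lp <- withr::local_tempfile()
  write_expression(make_dataset(v, c("A", "A", "B"), scale = "raw"), mp, lp)
  lab <- readLines(lp)
  writeLines(lab[lab != "s2\tA"], lp)
  expect_error(read_expression(mp, lp, min_class_size = 1), "s2")
})

test_that("genes-as-rows matrices are auto-detected and transposed", {
  g <- generate_dataset(synthetic_spec(2, c(8, 8), 2, 0, 6, seed = 9))
  d <- g$dataset
  mp <- withr::local_tempfile(); lp <- withr::local_tempfile()
  tv <- t(d$values)
  lines <- c(paste(c("gene_id", colnames(tv)), collapse = "\t"),
             vapply(seq_len(nrow(tv)), function(i)
               paste(c(rownames(tv)[i], sprintf("%.17g", tv[i, ])),
                     collapse = "\t"), character(1)))
  writeLines(lines, mp)
  writeLines(c("sample_id\tclass",
               paste(rownames(d$values), as.character(d$labels), sep = "\t")),
             lp)
  back <- read_expression(mp, lp, min_class_size = 2, scale = "log2")
  expect_equal(back$values[rownames(d$values), colnames(d$values)],
               d$values, tolerance = 1e-12)
})

test_that("reading is insensitive to label-file row order", {
  g <- generate_dataset(synthetic_spec(2, c(8, 8), 2, 0, 6, seed = 9))
  mp <- withr::local_tempfile(); lp <- withr::local_tempfile()
  write_expression(g$dataset, mp, lp)
  lab <- readLines(lp)
  writeLines(c(lab[1], rev(lab[-1])), lp)
  back <- read_expression(mp, lp, min_class_size = 2, scale = "log2")
  expect_identical(back$labels, g$dataset$labels)
})

test_that("ranked lists, IFS curves and rule sets round-trip", {
  rk <- ranked_features(sprintf("G%03d", 1:5), c(0.9, 0.5, 0.41, 0.4, 0.1))
  rp <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_list(rk, rp)
  expect_equal(read_ranked_list(rp), rk, tolerance = 1e-12)

  g <- generate_dataset(synthetic_spec(3, c(10, 10, 10), 4, 0, 8, seed = 4))
  cur <- run_ifs(g$dataset, rank_mrmr(g$dataset), classifier_spec("tree"),
                 step = 4, K_folds = 3, seed = 1)
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_ifs_curve(cur, cp)
  back <- read_ifs_curve(cp)
  expect_equal(back$records, cur$records, tolerance = 1e-12)
  expect_identical(back$class_names, cur$class_names)
  # schema: k, overall_accuracy, mcc, then one accuracy column per class
  expect_identical(colnames(back$records),
                   c("k", "overall_accuracy", "mcc",
                     paste0("acc.", cur$class_names)))

  tr <- train_tree(g$dataset$values[, 1:4], g$dataset$labels)
  rl <- extract_rules(tr)
  jp <- withr::local_tempfile(fileext = ".jsonl")
  tp <- withr::local_tempfile(fileext = ".txt")
  write_rules(rl, jp, tp)
  back_rl <- read_rules(jp)
  expect_equal(back_rl$rules, rl$rules, tolerance = 1e-12)
  expect_identical(back_rl$class_names, rl$class_names)
  expect_true(any(grepl("THEN class", readLines(tp))))
})

test_that("an empty rule set writes and reads back as zero rules", {
  empty <- structure(list(rules = list(), class_names = c("A", "B")),
                     class = "rule_set")
  jp <- withr::local_tempfile(fileext = ".jsonl")
  write_rules(empty, jp)
  back <- read_rules(jp)
  expect_length(back$rules, 0)
  expect_identical(back$class_names, c("A", "B"))
  expect_equal(summarize_rules(back)$n_rules, c(0L, 0L))
})
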