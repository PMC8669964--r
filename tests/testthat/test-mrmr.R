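test_that("three-bin discretization follows the mean +/- sigma*sd rule", {
  expect_equal(discretize(rep(3.2, 10))$codes, rep(1L, 10))
  # boundaries land exactly on the two points, which stay in the middle bin
  expect_equal(discretize(c(0, 10), sigma = 1)$codes, c(1L, 1L))
  set.seed(1)
  d <- discretize(rnorm(10000), sigma = 1)
  expect_setequal(unique(d$codes), 0:2)
  expect_error(discretize(1:5, sigma = 0), "sigma")
})

test_that("mutual information matches hand-computed cases", {
  a <- as_discretized(c(0, 0, 1, 1), 2)
  expect_equal(mutual_information(a, a), 1.0)          # = H(a) for a copy
  b <- as_discretized(c(0, 1, 0, 1), 2)
  expect_equal(mutual_information(a, b), 0.0)          # empirically independent
  const <- as_discretized(rep(0, 4), 2)
  expect_equal(mutual_information(a, const), 0.0)      # zero-entropy variable
  expect_error(mutual_information(a, as_discretized(0:1, 2)), "length")
})

test_that("mutual information matches the joint-histogram oracle and is symmetric", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    Ba <- sample(2:4, 1); Bb <- sample(2:4, 1)
    a <- as_discretized(sample(0:(Ba - 1), n, replace = TRUE), Ba)
    b <- as_discretized(sample(0:(Bb - 1), n, replace = TRUE), Bb)
    mi <- mutual_information(a, b)
    expect_gte(mi, 0)
    expect_lt(abs(mi - oracle_mi(a$codes, b$codes)), 1e-12)
    expect_lt(abs(mi - mutual_information(b, a)), 1e-12)
  }
})

test_that("mRMR ranks a perfectly label-aligned gene first and penalizes its copy", {
  set.seed(4)
  y <- rep(c("A", "B", "C"), each = 20)
  v <- cbind(g1 = rep(c(1, 5, 9), each = 20),     # tracks the label exactly
             g2 = rnorm(60) + 0.6 * (y == "B"),   # weakly relevant
             g3 = rnorm(60) + 0.6 * (y == "C"))
  d <- make_dataset(v, y)
  r <- rank_mrmr(d)
  expect_equal(r$gene_id[1], "g1")
  # an exact copy of g1 has its relevance exactly cancelled by redundancy
  # under MID at the step after g1 is taken, so it cannot be ranked second
  # (later steps average redundancy over more genes, diluting the penalty)
  v4 <- cbind(v, g4 = v[, "g1"])
  r4 <- rank_mrmr(make_dataset(v4, y), criterion = "MID")
  expect_equal(r4$gene_id[1], "g1")
  expect_false(r4$gene_id[2] == "g4")
})

test_that("n_select clamps to the candidate count and errors sensibly", {
  g <- generate_dataset(synthetic_spec(2, c(10, 10), 2, 0, 3, seed = 6))
  r <- rank_mrmr(g$dataset, n_select = 50)
  expect_equal(nrow(r), 5)
  expect_setequal(r$gene_id, colnames(g$dataset$values))
  expect_error(rank_mrmr(g$dataset, candidate_genes = character(0)), "empty")
  expect_error(rank_mrmr(g$dataset, candidate_genes = "nope"), "nope")
})

test_that("every greedy step equals the brute-force criterion argmax", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(15:40, 1)
    p <- sample(3:8, 1)
    C <- sample(2:4, 1)
    crit <- sample(c("MID", "MIQ"), 1)
    y <- factor(sample(letters[seq_len(C)], n, replace = TRUE))
    v <- matrix(rnorm(n * p), nrow = n,
                dimnames = list(NULL, sprintf("g%02d", seq_len(p))))
    # make a couple of genes label-associated so relevance varies
    v[, 1] <- v[, 1] + as.integer(y)
    d <- make_dataset(v, as.character(y))
    r <- rank_mrmr(d, criterion = crit)
    codes <- vapply(colnames(v), function(g) discretize(v[, g])$codes,
                    integer(n))
    oracle <- oracle_mrmr(codes, as.integer(y) - 1L, 3L, C, crit)
    expect_equal(r$gene_id, colnames(v)[oracle])
  }
})

test_that("the ranking is invariant to sample order", {
  g <- generate_dataset(synthetic_spec(3, c(15, 15, 15), 5, 0, 15, seed = 8))
  r1 <- rank_mrmr(g$dataset)
  set.seed(9)
  ord <- sample.int(45)
  d2 <- make_dataset(g$dataset$values[ord, ],
                     as.character(g$dataset$labels)[ord])
  expect_identical(rank_mrmr(d2)$gene_id, r1$gene_id)
})
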