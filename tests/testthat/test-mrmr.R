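test_that("mutual information matches the contingency oracle and its identities", {
  # a balanced binary variable carries exactly one bit about itself
  y <- rep(c(0, 1), 50)
  expect_equal(mutual_information(y, y), 1.0)
  # constant column has zero entropy
  expect_equal(mutual_information(rep(1, 100), y), 0)
  # symmetry is exact and the estimate matches the loop-based oracle
  set.seed(31)
  for (rep in 1:10) {
    x <- sample(0:3, 80, replace = TRUE)
    z <- sample(0:2, 80, replace = TRUE)
    expect_identical(mutual_information(x, z), mutual_information(z, x))
    expect_equal(mutual_information(x, z), oracle_mi(x, z), tolerance = 1e-12)
    expect_gte(mutual_information(x, z), 0)
  }
})

test_that("independent variables have vanishing estimated MI at large n", {
  set.seed(32)
  x <- stats::rnorm(10000)
  y <- sample(0:1, 10000, replace = TRUE)
  expect_lt(mutual_information(x, y), 0.05)
})

test_that("equal-frequency binning balances occupancy on continuous data", {
  set.seed(33)
  x <- stats::rexp(1000)
  codes <- discretize_equal_frequency(x, 10)
  expect_equal(length(unique(codes)), 10)
  expect_true(max(table(codes)) - min(table(codes)) <= 1)
  # heavy ties collapse bins rather than erroring
  expect_lte(length(unique(discretize_equal_frequency(rep(c(0, 1), 50), 10))), 2)
})

test_that("relevance and redundancy follow their subset definitions", {
  tab <- make_copy_table(n = 200, seed = 2)
  Hy <- 1.0   # balanced binary label entropy
  expect_equal(relevance(tab, "f1"), Hy)
  # mean over a duplicated feature equals the single-feature value
  expect_equal(relevance(tab, c("f1", "f2")), relevance(tab, "f1"))
  # single-feature redundancy is the self-information
  expect_equal(redundancy(tab, "f1"), 1.0)
  # two independent balanced features: only self-pairs contribute (H1+H2)/4
  set.seed(34)
  n <- 4000
  a <- sample(0:1, n, replace = TRUE)
  b <- sample(0:1, n, replace = TRUE)
  t2 <- feature_table(cbind(a = a, b = b), sample(0:1, n, replace = TRUE))
  H1 <- -sum(table(a) / n * log2(table(a) / n))
  H2 <- -sum(table(b) / n * log2(table(b) / n))
  expect_equal(redundancy(t2, c("a", "b")), (H1 + H2) / 4, tolerance = 0.01)
  # a duplicated pair is strictly more redundant than an independent pair
  t3 <- feature_table(cbind(a = a, b = a), t2$labels)
  expect_gt(redundancy(t3, c("a", "b")), redundancy(t2, c("a", "b")))
  expect_error(relevance(tab, integer(0)), "non-empty")
})

test_that("greedy ranking picks relevance first, then least redundancy", {
  tab <- make_copy_table(n = 160, seed = 3)
  rk <- mrmr_rank(tab, k = 2)
  # f1 (label copy) first; f3 (noise) second because f2 duplicates f1
  expect_equal(rk$feature, c("f1", "f3"))
  expect_equal(rk$score, rk$relevance - rk$redundancy)
  expect_equal(nrow(mrmr_rank(tab, k = 0)), 0)
  expect_setequal(mrmr_rank(tab)$feature, c("f1", "f2", "f3"))
  expect_error(mrmr_rank(tab, k = 5), "exceeds")
})

test_that("greedy ranking matches the exhaustive oracle on small tables", {
  set.seed(35)
  for (rep in 1:8) {
    p <- 5
    n <- 150
    X <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
    y <- as.integer(stats::runif(n) < stats::plogis(X[, 1] - X[, 2]))
    if (length(unique(y)) < 2) next
    tab <- feature_table(X, y)
    codes <- lapply(seq_len(p), function(j) tab$values[, j])
    want <- oracle_mrmr_sequence(codes, y, k = 4)
    got <- mrmr_rank(tab, k = 4)$index
    expect_equal(got, want)
  }
})

test_that("a label copy attains maximal relevance among all features", {
  set.seed(36)
  n <- 300
  X <- cbind(matrix(stats::rnorm(n * 3), n, 3),
             copy = rep(c(0, 1), length.out = n))
  tab <- feature_table(X, rep(c(0L, 1L), length.out = n))
  rel <- vapply(seq_len(4), function(j) relevance(tab, j), numeric(1))
  expect_equal(which.max(rel), 4L)
})

test_that("incremental subset verification finds a single separating feature", {
  set.seed(37)
  n <- 120
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(sep = y + stats::rnorm(n, sd = 0.05),
             noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
  tab <- feature_table(X, y)
  rk <- mrmr_rank(tab)
  expect_equal(rk$feature[1], "sep")
  out <- incremental_subset_accuracy(tab, rk, folds = 5, maxit = 80,
                                     seed = 2)
  expect_length(out$accuracy, 3)
  expect_equal(out$optimal_k, 1)
  expect_equal(out$features, "sep")
  out2 <- incremental_subset_accuracy(tab, rk, folds = 5, maxit = 80,
                                      seed = 2)
  expect_identical(out$accuracy, out2$accuracy)
})
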