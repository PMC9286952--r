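random_rbm <- function(m, n, seed = 1, scale = 0.8) {
  set.seed(seed)
  list(W = matrix(stats::rnorm(m * n, 0, scale), m, n),
       a = stats::rnorm(m, 0, scale), b = stats::rnorm(n, 0, scale))
}

test_that("the energy function follows its bilinear form", {
  p <- list(W = matrix(0, 2, 2), a = numeric(2), b = numeric(2))
  expect_equal(rbm_energy(p, c(1, 1), c(1, 0)), 0)
  p1 <- list(W = matrix(1, 1, 1), a = 0, b = 0)
  expect_equal(rbm_energy(p1, 1, 1), -1)
  # linearity in the visible bias
  p2 <- random_rbm(3, 2, seed = 2)
  v <- c(1, 0, 1)
  h <- c(0, 1)
  e1 <- rbm_energy(p2, v, h)
  p3 <- p2
  p3$a <- 2 * p2$a
  expect_equal(rbm_energy(p3, v, h) - e1, -sum(p2$a * v))
  expect_error(rbm_energy(p2, c(1, 0), h), "dimensions")
})

test_that("conditionals are sigmoids matching the exact enumeration oracle", {
  p0 <- list(W = matrix(0, 3, 2), a = numeric(3), b = numeric(2))
  expect_equal(unname(hidden_given_visible(p0, c(1, 0, 1))),
               matrix(0.5, 1, 2))
  expect_equal(unname(visible_given_hidden(p0, c(1, 0))),
               matrix(0.5, 1, 3))
  psat <- list(W = matrix(0, 1, 1), a = 0, b = 50)
  expect_gt(hidden_given_visible(psat, 1)[1], 1 - 1e-12)
  for (seed in 1:5) {
    p <- random_rbm(3, 2, seed = seed)
    for (v in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
      expect_equal(as.numeric(hidden_given_visible(p, v)),
                   oracle_hidden_conditional(p$W, p$a, p$b, v),
                   tolerance = 1e-12)
    }
    h <- c(1, 0)
    expect_equal(as.numeric(visible_given_hidden(p, h)),
                 oracle_visible_conditional(p$W, p$a, p$b, h),
                 tolerance = 1e-12)
    # transpose symmetry swaps the two conditionals
    pt <- list(W = t(p$W), a = p$b, b = p$a)
    expect_equal(hidden_given_visible(pt, h),
                 visible_given_hidden(p, h))
  }
})

test_that("the CD update reproduces the exact data term when sampling is off", {
  set.seed(41)
  p <- random_rbm(3, 2, seed = 6, scale = 0.5)
  batch <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0))
  alpha <- 0.25
  upd <- cd1_update(p, batch, alpha, sample_hidden = FALSE)
  # reconstruct the deterministic chain with the enumeration conditionals
  ph0 <- t(apply(batch, 1, function(v) {
    oracle_hidden_conditional(p$W, p$a, p$b, v)
  }))
  pv1 <- visible_given_hidden(p, ph0)
  ph1 <- hidden_given_visible(p, pv1)
  dW <- (crossprod(batch, ph0) - crossprod(pv1, ph1)) / nrow(batch)
  expect_equal(upd$W, p$W + alpha * dW, tolerance = 1e-12)
  expect_equal(upd$a, p$a + alpha * (colMeans(batch) - colMeans(pv1)),
               tolerance = 1e-12)
  expect_equal(upd$b, p$b + alpha * (colMeans(ph0) - colMeans(ph1)),
               tolerance = 1e-12)
  # a zero learning rate is a no-op
  same <- cd1_update(p, batch, 0, sample_hidden = FALSE)
  expect_equal(same, p)
  expect_error(cd1_update(p, batch[0, , drop = FALSE], 0.1), "empty")
})

test_that("repeated CD raises the model probability of the training vector", {
  p <- random_rbm(3, 2, seed = 9, scale = 0.1)
  v <- c(1, 0, 1)
  batch <- rbind(v, v, v, v)
  before <- oracle_visible_marginal(p$W, p$a, p$b, v)
  set.seed(10)
  for (i in 1:50) p <- cd1_update(p, batch, 0.2)
  after <- oracle_visible_marginal(p$W, p$a, p$b, v)
  expect_gt(after, before)
})

test_that("CD training is numerically stable over many updates", {
  p <- random_rbm(5, 4, seed = 12, scale = 0.01)
  set.seed(13)
  X <- matrix(stats::runif(5 * 8), 8, 5)
  for (i in 1:10000) p <- cd1_update(p, X, 0.1)
  expect_true(all(is.finite(p$W)) && all(is.finite(p$a)) &&
                all(is.finite(p$b)))
  probs <- hidden_given_visible(p, X)
  expect_true(all(probs > 0 & probs < 1))
})

test_that("layer-wise pretraining chains dimensions bottom-up", {
  set.seed(14)
  X <- matrix(stats::runif(40), 10, 4)
  cfg <- dbn_config(layers = c(6, 3), pretrain_epochs = 0)
  set.seed(15)
  rbms <- dbn_pretrain(X, cfg)
  expect_equal(dim(rbms[[1]]$W), c(4L, 6L))
  expect_equal(dim(rbms[[2]]$W), c(6L, 3L))
  # zero epochs leaves the seeded random initialization untouched
  set.seed(15)
  expect_equal(rbms[[1]], rbm_init(4, 6))
  # reconstruction error decreases with training on structured data
  set.seed(16)
  Xs <- matrix(rep(c(1, 0, 1, 0), each = 30), 30, 4) * 0.9 + 0.05
  recon_err <- function(p) {
    h <- hidden_given_visible(p, Xs)
    mean((visible_given_hidden(p, h) - Xs)^2)
  }
  set.seed(17)
  p0 <- rbm_init(4, 6)
  set.seed(18)
  p1 <- iaoadbn:::rbm_train(Xs, 6, epochs = 40, alpha = 0.3,
                            batch_size = 10)
  expect_lt(recon_err(p1), recon_err(p0))
})

test_that("the full classifier separates blobs and is seeded end-to-end", {
  b <- generate_blobs(240, 2, separation = 10, seed = 51)
  tr <- 1:160
  te <- 161:240
  cfg <- dbn_config(seed = 3)   # default configuration
  m1 <- dbn_train(b$values[tr, ], b$labels[tr], cfg)
  m2 <- dbn_train(b$values[tr, ], b$labels[tr], cfg)
  expect_identical(m1$weights, m2$weights)
  acc <- mean(predict(m1, b$values[te, ]) == b$labels[te])
  expect_gte(acc, 0.95)
  # capacity check: memorizes a tiny training set
  tiny <- generate_blobs(24, 2, separation = 6, seed = 52)
  mt <- dbn_train(tiny$values, tiny$labels,
                  dbn_config(pretrain_epochs = 10, finetune_epochs = 150,
                             batch_size = 8, seed = 4))
  expect_equal(mean(predict(mt, tiny$values) == tiny$labels), 1.0)
  expect_error(dbn_train(tiny$values, rep(1L, 24), cfg), "single class")
})

test_that("permuted labels give chance-level cross-validation accuracy", {
  b <- generate_blobs(200, 2, separation = 8, seed = 53)
  set.seed(54)
  null_tab <- feature_table(b$values, sample(b$labels))
  cv <- dbn_cv(null_tab, dbn_config(pretrain_epochs = 10,
                                    finetune_epochs = 40),
               folds = 5, seed = 55)
  expect_gt(cv$mean_accuracy, 0.35)
  expect_lt(cv$mean_accuracy, 0.65)
})

test_that("a trained model round-trips through its JSON archive", {
  b <- generate_blobs(60, 2, separation = 8, seed = 56)
  m <- dbn_train(b$values, b$labels,
                 dbn_config(layers = c(8, 4), pretrain_epochs = 5,
                            finetune_epochs = 30, seed = 6))
  path <- file.path(tempdir(), "dbn.json")
  save_dbn(m, path)
  m2 <- load_dbn(path)
  expect_equal(m2$weights$W, m$weights$W, tolerance = 1e-12)
  expect_identical(predict(m2, b$values), predict(m, b$values))
})
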