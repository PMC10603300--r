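test_that("network initialisation is seeded, symmetric and small", {
  n1 <- init_network(50, 10, seed = 1)
  n2 <- init_network(50, 10, seed = 1)
  n3 <- init_network(50, 10, seed = 2)
  expect_identical(n1, n2)
  expect_false(identical(n1$W1, n3$W1))
  r1 <- sqrt(6 / 60)
  expect_true(all(abs(n1$W1) <= r1))
  expect_true(all(abs(n1$b1) <= 0.5))
  expect_equal(n1$b2, 0)
  expect_equal(dim(n1$W1), c(10L, 50L))
  expect_equal(dim(n1$W2), c(1L, 10L))
})

test_that("forward pass matches hand-computed values and honours contracts", {
  net <- init_network(5, 3, seed = 1)
  net$W1[] <- 0; net$W2[] <- 0; net$b1[] <- 0; net$b2 <- 4.2
  expect_equal(forward(net, rnorm(5)), 4.2)
  expect_equal(forward(net, matrix(rnorm(15), 5)), rep(4.2, 3))

  # tiny 2-3-1 instance, hand-set weights
  net2 <- list(W1 = matrix(c(1, 0, -1, 0.5, 0.25, 0), 3, 2),
               b1 = c(0.1, -0.2, 0), W2 = matrix(c(2, -1, 0.5), 1), b2 = 0.3)
  class(net2) <- "shallow_net"
  x <- c(0.4, -0.8)
  h <- tanh(c(1 * 0.4 + 0.5 * (-0.8) + 0.1,
              0 * 0.4 + 0.25 * (-0.8) - 0.2,
              -1 * 0.4 + 0 * (-0.8) + 0))
  expect_equal(forward(net2, x), 2 * h[1] - 1 * h[2] + 0.5 * h[3] + 0.3)

  expect_error(forward(net2, rnorm(7)), "features")
})

test_that("backprop gradients match central finite differences on a 6-4-1 net", {
  set.seed(14)
  net <- init_network(6, 4)
  x <- matrix(rnorm(6 * 12), 6)
  y <- rnorm(12)
  g <- coupledraw:::net_loss_grad(net, x, y)$grad
  eps <- 1e-6
  num_grad <- function(getter, setter) {
    p <- getter(net)
    out <- p
    for (i in seq_along(p)) {
      np <- p; np[i] <- p[i] + eps
      up <- coupledraw:::net_mse(setter(net, np), x, y)
      np[i] <- p[i] - eps
      dn <- coupledraw:::net_mse(setter(net, np), x, y)
      out[i] <- (up - dn) / (2 * eps)
    }
    out
  }
  gW1 <- num_grad(function(n) n$W1, function(n, p) { n$W1 <- p; n })
  gb1 <- num_grad(function(n) n$b1, function(n, p) { n$b1 <- p; n })
  gW2 <- num_grad(function(n) n$W2, function(n, p) { n$W2 <- p; n })
  gb2 <- num_grad(function(n) n$b2, function(n, p) { n$b2 <- p; n })
  rel <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-8)
  expect_lt(rel(g$W1, gW1), 1e-5)
  expect_lt(rel(g$b1, gb1), 1e-5)
  expect_lt(rel(g$W2, gW2), 1e-5)
  expect_lt(rel(g$b2, gb2), 1e-5)
})

test_that("adaptive learning-rate rule raises lr on progress and cuts it on rejection", {
  set.seed(15)
  x <- matrix(rnorm(4 * 30), 4)
  y <- as.numeric(crossprod(x, c(1, -1, 0.5, 0)))
  net <- init_network(4, 3)
  cfg <- train_config(max_epochs = 5, patience = 100)
  fit <- train_network(net, x, y, x, y, cfg)
  tr <- fit$trace
  # progressing epochs multiply lr by lr_inc
  accepted_improving <- which(tr$accepted == 1 & c(TRUE, diff(tr$train_mse) < 0))
  expect_true(all(diff(log(tr$lr))[tr$accepted[-1] == 1] > log(cfg$lr_dec)))
  # force a rejection: gigantic lr makes the first step overshoot
  cfg2 <- train_config(lr0 = 1e4, max_epochs = 1, patience = 10)
  fit2 <- train_network(init_network(4, 3), x, y, x, y, cfg2)
  expect_equal(fit2$trace$accepted, 0)
  expect_equal(fit2$trace$lr, 1e4 * cfg2$lr_dec)
})

test_that("training learns a noiseless linear target and early stopping behaves", {
  set.seed(16)
  n <- 80
  x <- matrix(rnorm(8 * n), 8)
  w <- rnorm(8)
  y <- as.numeric(crossprod(x, w))
  idx <- sample(n)
  tr_i <- idx[1:60]; va_i <- idx[61:70]; te_i <- idx[71:80]
  net <- init_network(8, 6)
  fit <- train_network(net, x[, tr_i], y[tr_i], x[, va_i], y[va_i],
                       train_config(max_epochs = 1500, patience = 50))
  pred <- forward(fit$net, x[, te_i])
  expect_gt(cor(pred, y[te_i]), 0.99)
  # returned parameters are from the best-validation epoch
  expect_lte(fit$best_val_mse, min(fit$trace$val_mse) + 1e-12)
  expect_equal(coupledraw:::net_mse(fit$net, x[, va_i], y[va_i]),
               fit$best_val_mse)

  # patience 1 with degrading validation stops after one failing epoch
  set.seed(17)
  xb <- matrix(rnorm(3 * 20), 3)
  fitb <- train_network(init_network(3, 2), xb, rnorm(20),
                        matrix(rnorm(3 * 5), 3), rnorm(5) + 100,
                        train_config(patience = 1, max_epochs = 50))
  expect_equal(fitb$stop_reason, "early_stopping")

  expect_error(train_network(net, x[, tr_i], numeric(0), x[, va_i], y[va_i]),
               "non-empty")
})

test_that("feature scaling maps train range to [-1, 1] without clipping test data", {
  x <- rbind(seq(0, 10, length.out = 8), rep(3, 8), seq(-5, 5, length.out = 8))
  sc <- fit_feature_scaler(x)
  z <- sc$apply(x)
  expect_equal(range(z[1, ]), c(-1, 1))
  expect_equal(sc$apply(matrix(c(5, 3, 0), 3))[1, 1], 0)  # midpoint -> 0
  expect_equal(z[2, ], rep(0, 8))                         # constant -> 0
  test_x <- matrix(c(20, 3, 0), 3)
  expect_gt(sc$apply(test_x)[1, 1], 1)                    # no clipping
  # round-trip
  expect_equal(sc$invert(sc$apply(x)), x)
})

test_that("splits are exact, disjoint, and exhaustive", {
  set.seed(18)
  for (i in 1:25) {
    sp <- make_split(240)
    expect_length(sp$train, 204L)
    expect_length(sp$val, 12L)
    expect_length(sp$test, 24L)
    expect_length(intersect(sp$train, sp$val), 0L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_length(intersect(sp$val, sp$test), 0L)
    expect_setequal(c(sp$train, sp$val, sp$test), 1:240)
  }
})

test_that("minimum test appearances over many iterations is near-certain by the binomial tail", {
  # each trial enters the test set with probability 0.1 per iteration;
  # P(min appearances < 5 in 1000 iterations) is astronomically small
  p_single_low <- pbinom(4, 1000, 0.1)
  p_any_low <- 1 - (1 - p_single_low)^240
  expect_lt(p_any_low, 1e-20)
})

test_that("iterated splits are reproducible, leak-free, and average only test predictions", {
  set.seed(19)
  n <- 40
  x <- matrix(rnorm(12 * n), 12)
  y <- as.numeric(crossprod(x, rnorm(12))) + rnorm(n, 0, 0.2)
  y <- y - min(y) + 0.1   # positive, like a coupling index
  cfg <- train_config(max_epochs = 60)
  r1 <- iterate_splits(x, y, n_iter = 6, cfg = cfg, hidden_dim = 8,
                       seed = 5, min_appearances = 0)
  r2 <- iterate_splits(x, y, n_iter = 6, cfg = cfg, hidden_dim = 8,
                       seed = 5, min_appearances = 0)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$iterations$r_test, r2$iterations$r_test)

  # appearance bookkeeping: counts sum to iterations x test size
  expect_equal(sum(r1$predictions$n_test_appearances),
               r1$n_iter_total * length(r1$test_index_log[[1]]))

  # no leakage: a trial's appearance count equals how often it was in a
  # logged test set, and test sets never overlap train/val of their split
  counts <- integer(n)
  for (te in r1$test_index_log) counts[te] <- counts[te] + 1L
  expect_equal(counts, r1$predictions$n_test_appearances)

  # coverage extension path: with few iterations and a requirement of 1,
  # extension tops up until every trial was tested
  r3 <- suppressMessages(
    iterate_splits(x, y, n_iter = 4, cfg = cfg, hidden_dim = 8,
                   seed = 6, min_appearances = 1, max_extra_iter = 200))
  expect_true(all(r3$predictions$n_test_appearances >= 1))

  expect_error(
    iterate_splits(x, y, n_iter = 2, cfg = cfg, hidden_dim = 8,
                   seed = 7, min_appearances = 5, max_extra_iter = 0),
    "coverage not reached")
})
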