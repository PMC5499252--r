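# Helper: brute-force two-loop forward evaluation, independent of the
# vectorised implementation.
loop_forward <- function(w, x) {
  nh <- w$sizes[2]
  y <- numeric(nh)
  for (j in seq_len(nh)) {
    z <- w$b1[j]
    for (i in seq_len(w$sizes[1])) z <- z + w$w1[i, j] * x[i]
    y[j] <- 1 / (1 + exp(-z))
  }
  o <- w$b2[1]
  for (j in seq_len(nh)) o <- o + w$w2[j, 1] * y[j]
  list(hidden = y, output = o)
}

zero_weights <- function(sizes) {
  w <- init_weights(sizes, seed = 1)
  w$w1[] <- 0; w$b1[] <- 0; w$w2[] <- 0; w$b2[] <- 0
  w
}

test_that("forward pass follows sigmoid-hidden / linear-output algebra", {
  w <- zero_weights(c(3, 4, 1))
  fp <- forward_pass(w, c(1, -2, 5))
  expect_equal(as.vector(fp$hidden), rep(0.5, 4))
  expect_equal(fp$output[1, 1], 0)

  w1 <- zero_weights(c(1, 1, 1)); w1$w1[] <- 1; w1$w2[] <- 1
  expect_equal(forward_pass(w1, 0)$output[1, 1], 0.5)

  w14 <- init_weights(c(14, 10, 1), seed = 8)
  x <- rnorm(14)
  expect_equal(forward_pass(w14, x)$output[1, 1], loop_forward(w14, x)$output,
               tolerance = 1e-12)
  expect_error(forward_pass(w14, rnorm(5)), "expects 14")
})

test_that("weighted MSE matches its documented formula", {
  w <- zero_weights(c(2, 3, 1))
  X <- matrix(rnorm(6), 3, 2)
  # outputs are identically 0; with b2 = t the loss vanishes
  w$b2[] <- 0.7
  expect_equal(mse_loss(w, X, rep(0.7, 3)), 0)
  # one sample, O = 1, T = 0, unit cost
  w$b2[] <- 1
  expect_equal(mse_loss(w, X[1, , drop = FALSE], 0), 1)
  # errors (1, 0) with class costs (HC = 2, AD = 1): weighted mean 2/3
  expect_equal(mse_loss(w, X[1:2, ], c(0, 1), class_costs = c(HC = 2, AD = 1)),
               2 / 3)
  expect_error(mse_loss(w, X, c(0, 1)), "targets")
})

test_that("analytic gradients match central finite differences", {
  worst <- 0
  for (i in 1:20) {
    set.seed(100 + i)
    ni <- sample(2:6, 1); nh <- sample(2:5, 1); ns <- sample(3:8, 1)
    w <- init_weights(c(ni, nh, 1), seed = i)
    X <- matrix(rnorm(ns * ni), ns, ni)
    tg <- sample(0:1, ns, replace = TRUE)
    cc <- c(HC = runif(1, 0.5, 2), AD = runif(1, 0.5, 2))
    g <- dtcwtcad:::.flatten(fnn_gradient(w, X, tg, cc))
    v <- dtcwtcad:::.flatten(w)
    fd <- vapply(seq_along(v), function(j) {
      e <- v; e[j] <- v[j] + 1e-6
      f1 <- mse_loss(dtcwtcad:::.unflatten(e, w), X, tg, cc)
      e[j] <- v[j] - 1e-6
      f0 <- mse_loss(dtcwtcad:::.unflatten(e, w), X, tg, cc)
      (f1 - f0) / 2e-6
    }, numeric(1))
    worst <- max(worst, max(abs(g - fd) / pmax(abs(fd), 1e-4)))
  }
  expect_lt(worst, 1e-6)
})

test_that("gradient vanishes at a perfect fit and scales out of the costs", {
  w <- zero_weights(c(2, 2, 1)); w$b2[] <- 0.3
  X <- matrix(rnorm(8), 4, 2)
  g <- fnn_gradient(w, X, rep(0.3, 4))
  expect_lt(max(abs(dtcwtcad:::.flatten(g))), 1e-14)
  # doubling every cost leaves the gradient unchanged (weighted mean)
  w2 <- init_weights(c(3, 2, 1), seed = 5)
  X2 <- matrix(rnorm(15), 5, 3); tg <- c(0, 1, 1, 0, 1)
  g1 <- dtcwtcad:::.flatten(fnn_gradient(w2, X2, tg, c(HC = 1, AD = 3)))
  g2 <- dtcwtcad:::.flatten(fnn_gradient(w2, X2, tg, c(HC = 2, AD = 6)))
  expect_equal(g1, g2, tolerance = 1e-14)
})

test_that("SCG solves XOR for most seeds within 500 iterations", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  tg <- c(0, 1, 1, 0)
  solved <- 0
  for (s in 1:10) {
    fit <- train_scg(X, tg, sizes = c(2, 2, 1),
                     config = scg_config(max_iterations = 500, mse_goal = 0.009,
                                         seed = s))
    if (tail(fit$trace, 1) < 0.01) solved <- solved + 1
  }
  expect_gte(solved, 8)
})

test_that("SCG separates well-separated Gaussian classes perfectly", {
  set.seed(61)
  X <- rbind(matrix(rnorm(200, mean = 0), 100, 2),
             matrix(rnorm(200, mean = 6), 100, 2))
  tg <- rep(c(0, 1), each = 100)
  fit <- train_scg(X, tg, sizes = c(2, 4, 1),
                   config = scg_config(max_iterations = 300, seed = 3))
  expect_identical(mean(fnn_classify(fit$weights, X) ==
                          ifelse(tg == 1, "AD", "HC")), 1)
})

test_that("a 14-10-1 network can overfit 20 random labellings", {
  set.seed(17)
  X <- matrix(rnorm(20 * 14), 20, 14)
  tg <- sample(0:1, 20, replace = TRUE)
  fit <- train_scg(X, tg, sizes = c(14, 10, 1),
                   config = scg_config(max_iterations = 2000, mse_goal = 1e-6,
                                       seed = 2))
  expect_identical(mean(fnn_classify(fit$weights, X) ==
                          ifelse(tg == 1, "AD", "HC")), 1)
})

test_that("training is seeded-deterministic with a non-increasing trace", {
  set.seed(71)
  X <- matrix(rnorm(40 * 5), 40, 5)
  tg <- as.numeric(X[, 1] + 0.3 * rnorm(40) > 0)
  cfg <- scg_config(max_iterations = 200, seed = 12, class_costs = "balanced")
  f1 <- train_scg(X, tg, sizes = c(5, 4, 1), config = cfg)
  f2 <- train_scg(X, tg, sizes = c(5, 4, 1), config = cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(dtcwtcad:::.flatten(f1$weights), dtcwtcad:::.flatten(f2$weights))
  expect_true(all(diff(f1$trace) <= 1e-12))
  # zero-iteration training returns the seeded initial weights untouched
  f0 <- train_scg(X, tg, sizes = c(5, 4, 1),
                  config = scg_config(max_iterations = 0, seed = 12))
  expect_identical(dtcwtcad:::.flatten(f0$weights),
                   dtcwtcad:::.flatten(init_weights(c(5, 4, 1), seed = 12)))
  expect_length(f0$trace, 1L)
})

test_that("classification thresholds label AD at or above the cut", {
  # zero first layer: hidden = sigmoid(0) = 0.5, so output = 0.5 * w2
  w <- zero_weights(c(1, 1, 1))
  X <- matrix(c(0, 0), 2, 1)
  w$w2[] <- 1.8                       # outputs exactly 0.9
  expect_equal(forward_pass(w, X)$output[, 1], c(0.9, 0.9))
  expect_identical(fnn_classify(w, X, threshold = 0.5), c("AD", "AD"))
  w$w2[] <- 0.2                       # outputs exactly 0.1
  expect_identical(fnn_classify(w, X, threshold = 0.5), c("HC", "HC"))
  expect_identical(fnn_classify(w, X, threshold = 0), c("AD", "AD"))
  # an output exactly at the threshold is labelled AD
  w$w2[] <- 1
  expect_identical(fnn_classify(w, X, threshold = 0.5), c("AD", "AD"))
})
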