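test_that("hidden matrix applies the activation to affine projections", {
  X <- matrix(0, 3, 2)
  H <- hidden_matrix(X, matrix(0, 4, 2), rep(0, 4))
  expect_equal(H, matrix(0.5, 3, 4))  # sigmoid(0) = 0.5
  # hand-computed 2 x 2
  X2 <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2, byrow = TRUE)
  w <- matrix(c(1, -1, 0.5, 0.5), 2, 2, byrow = TRUE)
  b <- c(0, 0.1)
  Z <- X2 %*% t(w) + rep(b, each = 2)
  expect_equal(hidden_matrix(X2, w, b), 1 / (1 + exp(-Z)))
  expect_equal(hidden_matrix(X2, w, b, "tanh"), tanh(Z))
  expect_error(hidden_matrix(X2, matrix(1, 2, 3), b), "input dimension")
})

test_that("output weights solve minimum-norm least squares", {
  T_ <- c(1, 2, 3)
  expect_equal(as.numeric(solve_output_weights(diag(3), T_)), T_)
  H <- withr::with_seed(1, matrix(runif(16), 4, 4))
  beta <- solve_output_weights(H, 1:4)
  expect_equal(as.numeric(H %*% beta), 1:4, tolerance = 1e-8)
  # overdetermined: agree with the normal-equations solution
  H2 <- withr::with_seed(2, matrix(runif(60), 20, 3))
  y <- withr::with_seed(3, runif(20))
  beta2 <- solve_output_weights(H2, y)
  oracle <- solve(t(H2) %*% H2, t(H2) %*% y)
  expect_equal(as.numeric(beta2), as.numeric(oracle), tolerance = 1e-6)
  # residual orthogonality of the least-squares solution
  expect_lt(max(abs(t(H2) %*% (H2 %*% beta2 - y))), 1e-6 * sqrt(sum(y^2)))
})

test_that("L = N gives exact interpolation across seeds", {
  # random square hidden matrices are occasionally near-singular; such
  # draws are re-drawn, as interpolation presumes a full-rank H
  full_rank <- function(m, w) {
    X <- (w$inputs - m$x_scaler$min) / m$x_scaler$range
    H <- hidden_matrix(X, m$w, m$b)
    d <- svd(H)$d
    d[length(d)] / d[1] > 1e-8
  }
  checked <- 0L
  s <- 0L
  while (checked < 10L && s < 40L) {
    s <- s + 1L
    w <- withr::with_seed(s, list(inputs = matrix(runif(20 * 3), 20, 3),
                                  targets = runif(20)))
    m <- train_elm(w, L = 20, seed = s)
    if (!full_rank(m, w)) next
    checked <- checked + 1L
    expect_lt(m$training_rmse, 1e-6)
  }
  expect_gte(checked, 10L)
})

test_that("predictions scale linearly with the targets", {
  w <- withr::with_seed(4, list(inputs = matrix(runif(60), 30, 2),
                                targets = runif(30)))
  m1 <- train_elm(w, L = 10, seed = 5, scale = FALSE)
  w2 <- w; w2$targets <- 3 * w$targets
  m2 <- train_elm(w2, L = 10, seed = 5, scale = FALSE)
  expect_equal(m2$beta, 3 * m1$beta, tolerance = 1e-8)
  newX <- matrix(runif(10), 5, 2)
  expect_equal(predict(m2, newX), 3 * predict(m1, newX), tolerance = 1e-7)
  # zero targets give (numerically) zero predictions via minimum norm
  w0 <- w; w0$targets <- rep(0, 30)
  m0 <- train_elm(w0, L = 10, seed = 5, scale = FALSE)
  expect_lt(max(abs(predict(m0, newX))), 1e-10)
})

test_that("a smooth function is approximated well out of sample", {
  x <- seq(0, 1, length.out = 100)
  w <- list(inputs = matrix(x, ncol = 1), targets = 2 * x)
  m <- train_elm(w, L = 20, seed = 6)
  xt <- seq(0.01, 0.99, length.out = 50)
  expect_lt(sqrt(mean((predict(m, matrix(xt, ncol = 1)) - 2 * xt)^2)), 0.01)
})

test_that("elm models serialize to flat text and read back", {
  w <- withr::with_seed(7, list(inputs = matrix(runif(40), 20, 2),
                                targets = runif(20)))
  m <- train_elm(w, L = 5, seed = 8)
  path <- withr::local_tempfile(fileext = ".txt")
  write_elm(m, path)
  m2 <- read_elm(path)
  expect_equal(predict(m2, w$inputs), predict(m, w$inputs))
})

test_that("WOA tuning is seeded, never worse than its starting population", {
  w <- withr::with_seed(10, {
    x <- as.numeric(stats::arima.sim(list(ar = c(0.6, 0.2)), 120))
    make_windows(x - min(x) + 1, 4)
  })
  m1 <- train_woa_elm(w, L = 8, n_agents = 5, max_iter = 15, seed = 3)
  m2 <- train_woa_elm(w, L = 8, n_agents = 5, max_iter = 15, seed = 3)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$woa_history, m2$woa_history)
  # best-so-far history is monotone, so the final model cannot be worse
  # than the best initial candidate
  expect_true(all(diff(m1$woa_history) <= 0))
  expect_lte(m1$validation_rmse, m1$woa_history[1])
})

test_that("WOA-tuned hidden layers beat random ones on held-out windows", {
  # paired seeds; the tuned model's validation RMSE uses the same
  # chronological tail an untuned ELM is scored on
  wins <- 0L
  for (s in 1:10) {
    w <- withr::with_seed(s, {
      x <- as.numeric(stats::arima.sim(list(ar = c(0.6, 0.2)), 150))
      make_windows(x - min(x) + 1, 4)
    })
    N <- length(w$targets); n_fit <- N - floor(0.2 * N)
    w_fit <- list(inputs = w$inputs[1:n_fit, ], targets = w$targets[1:n_fit])
    m_plain <- train_elm(w_fit, L = 8, seed = s)
    pred <- predict(m_plain, w$inputs[(n_fit + 1):N, ])
    rmse_plain <- sqrt(mean((pred - w$targets[(n_fit + 1):N])^2))
    m_woa <- train_woa_elm(w, L = 8, n_agents = 5, max_iter = 15, seed = s)
    if (m_woa$validation_rmse <= rmse_plain) wins <- wins + 1L
  }
  expect_gte(wins, 6)
})

test_that("invalid training requests error early", {
  w <- list(inputs = matrix(1:10, 5, 2), targets = 1:5)
  expect_error(train_elm(w, L = 0), "L")
  expect_error(train_woa_elm(w, L = 2, val_fraction = 1), "val_fraction")
})
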