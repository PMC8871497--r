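test_that("fixed-lambda solve matches the closed-form stationary point", {
  # K = I, no covariates, n = 2: (K + n lambda1 I) alpha = Y with factor 2
  sol <- solve_fixed_lambda(c(2, 4), NULL, diag(2), lambda1 = 0.5)
  expect_equal(sol$alpha, c(1, 2), tolerance = 1e-10)
  expect_equal(sol$h_hat, c(1, 2), tolerance = 1e-10)

  expect_error(solve_fixed_lambda(c(1, 2), NULL, diag(2), lambda1 = -1),
               "positive")
  expect_error(solve_fixed_lambda(rnorm(5), matrix(1, 5, 2), diag(5), 1),
               "rank deficient")
})

test_that("infinite smoothing collapses to ordinary least squares", {
  set.seed(31)
  tp <- toy_kernel_problem(n = 40)
  K <- kernel_matrix(tp$Z, 1)
  sol <- solve_fixed_lambda(tp$y, tp$x, K, lambda1 = 1e8)
  expect_lt(max(abs(sol$h_hat)), 1e-4)
  ols <- coef(lm(tp$y ~ tp$x - 1))
  expect_equal(unname(sol$beta), unname(ols), tolerance = 1e-4)
})

test_that("the returned solution is a local minimum of the penalized loss", {
  set.seed(32)
  tp <- toy_kernel_problem(n = 25)
  K <- kernel_matrix(tp$Z, 1)
  lam1 <- 0.05
  sol <- solve_fixed_lambda(tp$y, tp$x, K, lam1)
  objective <- function(beta, alpha) {
    r <- tp$y - drop(tp$x %*% beta) - drop(K %*% alpha)
    sum(r^2) / (2 * tp$n) + (lam1 / 2) * sum(alpha * drop(K %*% alpha))
  }
  o0 <- objective(sol$beta, sol$alpha)
  for (i in 1:100) {
    expect_gte(objective(sol$beta + rnorm(1, sd = 0.01),
                         sol$alpha + rnorm(tp$n, sd = 0.01)), o0 - 1e-12)
  }
})

test_that("REML route and fixed-lambda route agree at the REML optimum", {
  set.seed(33)
  tp <- toy_kernel_problem(n = 60)
  K <- kernel_matrix(tp$Z, 1)
  rf <- reml_fit(tp$y, tp$x, K)
  sf <- solve_fixed_lambda(tp$y, tp$x, K + diag(1e-10, tp$n), rf$lambda1)
  expect_lt(max(abs(rf$beta - sf$beta)), 1e-6)
  expect_lt(max(abs(rf$alpha - sf$alpha)), 1e-6)
  expect_lt(max(abs(rf$h_hat - drop(K %*% rf$alpha))), 1e-6)
  expect_equal(rf$lambda1, rf$sigma2 / (tp$n * rf$tau), tolerance = 1e-8)
})

test_that("REML optimum beats a surrounding grid of variance ratios", {
  set.seed(34)
  tp <- toy_kernel_problem(n = 50)
  K <- kernel_matrix(tp$Z, 1)
  rf <- reml_fit(tp$y, tp$x, K)
  # rebuild the profiled criterion and scan around the optimum
  eigK <- eigen(K + diag(1e-10, tp$n), symmetric = TRUE)
  d <- pmax(eigK$values, 0); U <- eigK$vectors
  Yt <- drop(crossprod(U, tp$y)); Xt <- crossprod(U, tp$x)
  crit <- function(th) {
    v <- th * d + 1
    A <- crossprod(Xt, Xt / v)
    r <- Yt - drop(Xt %*% solve(A, crossprod(Xt, Yt / v)))
    s2 <- sum(r^2 / v) / (tp$n - 1)
    -0.5 * ((tp$n - 1) * log(s2) + sum(log(v)) +
              determinant(A, logarithm = TRUE)$modulus)
  }
  th_hat <- rf$tau / rf$sigma2
  grid <- th_hat * exp(seq(-1, 1, length.out = 20))
  expect_gte(crit(th_hat) + 1e-6, max(vapply(grid, crit, 0)))
})

test_that("degenerate kernels are flagged", {
  set.seed(35)
  y <- rnorm(30); x <- matrix(rnorm(30), 30, 1)
  expect_warning(reml_fit(y, x, diag(30)), "unidentifiable")

  # exact linear outcome: no kernel effect
  y0 <- drop(2 * x)
  K <- kernel_matrix(matrix(runif(60), 30, 2), 1)
  expect_warning(reml_fit(y0, x, K), "no kernel effect")
})

test_that("predictions combine fixed effects and the kernel part", {
  set.seed(36)
  tp <- toy_kernel_problem(n = 40)
  K <- kernel_matrix(tp$Z, 1)
  rf <- reml_fit(tp$y, tp$x, K)
  expect_equal(predict_lskm(rf, tp$x, K), rf$fitted, tolerance = 1e-8)

  rf0 <- rf; rf0$alpha <- rep(0, tp$n)
  expect_equal(predict_lskm(rf0, tp$x, K), drop(tp$x %*% rf$beta),
               tolerance = 1e-12)
})

test_that("oracle kernel machine predicts Scenario-2 test outcomes well", {
  sim <- simulate_dataset(scenario_config(2, n_subjects = 600), seed = 37)
  tr <- sim$train_index; te <- sim$test_index
  Zs <- sim$true_zeta[, sim$signal_features]
  K <- kernel_matrix(Zs[tr, ], 1, p = 5)
  f <- reml_fit(sim$scalars$y[tr], matrix(sim$scalars$x[tr], ncol = 1), K)
  Kc <- kernel_cross(Zs[te, ], Zs[tr, ], 1, p = 5)
  pred <- predict_lskm(f, matrix(sim$scalars$x[te], ncol = 1), Kc)
  expect_gt(quasi_r2(sim$scalars$y[te], pred), 0.8)
})
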