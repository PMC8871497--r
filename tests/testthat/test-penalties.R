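test_that("penalty values match closed forms across families", {
  sp_g <- penalty_spec("group_lasso", groups = 2)
  expect_equal(penalty_value(c(3, 4), sp_g), 5)

  for (fam in c("lasso", "group_lasso", "sgl", "mcp", "group_mcp")) {
    sp <- penalty_spec(fam, groups = c(2, 2))
    expect_equal(penalty_value(rep(0, 4), sp), 0)
  }

  v <- c(1, -2, 0.5, 3)
  sp0 <- penalty_spec("sgl", groups = c(2, 2), delta = 0)
  expect_equal(penalty_value(v, sp0),
               penalty_value(v, penalty_spec("group_lasso", groups = c(2, 2))))
  sp1 <- penalty_spec("sgl", groups = c(2, 2), delta = 1)
  expect_equal(penalty_value(v, sp1),
               penalty_value(v, penalty_spec("lasso", groups = c(2, 2))))

  expect_error(penalty_spec("sgl", groups = 4, delta = 1.2), "delta")
})

test_that("proximal operators match their closed forms", {
  spl <- penalty_spec("lasso", groups = 1)
  expect_equal(prox(3, 1, spl), 2)
  expect_equal(prox(-3, 1, spl), -2)
  expect_equal(prox(0.5, 1, spl), 0)

  spg <- penalty_spec("group_lasso", groups = 2)
  expect_equal(prox(c(3, 4), 5, spg), c(0, 0))
  expect_equal(prox(c(3, 4), 2.5, spg), c(1.5, 2))

  # SGL prox composes soft-threshold and group shrink
  sps <- penalty_spec("sgl", groups = 2, delta = 0.5)
  v <- c(3, 4)
  st <- pmax(abs(v) - 0.5 * 2, 0) * sign(v)
  gn <- sqrt(sum(st^2))
  expect_equal(prox(v, 2, sps), st * max(1 - 0.5 * 2 / gn, 0))

  # MCP firm threshold: zero, interior, identity regions
  spm <- penalty_spec("mcp", groups = 1, mcp_a = 3)
  expect_equal(prox(0.5, 1, spm, lambda = 1), 0)
  expect_equal(prox(1.5, 1, spm, lambda = 1), 0.75)
  expect_equal(prox(4, 1, spm, lambda = 1), 4)
})

test_that("convex proximal operators are non-expansive", {
  set.seed(41)
  for (fam in c("lasso", "group_lasso", "sgl")) {
    sp <- penalty_spec(fam, groups = c(3, 3))
    for (i in 1:20) {
      u <- rnorm(6); v <- rnorm(6)
      expect_lte(sqrt(sum((prox(u, 0.7, sp) - prox(v, 0.7, sp))^2)),
                 sqrt(sum((u - v)^2)) + 1e-12)
    }
  }
})

test_that("path solver reproduces least squares and the all-zero endpoint", {
  set.seed(42)
  X <- matrix(rnorm(60 * 5), 60, 5)
  b_true <- c(2, 0, -1, 0, 0.5)
  y <- drop(X %*% b_true) + rnorm(60, sd = 0.3)
  sp <- penalty_spec("lasso", groups = rep(1, 5))

  fit0 <- solve_penalized_ls(X, y, sp, lambda = 1e-10)
  expect_equal(drop(fit0$beta), unname(coef(lm(y ~ X - 1))), tolerance = 1e-5)

  lmax <- fkmr:::lambda_max_value(X, y, sp)
  fitmax <- solve_penalized_ls(X, y, sp, lambda = lmax * 1.0001)
  expect_equal(drop(fitmax$beta), rep(0, 5))
  fit_over <- solve_penalized_ls(X, y, sp, lambda = lmax * 0.95)
  expect_gt(max(abs(fit_over$beta)), 0)
})

test_that("all-zero bound is exact for the sparse group lasso too", {
  set.seed(43)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- rnorm(50) + X[, 2]
  sp <- penalty_spec("sgl", groups = c(3, 3), delta = 0.3)
  lmax <- fkmr:::lambda_max_value(X, y, sp)
  expect_equal(drop(solve_penalized_ls(X, y, sp, lambda = lmax * 1.001)$beta),
               rep(0, 6))
  expect_gt(max(abs(solve_penalized_ls(X, y, sp, lambda = lmax * 0.97)$beta)), 0)
})

test_that("lasso on an orthonormal design equals soft-thresholded OLS", {
  set.seed(44)
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * 8), n, 8))) * sqrt(n) # columns: X'X = n I
  b_true <- c(3, -2, 1.5, 0, 0, 0.8, 0, 0)
  y <- drop(Q %*% b_true) + rnorm(n, sd = 0.2)
  sp <- penalty_spec("lasso", groups = rep(1, 8))
  ols <- drop(crossprod(Q, y)) / n
  for (lam in c(0.1, 0.5, 1.5)) {
    fit <- solve_penalized_ls(Q, y, sp, lambda = lam)
    expect_lt(max(abs(drop(fit$beta) - sign(ols) * pmax(abs(ols) - lam, 0))),
              1e-8)
  }
})

test_that("objective is non-increasing along the proximal-gradient run", {
  set.seed(45)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  for (fam in c("lasso", "sgl", "group_lasso")) {
    sp <- penalty_spec(fam, groups = c(3, 3), delta = 0.4)
    lam <- 0.2
    objs <- vapply(c(1, 2, 5, 10, 50, 200), function(k) {
      b <- drop(solve_penalized_ls(X, y, sp, lambda = lam, max_iter = k)$beta)
      sum((y - X %*% b)^2) / (2 * 40) + lam * penalty_value(b, sp)
    }, 0)
    expect_true(all(diff(objs) <= 1e-10))
  }
})

test_that("cross-validation selects sensible penalty levels", {
  set.seed(46)
  X <- matrix(rnorm(80 * 6), 80, 6)
  sp <- penalty_spec("lasso", groups = rep(1, 6))

  hits_null <- 0; hits_sig <- 0
  for (i in 1:10) {
    y_null <- rnorm(80)
    cv <- cv_lambda(X, y_null, sp, folds = 5)
    if (cv$index <= 10) hits_null <- hits_null + 1 # largest decile of the path

    y_sig <- 3 * X[, 1] + rnorm(80, sd = 0.5)
    cv2 <- cv_lambda(X, y_sig, sp, folds = 5)
    b <- solve_penalized_ls(X, y_sig, sp, lambda = cv2$lambda)$beta[, cv2$index]
    if (abs(b[1]) > 1e-8) hits_sig <- hits_sig + 1
  }
  expect_gte(hits_null, 8)
  expect_gte(hits_sig, 10)

  set.seed(7); a <- cv_lambda(X, rnorm(80), sp, folds = 4)
  set.seed(7); b <- cv_lambda(X, rnorm(80), sp, folds = 4)
  expect_identical(a$fold_id, b$fold_id)
  expect_error(cv_lambda(X[1:3, ], rnorm(3), sp, folds = 5), "folds")
})
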