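test_that("penalized objective reduces to its closed-form pieces", {
  set.seed(51)
  tp <- toy_kernel_problem(n = 20)
  sp <- penalty_spec("sgl", groups = c(2, 2), delta = 0.3)
  gam <- runif(4)
  j2 <- objective_J2(tp$y, NULL, tp$Z, numeric(0), rep(0, 20), gam,
                     lambda1 = 0.1, lambda2 = 0.7, sp)
  expect_equal(j2, sum(tp$y^2) / 40 + 0.7 * penalty_value(gam, sp),
               tolerance = 1e-12)

  # lambda2 = 0 at fixed gamma matches the kernel-machine loss
  K <- kernel_matrix(tp$Z, gam)
  sol <- solve_fixed_lambda(tp$y, tp$x, K, 0.1)
  loss <- sum((tp$y - sol$fitted)^2) / 40 +
    0.05 * sum(sol$alpha * drop(K %*% sol$alpha))
  expect_equal(objective_J2(tp$y, tp$x, tp$Z, sol$beta, sol$alpha, gam,
                            0.1, 0, sp), loss, tolerance = 1e-10)
})

test_that("the gamma subproblem differs from J2 by a gamma-constant", {
  set.seed(52)
  tp <- toy_kernel_problem(n = 15)
  sp <- penalty_spec("sgl", groups = c(2, 2), delta = 0.5)
  alpha <- rnorm(15, sd = 0.2); beta <- 1.4; lam1 <- 0.2; lam2 <- 0.3
  Y_tilde <- tp$y - drop(tp$x * beta) - (15 * lam1 / 2) * alpha
  diffs <- replicate(50, {
    gam <- rnorm(4)
    j2 <- objective_J2(tp$y, tp$x, tp$Z, beta, alpha, gam, lam1, lam2, sp)
    e7 <- fkmr:::obj_gamma(Y_tilde, tp$Z, alpha, gam, lam2, sp, 4)
    j2 - e7
  })
  expect_lt(sd(diffs), 1e-9 * max(abs(diffs)))
})

test_that("linearization has the right shapes, degenerate case and Taylor order", {
  set.seed(53)
  tp <- toy_kernel_problem(n = 18)
  gam <- runif(4, 0.5, 1.5)

  lin0 <- linearize(tp$y, tp$x, tp$Z, 2, rep(0, 18), gam, 0.1)
  expect_equal(lin0$design, matrix(0, 18, 4))
  expect_equal(lin0$response, tp$y - drop(tp$x * 2), tolerance = 1e-12)

  alpha <- rnorm(18, sd = 0.3)
  lin <- linearize(tp$y, tp$x, tp$Z, 2, alpha, gam, 0.1)
  expect_equal(dim(lin$design), c(18L, 4L))
  expect_length(lin$response, 18)

  # halving the perturbation shrinks the linearization error ~4x
  dirn <- rnorm(4); dirn <- dirn / sqrt(sum(dirn^2))
  err <- vapply(c(0.1, 0.05, 0.025), function(h) {
    Fg <- drop(kernel_matrix(tp$Z, gam + h * dirn) %*% alpha)
    Fl <- lin$F_ref + drop(lin$design %*% (h * dirn))
    sqrt(sum((Fg - Fl)^2))
  }, 0)
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)

  expect_error(linearize(tp$y, tp$x, tp$Z, 2, c(NA, alpha[-1]), gam, 0.1),
               "non-finite")
})

test_that("gamma update shrinks to zero under a dominating penalty", {
  set.seed(54)
  tp <- toy_kernel_problem(n = 20)
  sp <- penalty_spec("sgl", groups = c(2, 2), delta = 0.5)
  alpha <- rnorm(20, sd = 0.2)
  lin <- linearize(tp$y, tp$x, tp$Z, 1.5, alpha, rep(1, 4), 0.1)
  lmax <- fkmr:::lambda_max_value(lin$design, lin$response, sp, 20)
  up <- update_gamma(tp$y, tp$x, tp$Z, 1.5, alpha, rep(1, 4), 0.1,
                     lambda2 = lmax * 10, sp)
  expect_equal(up$gamma, rep(0, 4))
  expect_true(all(diff(up$trace) <= 1e-10))
})

test_that("unpenalized scalar gamma update matches a grid search", {
  set.seed(55)
  n <- 20
  Z <- matrix(runif(n), n, 1)
  alpha <- rnorm(n, sd = 0.5)
  y <- rnorm(n)
  sp <- penalty_spec("lasso", groups = 1)
  lam1 <- 0.05
  up <- update_gamma(y, NULL, Z, numeric(0), alpha, 1, lam1, 1e-12, sp,
                     max_iter = 100)
  Y_tilde <- y - (n * lam1 / 2) * alpha
  obj1 <- function(g) sum((drop(kernel_matrix(Z, g, 1) %*% alpha) - Y_tilde)^2) / (2 * n)
  grid <- seq(0, 4, by = 0.005)
  gstar <- grid[which.min(vapply(grid, obj1, 0))]
  expect_lt(min(abs(abs(up$gamma) - gstar)), 0.05)
})

test_that("fitted values are invariant to gamma sign flips", {
  set.seed(56)
  tp <- toy_kernel_problem(n = 25)
  gam <- runif(4, 0.5, 1.5)
  flip <- gam * c(1, -1, 1, -1)
  expect_equal(kernel_matrix(tp$Z, gam), kernel_matrix(tp$Z, flip),
               tolerance = 1e-15)
  K <- kernel_matrix(tp$Z, gam)
  sol <- solve_fixed_lambda(tp$y, tp$x, K, 0.1)
  expect_equal(predict_lskm(sol, tp$x, kernel_cross(tp$Z, tp$Z, flip)),
               sol$fitted, tolerance = 1e-10)
})

test_that("selection sets respond to the zero threshold as expected", {
  expect_equal(selected_features(rep(0, 6), c(3, 3))$features, integer(0))
  expect_equal(selected_features(rep(0, 6), c(3, 3))$groups, integer(0))
  s1 <- selected_features(c(0, 0, 0, 0, 0, 1), c(3, 3))
  expect_equal(s1$features, 6L)
  expect_equal(s1$groups, 2L)
  g <- c(0.5, 1e-7, 0.2, 0, 2, 0.05)
  tols <- c(1e-8, 1e-4, 0.1, 1)
  sizes <- vapply(tols, function(tl)
    length(selected_features(g, c(3, 3), tl)$features), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("full fit on a small Scenario-2 dataset behaves coherently", {
  sim <- tiny_scenario2(n = 150, seed = 57)
  feats <- fpca_features(sim$curves, n_components = 9,
                         train_index = sim$train_index)
  tr <- sim$train_index
  set.seed(57)
  fit <- fkmr_fit(feats$blocks$matrix[tr, ], sim$scalars$y[tr],
                  matrix(sim$scalars$x[tr], ncol = 1),
                  groups = sim$group_sizes, n_lambda2 = 6,
                  scale_grid = c(1, 4))
  expect_s3_class(fit, "fkmr_fit")
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  expect_true(all(diff(fit$inner_trace) <= 1e-8))
  expect_true(all(fit$gamma >= 0))
  expect_identical(sort(unique(rep(1:4, each = 9)[fit$selected$features])),
                   fit$selected$groups)

  pr_tr <- predict(fit, feats$blocks$matrix[tr, ],
                   matrix(sim$scalars$x[tr], ncol = 1))
  expect_equal(pr_tr, fit$fitted, tolerance = 1e-10)

  td <- tidy(fit)
  expect_identical(nrow(td), 36L)
  expect_identical(sum(td$selected), length(fit$selected$features))
  gl <- glance(fit)
  expect_identical(gl$n_selected, length(fit$selected$features))
  expect_output(print(fit), "kernel machine")
})

test_that("pure-noise outcomes yield (near-)empty selections", {
  set.seed(58)
  hits <- 0
  for (i in 1:5) {
    n <- 120
    Z <- matrix(runif(n * 8), n, 8)
    y <- rnorm(n)
    fit <- fkmr_fit(Z, y, groups = c(4, 4), n_lambda2 = 6, scale_grid = c(1, 4))
    if (length(fit$selected$groups) == 0) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("grid-based and operational fits select the same signal groups", {
  sim <- tiny_scenario2(n = 300, seed = 59)
  feats <- fpca_features(sim$curves, n_components = 9,
                         train_index = sim$train_index)
  tr <- sim$train_index
  x_tr <- matrix(sim$scalars$x[tr], ncol = 1)
  set.seed(59)
  fit2 <- fkmr_fit(feats$blocks$matrix[tr, ], sim$scalars$y[tr], x_tr,
                   groups = sim$group_sizes, n_lambda2 = 8)
  set.seed(59)
  fit1 <- fkmr_fit_grid(feats$blocks$matrix[tr, ], sim$scalars$y[tr], x_tr,
                        groups = sim$group_sizes,
                        lambda2_grid = fit2$lambda2 * c(0.5, 1, 2),
                        cv_folds = 2, max_outer = 5)
  expect_true(all(diff(fit1$objective_trace) <= 1e-8))
  # both algorithms recover the same signal groups (the grid fit may keep
  # additional small-magnitude scalings at its converged stationary point)
  expect_identical(intersect(fit1$selected$groups, sim$signal_groups),
                   intersect(fit2$selected$groups, sim$signal_groups))
  expect_setequal(fit2$selected$groups, sim$signal_groups)
})
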