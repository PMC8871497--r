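test_that("quasi-R2 and its adjustment match the defining formulas", {
  y <- c(0, 1, 2)
  expect_equal(quasi_r2(y, y), 1, tolerance = 1e-12)
  expect_equal(quasi_r2(y, rep(mean(y), 3)), 0, tolerance = 1e-12)
  expect_equal(quasi_r2(y, c(0, 1, 1)), 0.5, tolerance = 1e-12)
  expect_error(quasi_r2(rep(1, 4), rnorm(4)), "constant")

  expect_equal(adjusted_quasi_r2(1, 100, 7), 1, tolerance = 1e-12)
  expect_equal(adjusted_quasi_r2(0.62, 50, 0), 0.62, tolerance = 1e-12)
  expect_equal(adjusted_quasi_r2(0.5, 251, 10), 1 - 0.5 * 250 / 240,
               tolerance = 1e-12)
  expect_error(adjusted_quasi_r2(0.5, 10, 9), "requires")

  # strictly decreasing in model size at fixed accuracy
  vals <- vapply(0:20, function(k) adjusted_quasi_r2(0.8, 100, k), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("concordance regression recovers exact relationships", {
  set.seed(61)
  h <- rnorm(200)
  cc <- concordance_regression(h, h)
  expect_equal(cc$intercept, 0, tolerance = 1e-12)
  expect_equal(cc$slope, 1, tolerance = 1e-12)
  expect_equal(cc$r2, 1, tolerance = 1e-12)

  h0 <- h - mean(h)
  cc2 <- concordance_regression(h0, 2 * h0)
  expect_equal(cc2$slope, 0.5, tolerance = 1e-12)
  expect_equal(cc2$r2, 1, tolerance = 1e-12)

  set.seed(62)
  cc3 <- concordance_regression(rnorm(1000), rnorm(1000))
  expect_lt(cc3$r2, 0.02)
  expect_error(concordance_regression(h, rep(1, 200)), "constant")
})

test_that("selection metrics count frequencies, sensitivity and specificity", {
  truth <- c(1, 3)
  sel_perfect <- matrix(rep(c(TRUE, FALSE, TRUE, FALSE), 10), 10, 4, byrow = TRUE)
  m <- selection_metrics(sel_perfect, truth)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(unname(m$frequency), c(100, 0, 100, 0))

  m0 <- selection_metrics(matrix(FALSE, 10, 4), truth)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 100)

  sel3 <- matrix(FALSE, 10, 4); sel3[1:3, 2] <- TRUE
  expect_equal(unname(selection_metrics(sel3, truth)$frequency[2]), 30)
})

test_that("marginal curves anchor at the baseline and flatten dropped features", {
  sim <- tiny_scenario2(n = 120, seed = 63)
  tr <- sim$train_index
  set.seed(63)
  fit <- fkmr_fit(sim$true_zeta[tr, ], sim$scalars$y[tr],
                  matrix(sim$scalars$x[tr], ncol = 1),
                  groups = sim$group_sizes, n_lambda2 = 6, scale_grid = c(1, 4))
  anchor <- predict(fit, matrix(0.5, 1, 36), type = "h")
  for (j in c(1, 20)) {
    mc <- marginal_curve(fit, j, grid = seq(0, 1, length.out = 21))
    expect_equal(mc$h_hat[11], anchor, tolerance = 1e-10)
    if (!(j %in% fit$selected$features)) {
      expect_lt(diff(range(mc$h_hat)), 1e-10)
    }
  }
  expect_error(marginal_curve(fit, 37), "out of range")
})

test_that("replicate study aggregates methods reproducibly", {
  st <- replicate_study(1, methods = c("lm_lasso", "oracle_signals"),
                        n_replicates = 2, n = 80, seed = 9)
  expect_s3_class(st, "fkmr_replicates")
  expect_identical(nrow(st$results), 4L)
  expect_setequal(unique(st$results$method), c("lm_lasso", "oracle_signals"))

  gl <- glance(st)
  expect_identical(nrow(gl), 2L)
  expect_true(all(c("raq2", "beta", "slope", "r2", "sensitivity",
                    "specificity") %in% names(gl)))
  # oracle fit always flags exactly the true signals
  expect_equal(gl$sensitivity[gl$method == "oracle_signals"], 100)
  expect_equal(gl$specificity[gl$method == "oracle_signals"], 100)

  st2 <- replicate_study(1, methods = c("lm_lasso", "oracle_signals"),
                         n_replicates = 2, n = 80, seed = 9)
  expect_identical(tidy(st), tidy(st2))

  freq <- selection_frequencies(st, "feature")
  expect_identical(nrow(freq), 30L)
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 100))
  expect_error(replicate_study(1, methods = "nope", n_replicates = 1),
               "unknown method")
})

test_that("plot builders return ggplot objects", {
  sim <- tiny_scenario2(n = 100, seed = 64)
  tr <- sim$train_index
  set.seed(64)
  fit <- fkmr_fit(sim$true_zeta[tr, ], sim$scalars$y[tr],
                  groups = sim$group_sizes, lambda2 = 1, gamma_scale = 2)
  p1 <- autoplot(fit, features = c(1, 2))
  expect_s3_class(p1, "ggplot")

  st <- replicate_study(1, methods = "lm_lasso", n_replicates = 2, n = 60,
                        seed = 10)
  expect_s3_class(autoplot(st), "ggplot")
  expect_s3_class(autoplot(st, "group"), "ggplot")
})
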