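#' Quasi-R2 on held-out data
#'
#' \eqn{R^2_Q = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2},
#' with the total sum of squares about the mean of the evaluated set. Can
#' be negative when the predictor is worse than the mean.
#'
#' @param y Observed outcomes.
#' @param yhat Predictions of the same length.
#' @return Scalar \eqn{\le 1}.
#' @export
quasi_r2 <- function(y, yhat) {
  assert_that(length(y) == length(yhat), "y and yhat must have equal length")
  sst <- sum((y - mean(y))^2)
  assert_that(sst > 0, "quasi-R2 is undefined for a constant outcome")
  1 - sum((y - yhat)^2) / sst
}

#' Adjusted quasi-R2
#'
#' \eqn{R^2_{AQ} = 1 - (1 - R^2_Q)\,(n-1)/(n-(k+1))}: the quasi-R2
#' penalized by the number of selected model terms `k`, which makes fits of
#' different sparsity comparable.
#'
#' @param rq2 Quasi-R2 value.
#' @param n Evaluation-set size.
#' @param k Number of model terms (selected features plus scalar
#'   covariates).
#' @return Scalar \eqn{\le} `rq2` for `k >= 1`.
#' @export
adjusted_quasi_r2 <- function(rq2, n, k) {
  assert_that(n > k + 1, "adjusted quasi-R2 requires n > k + 1")
  1 - (1 - rq2) * (n - 1) / (n - (k + 1))
}

#' Concordance regression of the true on the estimated surface
#'
#' Ordinary least squares of the true nonparametric effect values on the
#' estimated ones at the same design points. Intercept near 0, slope near 1
#' and R-squared near 1 indicate accurate recovery of the surface up to the
#' intercept that the kernel machine absorbs.
#'
#' @param h_true True effect values (centered by the caller if the level is
#'   not identified).
#' @param h_hat Estimated effect values.
#' @return Tibble with columns `intercept`, `slope`, `r2`.
#' @export
concordance_regression <- function(h_true, h_hat) {
  assert_that(length(h_true) == length(h_hat), "length mismatch")
  assert_that(var(h_hat) > 0, "concordance is undefined for a constant estimate")
  fit <- lm(h_true ~ h_hat)
  tibble::tibble(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r2 = summary(fit)$r.squared)
}

#' Marginal curve of the fitted surface in one feature
#'
#' Evaluates the estimated kernel-machine surface \eqn{\hat h} along one
#' feature over a grid while all other features are held at `baseline`
#' (0.5, the centre of the probit-feature scale); the scalar-covariate part
#' is excluded. Features with zero scaling give flat curves.
#'
#' @param fit An `"fkmr_fit"`.
#' @param feature_index Column index of the feature to vary.
#' @param grid Evaluation grid (default 100 equally spaced points on
#'   `[0, 1]`).
#' @param baseline Value of the held-fixed features (default 0.5).
#' @return Tibble with columns `feature`, `zeta`, `h_hat`.
#' @export
marginal_curve <- function(fit, feature_index, grid = seq(0, 1, length.out = 100),
                           baseline = 0.5) {
  s <- length(fit$gamma)
  assert_that(is_count(feature_index) && feature_index <= s,
              "feature_index out of range")
  Z_new <- matrix(baseline, length(grid), s)
  Z_new[, feature_index] <- grid
  tibble::tibble(
    feature = if (!is.null(fit$feature_names)) fit$feature_names[feature_index]
              else paste0("feature_", feature_index),
    zeta = grid,
    h_hat = predict(fit, Z_new, type = "h")
  )
}

#' Selection frequencies, sensitivity and specificity across replicates
#'
#' @param selected Logical matrix, replicates in rows, features (or groups)
#'   in columns: was the feature selected in that replicate?
#' @param truth Integer vector of true signal column indices.
#' @return List: `frequency` (percentage per column), `sensitivity` and
#'   `specificity` (percentages).
#' @export
selection_metrics <- function(selected, truth) {
  selected <- as.matrix(selected)
  freq <- 100 * colMeans(selected)
  noise <- setdiff(seq_len(ncol(selected)), truth)
  list(
    frequency = freq,
    sensitivity = if (length(truth)) 100 * mean(selected[, truth, drop = FALSE]) else NA_real_,
    specificity = if (length(noise)) 100 * mean(!selected[, noise, drop = FALSE]) else NA_real_
  )
}

method_catalog <- c("fkmr_sgl", "fkmr_lasso", "fkmr_glasso", "fkmr_mcp",
                    "fkmr_gmcp", "lm_sgl", "lm_lasso", "lm_glasso", "lm_mcp",
                    "lm_gmcp", "oracle_fkmr_sgl", "oracle_fkmr_gmcp",
                    "oracle_signals")

penalty_of <- function(method) {
  suf <- sub("^(fkmr_|lm_|oracle_fkmr_)", "", method)
  c(sgl = "sgl", lasso = "lasso", glasso = "group_lasso",
    mcp = "mcp", gmcp = "group_mcp")[[suf]]
}

# one method on one replicate; returns a one-row tibble + selection vectors
run_method <- function(method, sim, feats, delta) {
  cfg <- sim$config
  tr <- sim$train_index; te <- sim$test_index
  x_tr <- matrix(sim$scalars$x[tr], ncol = 1)
  x_te <- matrix(sim$scalars$x[te], ncol = 1)
  y_tr <- sim$scalars$y[tr]; y_te <- sim$scalars$y[te]
  h_te <- sim$true_h[te]
  s <- sum(sim$group_sizes); pgr <- length(sim$group_sizes)
  sel_f <- rep(FALSE, s); sel_g <- rep(FALSE, pgr)
  gi <- rep(seq_len(pgr), times = sim$group_sizes)

  if (startsWith(method, "fkmr_") || startsWith(method, "oracle_fkmr_")) {
    Z_all <- if (startsWith(method, "oracle")) sim$true_zeta else feats$blocks$matrix
    fit <- fkmr_fit(Z_all[tr, , drop = FALSE], y_tr, x_tr,
                    groups = sim$group_sizes, penalty = penalty_of(method),
                    delta = delta)
    yhat <- predict(fit, Z_all[te, , drop = FALSE], x_te)
    hhat <- predict(fit, Z_all[te, , drop = FALSE], type = "h")
    sel_f[fit$selected$features] <- TRUE
    sel_g[fit$selected$groups] <- TRUE
    k <- length(fit$selected$features) + 1L
    beta_hat <- fit$beta[1]
  } else if (startsWith(method, "lm_")) {
    Z_all <- feats$blocks$matrix
    mu <- colMeans(Z_all[tr, , drop = FALSE])
    sdv <- pmax(apply(Z_all[tr, , drop = FALSE], 2L, sd), 1e-12)
    Zs_tr <- sweep(sweep(Z_all[tr, , drop = FALSE], 2L, mu), 2L, sdv, `/`)
    Zs_te <- sweep(sweep(Z_all[te, , drop = FALSE], 2L, mu), 2L, sdv, `/`)
    spec <- penalty_spec(penalty_of(method), groups = sim$group_sizes,
                         delta = delta)
    unpen <- cbind(1, x_tr)
    cv <- cv_lambda(Zs_tr, y_tr, spec, unpenalized = unpen)
    path <- solve_penalized_ls(Zs_tr, y_tr, spec, lambda = cv$lambda,
                               unpenalized = unpen)
    b <- path$beta[, cv$index]
    b0 <- path$beta_unpen[, cv$index]
    yhat <- drop(cbind(1, x_te) %*% b0 + Zs_te %*% b)
    hhat <- drop(Zs_te %*% b)
    nz <- which(abs(b) > 1e-8)
    sel_f[nz] <- TRUE
    sel_g[unique(gi[nz])] <- TRUE
    k <- length(nz) + 1L
    beta_hat <- b0[2]
  } else if (method == "oracle_signals") {
    Z_sig <- sim$true_zeta[, sim$signal_features, drop = FALSE]
    K <- kernel_matrix(Z_sig[tr, , drop = FALSE], 1, ncol(Z_sig))
    fit <- reml_fit(y_tr, x_tr, K)
    Kc <- kernel_cross(Z_sig[te, , drop = FALSE], Z_sig[tr, , drop = FALSE],
                       1, ncol(Z_sig))
    yhat <- predict_lskm(fit, x_te, Kc)
    hhat <- drop(Kc %*% fit$alpha)
    sel_f[sim$signal_features] <- TRUE
    sel_g[sim$signal_groups] <- TRUE
    k <- length(sim$signal_features) + 1L
    beta_hat <- fit$beta[1]
  } else {
    abort_fkmr("unknown method '%s'", method)
  }

  rq2 <- quasi_r2(y_te, yhat)
  conc <- if (var(hhat) > 0) concordance_regression(h_te - mean(h_te), hhat)
          else tibble::tibble(intercept = NA_real_, slope = NA_real_, r2 = NA_real_)
  tibble::tibble(
    method = method, rq2 = rq2,
    raq2 = adjusted_quasi_r2(rq2, length(te), k),
    beta = beta_hat, k = k,
    intercept = conc$intercept, slope = conc$slope, r2 = conc$r2,
    selected_features = list(sel_f), selected_groups = list(sel_g)
  )
}

#' Replicate simulation study
#'
#' Regenerates the benchmark study: for each replicate a fresh dataset is
#' simulated, FPCA features are estimated on the training subjects and
#' projected onto the test subjects, every requested method is fitted on
#' the training split, and accuracy (quasi-R2, adjusted quasi-R2 with `k` =
#' selected features + scalar covariates), concordance of the estimated
#' surface with the truth, and selection indicators are recorded on the
#' test split. Replicate seeds are derived from `seed` by fixed offsets, so
#' every method within a replicate sees identical data and the whole study
#' is reproducible.
#'
#' @param scenario 1 or 2, or a [scenario_config()].
#' @param methods Character vector from
#'   `fkmr_{sgl,lasso,glasso,mcp,gmcp}`, `lm_{...}`,
#'   `oracle_fkmr_{sgl,gmcp}` (true features), `oracle_signals`
#'   (unpenalized kernel machine on the true signal features).
#' @param n_replicates Number of replicates (default 20).
#' @param n Subjects per replicate (default 1000, split 750/250).
#' @param seed Master seed.
#' @param delta SGL mixing passed to the SGL fits (default 0.05).
#' @return Object of class `"fkmr_replicates"`: `results` (one row per
#'   replicate x method), `truth` (signal sets and group structure),
#'   `errors` (tibble of per-replicate failures, if any), plus the settings.
#' @export
replicate_study <- function(scenario = 2,
                            methods = c("fkmr_sgl", "lm_sgl"),
                            n_replicates = 20, n = 1000, seed = 1,
                            delta = 0.05) {
  assert_that(all(methods %in% method_catalog),
              "unknown method(s): %s",
              paste(setdiff(methods, method_catalog), collapse = ", "))
  config <- if (inherits(scenario, "fkmr_scenario")) scenario
            else scenario_config(scenario, n_subjects = n)
  rows <- list(); errs <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- as.integer(seed) + 1000L * r
    sim <- simulate_dataset(config, seed = rep_seed)
    feats <- fpca_features(sim$curves, n_components = config$n_basis,
                           train_index = sim$train_index)
    for (mth in methods) {
      set.seed(rep_seed + match(mth, method_catalog))
      out <- tryCatch(run_method(mth, sim, feats, delta),
                      error = function(e) e)
      if (inherits(out, "error")) {
        errs[[length(errs) + 1L]] <- tibble::tibble(
          replicate = r, method = mth, message = conditionMessage(out))
      } else {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(replicate = r, seed = rep_seed), out)
      }
    }
  }
  structure(list(
    results = purrr::list_rbind(rows),
    errors = if (length(errs)) purrr::list_rbind(errs) else NULL,
    truth = list(signal_features = signal_sets(config)$features,
                 signal_groups = signal_sets(config)$groups,
                 group_sizes = rep(config$n_basis, config$n_functionals)),
    scenario = config$scenario, n = config$n_subjects,
    n_replicates = n_replicates, seed = seed, methods = methods,
    delta = delta
  ), class = "fkmr_replicates")
}

#' Per-method selection-frequency table from a replicate study
#'
#' @param study An `"fkmr_replicates"` object.
#' @param level `"feature"` or `"group"`.
#' @return Tibble: `method`, `index`, `label`, `frequency` (percent of
#'   replicates), `signal` (logical).
#' @export
selection_frequencies <- function(study, level = c("feature", "group")) {
  level <- match.arg(level)
  col <- if (level == "feature") "selected_features" else "selected_groups"
  truth <- if (level == "feature") study$truth$signal_features
           else study$truth$signal_groups
  sizes <- study$truth$group_sizes
  labels <- if (level == "feature")
    unlist(lapply(seq_along(sizes), function(l) paste0("zeta_", l, "_", seq_len(sizes[l]))))
  else paste0("Z", seq_along(sizes))
  study$results |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(df, key) {
      mat <- do.call(rbind, df[[col]])
      tibble::tibble(index = seq_len(ncol(mat)), label = labels,
                     frequency = 100 * colMeans(mat))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(signal = .data$index %in% truth)
}

#' @export
print.fkmr_replicates <- function(x, ...) {
  cat(sprintf("Replicate study: scenario %d, n = %d, %d replicates, seed %d\n",
              x$scenario, x$n, x$n_replicates, x$seed))
  print(glance(x), n = Inf)
  invisible(x)
}
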