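#' Penalty specification for grouped sparse regularization
#'
#' Defines the penalty \eqn{\rho(\cdot)} used both in the kernel-scaling
#' update and in the linear-model baselines. Families:
#' \describe{
#'   \item{lasso}{\eqn{\|v\|_1}}
#'   \item{group_lasso}{\eqn{\sum_\ell \|v_\ell\|_2}}
#'   \item{sgl}{sparse group lasso
#'     \eqn{(1-\delta)\sum_\ell\|v_\ell\|_2 + \delta\|v\|_1}; `delta = 0`
#'     recovers the group lasso, `delta = 1` the lasso}
#'   \item{mcp}{minimax concave penalty with concavity `a`}
#'   \item{group_mcp}{MCP applied to each group norm}
#' }
#'
#' @param family One of `"lasso"`, `"group_lasso"`, `"sgl"`, `"mcp"`,
#'   `"group_mcp"`.
#' @param groups Integer vector of contiguous block sizes `(s_1, ..., s_p)`.
#' @param delta SGL mixing in `[0, 1]`; weight `delta` on the elementwise
#'   l1 part, `1 - delta` on the group part. Default 0.05 (group-dominant).
#' @param mcp_a MCP concavity parameter `a > 1` (default 3).
#' @return List of class `"fkmr_penalty"`.
#' @export
penalty_spec <- function(family = c("sgl", "lasso", "group_lasso", "mcp", "group_mcp"),
                         groups, delta = 0.05, mcp_a = 3) {
  family <- match.arg(family)
  assert_that(delta >= 0 && delta <= 1, "delta must lie in [0, 1]")
  assert_that(mcp_a > 1, "mcp_a must exceed 1")
  assert_that(all(groups >= 1) && all(groups == floor(groups)),
              "groups must be positive integers")
  structure(list(family = family, groups = as.integer(groups), delta = delta,
                 mcp_a = mcp_a,
                 group_index = rep(seq_along(groups), times = groups)),
            class = "fkmr_penalty")
}

mcp_value <- function(x, lambda, a) {
  x <- abs(x)
  ifelse(x <= a * lambda, lambda * x - x^2 / (2 * a), a * lambda^2 / 2)
}

#' Penalty value
#'
#' Evaluates the penalty for the configured family. The convex families
#' (lasso, group lasso, SGL) are positively homogeneous, so their value is
#' returned at unit regularization and the caller multiplies by the level;
#' the MCP families are not, so `lambda` enters the MCP shape and the full
#' penalty \eqn{\sum_j MCP_{\lambda,a}(v_j)} (or its group-norm composite)
#' is returned.
#'
#' @param v Coefficient vector covering all groups.
#' @param spec A [penalty_spec()].
#' @param lambda Regularization level (used by the MCP families only).
#' @return Nonnegative scalar.
#' @export
penalty_value <- function(v, spec, lambda = 1) {
  assert_that(length(v) == sum(spec$groups), "v length must match the grouping")
  gi <- spec$group_index
  gn <- group_norms(v, gi)
  switch(spec$family,
    lasso = sum(abs(v)),
    group_lasso = sum(gn),
    sgl = (1 - spec$delta) * sum(gn) + spec$delta * sum(abs(v)),
    mcp = sum(mcp_value(v, lambda, spec$mcp_a)),
    group_mcp = sum(mcp_value(gn, lambda, spec$mcp_a))
  )
}

# penalty term as it appears in the objective at level lambda
penalty_term <- function(v, spec, lambda) {
  if (spec$family %in% c("mcp", "group_mcp")) penalty_value(v, spec, lambda)
  else lambda * penalty_value(v, spec)
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

group_norms <- function(v, gi) unname(sqrt(rowsum(v^2, gi, reorder = FALSE)[, 1]))

group_shrink <- function(v, t, gi) {
  gn <- group_norms(v, gi)
  fac <- pmax(1 - t / pmax(gn, .Machine$double.eps), 0)
  v * fac[gi]
}

firm_threshold <- function(v, lambda, t, a) {
  # prox of step-t * MCP(lambda, a); requires a > t
  t <- min(t, 0.99 * a)
  out <- v
  av <- abs(v)
  small <- av <= a * lambda
  out[small] <- soft_threshold(v[small], lambda * t)[] / (1 - t / a)
  out[av <= lambda * t] <- 0
  out
}

#' Proximal operator of the scaled penalty
#'
#' For the convex families, returns
#' \eqn{\arg\min_u \frac12\|u - v\|^2 + t\,\rho(u)} with total threshold
#' `t` (the regularization level is absorbed into `t`); the SGL operator
#' composes the elementwise soft-threshold at `t * delta` with the
#' blockwise group shrink at `t * (1 - delta)`, which is its exact prox.
#' For the MCP families `t` is the gradient step and `lambda` the penalty
#' level: the result is the firm-threshold
#' \eqn{\arg\min_u \frac12\|u - v\|^2 + t\,MCP_{\lambda,a}(u)} (requires
#' `t < a`), applied to group norms for `group_mcp`.
#'
#' @param v Input vector.
#' @param t Threshold (convex families) or step size (MCP families);
#'   positive.
#' @param spec A [penalty_spec()].
#' @param lambda MCP regularization level (default `t`).
#' @return Vector of the same length as `v`.
#' @export
prox <- function(v, t, spec, lambda = t) {
  assert_that(t > 0, "threshold must be positive")
  gi <- spec$group_index
  switch(spec$family,
    lasso = soft_threshold(v, t),
    group_lasso = group_shrink(v, t, gi),
    sgl = group_shrink(soft_threshold(v, t * spec$delta),
                       t * (1 - spec$delta), gi),
    mcp = firm_threshold(v, lambda, t, spec$mcp_a),
    group_mcp = {
      gn <- group_norms(v, gi)
      gn_new <- firm_threshold(gn, lambda, t, spec$mcp_a)
      fac <- ifelse(gn > 0, gn_new / gn, 0)
      v * fac[gi]
    }
  )
}

# smallest lambda at which the penalized solution is entirely zero
# (coordinates in `penalized`; the rest enter unpenalized)
lambda_max_value <- function(design, response, spec, scale_n = nrow(design),
                             unpenalized = NULL) {
  r <- response
  if (!is.null(unpenalized) && ncol(unpenalized) > 0) {
    r <- residuals(lm.fit(unpenalized, response))
  }
  g <- drop(crossprod(design, r)) / scale_n
  gi <- spec$group_index
  switch(spec$family,
    lasso = ,
    mcp = max(abs(g)),
    group_lasso = ,
    group_mcp = max(group_norms(g, gi)),
    sgl = {
      if (spec$delta >= 1) return(max(abs(g)))
      # per group: smallest lambda with ||soft(g_l, lambda*delta)||_2 <= lambda*(1-delta)
      max(vapply(split(g, gi), function(gl) {
        f <- function(l) sqrt(sum(soft_threshold(gl, l * spec$delta)^2)) -
          l * (1 - spec$delta)
        hi <- max(abs(gl)) / (1 - spec$delta) + 1e-12
        if (f(hi) > 0) return(hi)
        stats::uniroot(f, c(0, hi), tol = 1e-12)$root
      }, numeric(1)))
    }
  )
}

#' Penalized least squares along a regularization path
#'
#' Minimizes \eqn{(1/2n)\|y - X_u b_u - X b\|^2 + \lambda\,\rho(b)} by
#' proximal gradient descent (FISTA with restarts for the convex families,
#' plain ISTA for the MCP families) with fixed step `1/L`,
#' `L = ||[X_u X]||_2^2 / n`, warm-started along a decreasing `lambda`
#' path. Unpenalized columns (e.g. intercept or scalar covariates) are
#' carried in the same gradient step but never thresholded.
#'
#' @param design `n x s` penalized design matrix.
#' @param response Length-`n` response.
#' @param spec A [penalty_spec()] covering the `s` columns.
#' @param lambda Decreasing vector of penalty levels; `NULL` builds a
#'   100-point log-spaced path from the all-zero bound down to `1e-3` of it.
#' @param unpenalized Optional `n x q` matrix of unpenalized columns.
#' @param scale_n Loss denominator (defaults to `nrow(design)`).
#' @param init Optional warm start for the penalized coefficients.
#' @param max_iter,tol Iteration cap and relative-change tolerance per
#'   lambda.
#' @return List of class `"fkmr_path"`: `lambda`, `beta` (`s x nlambda`),
#'   `beta_unpen` (`q x nlambda`), `iterations`, `converged`.
#' @export
solve_penalized_ls <- function(design, response, spec, lambda = NULL,
                               unpenalized = NULL, scale_n = nrow(design),
                               init = NULL, max_iter = 2000, tol = 1e-8) {
  design <- as.matrix(design)
  n <- nrow(design); s <- ncol(design)
  assert_that(length(response) == n, "response length must match design rows")
  q <- if (is.null(unpenalized)) 0L else ncol(as.matrix(unpenalized))
  full <- if (q > 0) cbind(as.matrix(unpenalized), design) else design

  if (is.null(lambda)) {
    lmax <- lambda_max_value(design, response, spec, scale_n,
                             if (q > 0) as.matrix(unpenalized) else NULL)
    lmax <- max(lmax, 1e-10)
    lambda <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 100))
  }
  lambda <- sort(lambda, decreasing = TRUE)

  # precomputed Gram form: the per-iteration cost is O((q+s)^2), not O(n(q+s))
  G <- crossprod(full) / scale_n
  gy <- drop(crossprod(full, response)) / scale_n
  yy <- sum(response^2) / (2 * scale_n)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / max(L, .Machine$double.eps)
  accelerate <- spec$family %in% c("lasso", "group_lasso", "sgl")

  b <- c(if (q > 0) rep(0, q), if (is.null(init)) rep(0, s) else init)
  pen_idx <- if (q > 0) (q + 1L):(q + s) else seq_len(s)
  beta_out <- matrix(0, s, length(lambda))
  unpen_out <- matrix(0, max(q, 1L), length(lambda))
  iters <- integer(length(lambda)); conv <- logical(length(lambda))

  # lean per-family closures for the hot loop (the exported prox() /
  # penalty_value() carry validation overhead)
  gi <- spec$group_index
  idx <- split(seq_len(s), gi)
  gnorm <- function(v) sqrt(vapply(idx, function(ii) sum(v[ii]^2), 0))
  delta <- spec$delta; a <- spec$mcp_a
  pen_fun <- switch(spec$family,
    lasso = function(v, lam) lam * sum(abs(v)),
    group_lasso = function(v, lam) lam * sum(gnorm(v)),
    sgl = function(v, lam) lam * ((1 - delta) * sum(gnorm(v)) + delta * sum(abs(v))),
    mcp = function(v, lam) sum(mcp_value(v, lam, a)),
    group_mcp = function(v, lam) sum(mcp_value(gnorm(v), lam, a)))
  shrink_g <- function(v, t) {
    fac <- pmax(1 - t / pmax(gnorm(v), 1e-300), 0)
    v * fac[gi]
  }
  prox_fun <- switch(spec$family,
    lasso = function(v, lam) soft_threshold(v, step * lam),
    group_lasso = function(v, lam) shrink_g(v, step * lam),
    sgl = function(v, lam) shrink_g(soft_threshold(v, step * lam * delta),
                                    step * lam * (1 - delta)),
    mcp = function(v, lam) firm_threshold(v, lam, step, a),
    group_mcp = function(v, lam) {
      gn <- gnorm(v)
      fac <- ifelse(gn > 0, firm_threshold(gn, lam, step, a) / gn, 0)
      v * fac[gi]
    })
  obj_fun <- function(b, lam) {
    yy - sum(b * gy) + sum(b * drop(G %*% b)) / 2 + pen_fun(b[pen_idx], lam)
  }

  for (il in seq_along(lambda)) {
    lam <- lambda[il]
    z <- b; t_acc <- 1
    obj_prev <- obj_fun(b, lam)
    for (it in seq_len(max_iter)) {
      g <- drop(G %*% z) - gy
      u <- z - step * g
      b_new <- u
      b_new[pen_idx] <- prox_fun(u[pen_idx], lam)
      if (accelerate) {
        t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
        z <- b_new + ((t_acc - 1) / t_new) * (b_new - b)
        t_acc <- t_new
        # restart on objective increase to keep the run monotone
        obj_new <- obj_fun(b_new, lam)
        if (obj_new > obj_prev + 1e-12 * (1 + abs(obj_prev))) {
          z <- b_new; t_acc <- 1
        }
        obj_prev <- min(obj_prev, obj_new)
      } else {
        z <- b_new
      }
      delta_rel <- sqrt(sum((b_new - b)^2)) / max(sqrt(sum(b^2)), 1e-10)
      b <- b_new
      if (delta_rel < tol) break
    }
    iters[il] <- it
    conv[il] <- it < max_iter
    beta_out[, il] <- b[pen_idx]
    if (q > 0) unpen_out[, il] <- b[seq_len(q)]
  }
  structure(list(lambda = lambda, beta = beta_out,
                 beta_unpen = if (q > 0) unpen_out else NULL,
                 iterations = iters, converged = conv, spec = spec),
            class = "fkmr_path")
}

#' Cross-validated penalty level
#'
#' K-fold cross-validation of the penalized least-squares path; returns the
#' `lambda` minimizing the mean held-out prediction MSE (optionally the
#' one-standard-error rule).
#'
#' @inheritParams solve_penalized_ls
#' @param folds Number of folds (default 5).
#' @param one_se Use the 1-SE rule instead of the minimum (default FALSE).
#' @return List: `lambda_min` (selected level), `lambda`, `cv_mean`,
#'   `cv_se`, `fold_id`.
#' @export
cv_lambda <- function(design, response, spec, lambda = NULL, folds = 5,
                      unpenalized = NULL, scale_n = NULL, one_se = FALSE) {
  design <- as.matrix(design)
  n <- nrow(design)
  assert_that(folds >= 2 && folds <= n, "folds must lie in [2, n]")
  if (is.null(lambda)) {
    lmax <- lambda_max_value(design, response, spec, n,
                             if (!is.null(unpenalized)) as.matrix(unpenalized) else NULL)
    lmax <- max(lmax, 1e-10)
    lambda <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 100))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  err <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    inn <- fold_id != f
    path <- solve_penalized_ls(design[inn, , drop = FALSE], response[inn], spec,
                               lambda = lambda,
                               unpenalized = if (!is.null(unpenalized))
                                 as.matrix(unpenalized)[inn, , drop = FALSE] else NULL,
                               scale_n = if (is.null(scale_n)) sum(inn) else scale_n)
    pred <- design[!inn, , drop = FALSE] %*% path$beta
    if (!is.null(unpenalized))
      pred <- pred + as.matrix(unpenalized)[!inn, , drop = FALSE] %*% path$beta_unpen
    err[f, ] <- colMeans((response[!inn] - pred)^2)
  }
  cv_mean <- colMeans(err)
  cv_se <- apply(err, 2L, sd) / sqrt(folds)
  i_min <- which.min(cv_mean)
  i_sel <- if (one_se) {
    min(which(cv_mean <= cv_mean[i_min] + cv_se[i_min]))
  } else i_min
  list(lambda_min = lambda[i_sel], lambda = lambda, cv_mean = cv_mean,
       cv_se = cv_se, fold_id = fold_id, index = i_sel)
}
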