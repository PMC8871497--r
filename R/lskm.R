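#' Least-squares kernel machine at fixed smoothing parameter
#'
#' Minimizes \eqn{(1/2n)\|Y - X\beta - K\alpha\|^2 +
#' (\lambda_1/2)\,\alpha^\top K \alpha} at fixed kernel `K`. The stationary
#' conditions give \eqn{\alpha = (K + n\lambda_1 I)^{-1}(Y - X\beta)} and a
#' generalized-least-squares equation for \eqn{\beta} with weight matrix
#' \eqn{S = (K + n\lambda_1 I)^{-1}}.
#'
#' @param Y Length-`n` outcome vector.
#' @param X `n x q` fixed-effects design (or `NULL` for none).
#' @param K Symmetric positive semidefinite `n x n` kernel matrix.
#' @param lambda1 Positive smoothing parameter.
#' @param eigK Optional cached `eigen(K, symmetric = TRUE)`.
#' @return List with `beta`, `alpha`, `h_hat` (`= K alpha`) and `fitted`
#'   (`X beta + h_hat`).
#' @export
solve_fixed_lambda <- function(Y, X, K, lambda1, eigK = NULL) {
  assert_that(lambda1 > 0, "lambda1 must be positive")
  n <- length(Y)
  if (is.null(eigK)) eigK <- eigen(K, symmetric = TRUE)
  d <- pmax(eigK$values, 0)
  U <- eigK$vectors
  sinv <- 1 / (d + n * lambda1)       # spectrum of S = (K + n lambda1 I)^{-1}
  Yt <- crossprod(U, Y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    assert_that(nrow(X) == n, "X must have length(Y) rows")
    if (qr(X)$rank < ncol(X)) abort_fkmr("X is rank deficient")
    Xt <- crossprod(U, X)
    A <- crossprod(Xt, sinv * Xt)
    b <- crossprod(Xt, sinv * Yt)
    beta <- drop(solve(A, b))
    resid_t <- Yt - Xt %*% beta
  } else {
    beta <- numeric(0)
    resid_t <- Yt
  }
  alpha <- drop(U %*% (sinv * resid_t))
  h_hat <- drop(U %*% (d * sinv * resid_t))
  fitted <- h_hat + if (length(beta)) drop(X %*% beta) else 0
  list(beta = beta, alpha = alpha, h_hat = h_hat, fitted = fitted)
}

# Cholesky variant of solve_fixed_lambda (no eigendecomposition); used by
# the cross-validation loops where K changes at every step
lskm_solve_chol <- function(Y, X, K, lambda1) {
  n <- length(Y)
  R <- chol(K + diag(n * lambda1 + 1e-10, n))
  S <- function(v) backsolve(R, backsolve(R, v, transpose = TRUE))
  Sy <- S(Y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    SX <- apply(X, 2L, S)
    beta <- drop(solve(crossprod(X, SX), crossprod(X, Sy)))
    alpha <- drop(Sy - SX %*% beta)
  } else {
    beta <- numeric(0)
    alpha <- drop(Sy)
  }
  list(beta = beta, alpha = alpha)
}

#' REML fit of the kernel machine via its linear mixed model
#'
#' Fits \eqn{Y = X\beta + h + \epsilon} with \eqn{h \sim N(0, \tau K)} and
#' \eqn{\epsilon \sim N(0, \sigma^2 I)} by restricted maximum likelihood.
#' After a spectral decomposition of `K` the REML criterion is a smooth
#' 1-D function of \eqn{\theta = \tau/\sigma^2}, optimized over
#' \eqn{\log\theta \in [-12, 12]}; \eqn{\sigma^2} is profiled out. The
#' smoothing parameter of the penalized least-squares view is recovered as
#' \eqn{\lambda_1 = \hat\sigma^2 / (n \hat\tau)}, so REML tunes the amount
#' of smoothing without cross-validation.
#'
#' @inheritParams solve_fixed_lambda
#' @return Object of class `"fkmr_lskm"`: `beta`, `alpha`, `h_hat`,
#'   `fitted`, `tau`, `sigma2`, `lambda1`, `reml_loglik`, `converged`,
#'   `no_kernel_effect` (boundary flag), `eigK` (cached decomposition).
#' @export
reml_fit <- function(Y, X, K) {
  n <- length(Y)
  q <- if (is.null(X)) 0L else ncol(as.matrix(X))
  assert_that(n > q, "need more observations than fixed effects")
  eigK <- eigen(K + diag(1e-10, n), symmetric = TRUE)
  d <- pmax(eigK$values, 0)
  if (diff(range(d)) < 1e-8 * max(d, 1)) {
    warning("kernel matrix is numerically proportional to the identity; ",
            "tau and sigma2 are jointly unidentifiable", call. = FALSE)
  }
  U <- eigK$vectors
  Yt <- drop(crossprod(U, Y))
  Xt <- if (q > 0) crossprod(U, as.matrix(X)) else NULL

  neg_reml <- function(log_theta) {
    th <- exp(log_theta)
    v <- th * d + 1                       # V = sigma2 * diag(v) in rotated space
    if (q > 0) {
      A <- crossprod(Xt, Xt / v)
      b <- crossprod(Xt, Yt / v)
      beta <- solve(A, b)
      r <- Yt - drop(Xt %*% beta)
      rss <- sum(r^2 / v)
      s2 <- rss / (n - q)
      0.5 * ((n - q) * log(s2) + sum(log(v)) + determinant(A, logarithm = TRUE)$modulus)
    } else {
      rss <- sum(Yt^2 / v)
      s2 <- rss / n
      0.5 * (n * log(s2) + sum(log(v)))
    }
  }

  opt <- optimize(neg_reml, interval = c(-12, 12), tol = 1e-8)
  # polish near the boundary: accept the boundary if it is at least as good
  for (bnd in c(-12, 12)) {
    if (neg_reml(bnd) < opt$objective) opt <- list(minimum = bnd, objective = neg_reml(bnd))
  }
  th <- exp(opt$minimum)
  v <- th * d + 1
  if (q > 0) {
    A <- crossprod(Xt, Xt / v)
    beta <- drop(solve(A, crossprod(Xt, Yt / v)))
    r <- Yt - drop(Xt %*% beta)
    s2 <- sum(r^2 / v) / (n - q)
  } else {
    beta <- numeric(0)
    r <- Yt
    s2 <- sum(r^2 / v) / n
  }
  tau <- th * s2
  no_effect <- opt$minimum <= -12 + 1e-6 || tau < 1e-10
  if (no_effect) warning("no kernel effect detected (tau at boundary)", call. = FALSE)
  lambda1 <- if (tau > 0) s2 / (n * tau) else Inf
  alpha <- drop(U %*% (th * r / v))          # tau V^{-1} (Y - X beta), scaled
  h_hat <- drop(U %*% (d * th * r / v))
  fitted <- h_hat + if (q > 0) drop(as.matrix(X) %*% beta) else 0
  structure(list(
    beta = beta, alpha = alpha, h_hat = h_hat, fitted = fitted,
    tau = tau, sigma2 = s2, lambda1 = lambda1,
    reml_loglik = -opt$objective, converged = TRUE,
    no_kernel_effect = no_effect, eigK = eigK
  ), class = "fkmr_lskm")
}

#' Predict from a kernel-machine fit
#'
#' \eqn{\hat y = X_{new}\beta + K_{cross}\alpha}, with `K_cross` the
#' [kernel_cross()] matrix between the new and training subjects.
#'
#' @param fit A fit with components `beta` and `alpha` (from [reml_fit()]
#'   or [solve_fixed_lambda()]).
#' @param X_new New fixed-effects design (or `NULL`).
#' @param K_cross `n' x n` cross-kernel matrix.
#' @return Numeric prediction vector.
#' @export
predict_lskm <- function(fit, X_new, K_cross) {
  assert_that(ncol(K_cross) == length(fit$alpha),
              "K_cross columns must match the training size")
  h <- drop(K_cross %*% fit$alpha)
  if (length(fit$beta)) {
    X_new <- as.matrix(X_new)
    assert_that(ncol(X_new) == length(fit$beta), "X_new has wrong column count")
    h + drop(X_new %*% fit$beta)
  } else h
}
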