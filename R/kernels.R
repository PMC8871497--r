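#' Garrote-scaled Gaussian kernel matrix
#'
#' Gram matrix of the Gaussian kernel applied to elementwise-scaled
#' features, \eqn{K_{ik} = \exp\{-(1/p)\sum_j \gamma_j^2 (z_{ij} -
#' z_{kj})^2\}}. The bandwidth denominator `p` is held fixed at the total
#' number of features (the conventional choice for Gaussian kernels, and
#' necessary here because a free bandwidth is unidentifiable against the
#' scaling vector \eqn{\gamma}). The kernel depends on \eqn{\gamma} only
#' through \eqn{\gamma_j^2}, so a zero component deletes feature `j`.
#'
#' @param Z `n x s` feature matrix.
#' @param gamma Length-`s` scaling vector (a scalar is recycled).
#' @param p Bandwidth denominator; defaults to `ncol(Z)`.
#' @return Symmetric `n x n` matrix with unit diagonal.
#' @export
kernel_matrix <- function(Z, gamma = 1, p = ncol(Z)) {
  Z <- as.matrix(Z)
  assert_that(p > 0, "bandwidth denominator must be positive")
  if (length(gamma) == 1L) gamma <- rep(gamma, ncol(Z))
  assert_that(length(gamma) == ncol(Z), "gamma length must match feature count")
  assert_that(all(is.finite(Z)) && all(is.finite(gamma)),
              "non-finite values in features or gamma")
  W <- sweep(Z, 2L, gamma, `*`)
  sq <- rowSums(W^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(W)
  K <- exp(-pmax(D2, 0) / p)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' Cross-kernel matrix between new and training subjects
#'
#' Rows index the new subjects: entry `(i, k)` is
#' \eqn{K(\gamma \circ z_i^{new}, \gamma \circ z_k^{train})}. With
#' `Z_new = Z_train` this reproduces [kernel_matrix()].
#'
#' @param Z_new `n' x s` feature matrix of new subjects.
#' @param Z_train `n x s` training feature matrix.
#' @inheritParams kernel_matrix
#' @return `n' x n` matrix with entries in `(0, 1]`.
#' @export
kernel_cross <- function(Z_new, Z_train, gamma = 1, p = ncol(Z_train)) {
  Z_new <- as.matrix(Z_new); Z_train <- as.matrix(Z_train)
  assert_that(ncol(Z_new) == ncol(Z_train),
              "feature count mismatch: %d vs %d", ncol(Z_new), ncol(Z_train))
  if (length(gamma) == 1L) gamma <- rep(gamma, ncol(Z_train))
  assert_that(length(gamma) == ncol(Z_train), "gamma length must match feature count")
  Wn <- sweep(Z_new, 2L, gamma, `*`)
  Wt <- sweep(Z_train, 2L, gamma, `*`)
  D2 <- outer(rowSums(Wn^2), rowSums(Wt^2), `+`) - 2 * tcrossprod(Wn, Wt)
  exp(-pmax(D2, 0) / p)
}

#' Gradient of the kernel-machine fit map with respect to gamma
#'
#' For \eqn{F(\gamma) = K(\gamma; Z)\alpha}, returns the `n x s` Jacobian
#' with entries
#' \deqn{[\nabla_\gamma F]_{ij} = \sum_k \alpha_k K_{ik}
#'   \cdot (-2\gamma_j/p)(z_{ij}-z_{kj})^2,}
#' computed without forming the per-feature squared-distance matrices
#' (three kernel-weighted matrix-vector products per feature).
#'
#' @inheritParams kernel_matrix
#' @param alpha Length-`n` dual coefficient vector.
#' @param K Optional precomputed [kernel_matrix()] for `(Z, gamma, p)`.
#' @return `n x s` gradient matrix.
#' @export
grad_F <- function(Z, gamma, alpha, p = ncol(Z), K = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z); s <- ncol(Z)
  if (length(gamma) == 1L) gamma <- rep(gamma, s)
  assert_that(length(gamma) == s && length(alpha) == n, "shape mismatch in grad_F")
  if (is.null(K)) K <- kernel_matrix(Z, gamma, p)
  # sum_k alpha_k K_ik (z_ij - z_kj)^2, expanded so each term is one GEMM
  Ka <- drop(K %*% alpha)
  M1 <- K %*% (Z * alpha)
  M2 <- K %*% (Z^2 * alpha)
  G <- Z^2 * Ka - 2 * Z * M1 + M2
  sweep(G, 2L, -2 * gamma / p, `*`)
}
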