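#' Dense-design functional principal component analysis
#'
#' Estimates the mean curve, covariance eigenstructure, standardized FPC
#' scores and their probit-transformed features from densely observed
#' curves. The covariance operator is the sample covariance of the centered
#' curves; its eigenproblem is solved under trapezoid quadrature weights so
#' the eigenfunctions are orthonormal in \eqn{L^2} on the grid. Scores are
#' \eqn{\hat\xi_{ij} = \langle Z_i - \hat\mu, \hat\phi_j\rangle /
#' \sqrt{\hat\lambda_j}} (unit variance by construction of
#' \eqn{\hat\lambda_j}) and the features are \eqn{\hat\zeta = \Phi(\hat\xi)},
#' which map each score onto `(0, 1)`.
#'
#' Sign convention: each eigenfunction is flipped so that its quadrature
#' integral is positive; when that integral is numerically zero (all
#' non-constant Fourier shapes), the element of largest magnitude is made
#' positive. This makes the decomposition deterministic; a flip only relabels
#' \eqn{\zeta \leftrightarrow 1 - \zeta} and downstream model fits are
#' unaffected.
#'
#' @param curves `n x m` numeric matrix, one row per subject.
#' @param grid Strictly increasing vector of the `m` sampling points.
#' @param n_components Number of components to retain; alternatively
#'   `fve_threshold`.
#' @param fve_threshold Retain the smallest number of components whose
#'   cumulative fraction of variance explained reaches this value (used when
#'   `n_components` is `NULL`; default 0.995).
#' @return An object of class `"fkmr_fpca"` with elements `mean_curve`,
#'   `eigenvalues` (variance scale, descending), `eigenfunctions`
#'   (`m x k`, quadrature-orthonormal), `scores_std` (`n x k` matrix of
#'   \eqn{\hat\xi}), `features` (`n x k` matrix of \eqn{\hat\zeta}), `fve`
#'   (cumulative), `grid`, `quad_weights`.
#' @export
#' @examples
#' g <- seq(0, 1, length.out = 50)
#' z <- outer(rnorm(40, sd = 2), sqrt(2) * sin(2 * pi * g))
#' fp <- fit_fpca(z, g, n_components = 1)
#' fp$eigenvalues[1] # close to 4
fit_fpca <- function(curves, grid, n_components = NULL, fve_threshold = 0.995) {
  curves <- as.matrix(curves)
  n <- nrow(curves); m <- ncol(curves)
  assert_that(n >= 2L, "need at least two curves")
  assert_that(length(grid) == m, "grid length must match the number of columns")
  assert_that(all(diff(grid) > 0), "grid must be strictly increasing")

  w <- trapezoid_weights(grid)
  mu <- colMeans(curves)
  centered <- sweep(curves, 2L, mu)
  covm <- crossprod(centered) / (n - 1)

  # quadrature-weighted symmetric eigenproblem: B = W^{1/2} C W^{1/2}
  ws <- sqrt(w)
  B <- covm * tcrossprod(ws)
  eig <- eigen(B, symmetric = TRUE)
  lam <- eig$values
  pos <- sum(lam > max(lam[1], 0) * 1e-12)
  assert_that(pos >= 1L && lam[1] > 0, "degenerate input: no positive eigenvalue")

  k <- if (!is.null(n_components)) {
    assert_that(is_count(n_components), "n_components must be a positive integer")
    assert_that(n_components <= pos,
                "n_components = %d exceeds the numerical rank %d", n_components, pos)
    as.integer(n_components)
  } else {
    fve_all <- cumsum(pmax(lam, 0)) / sum(pmax(lam, 0))
    min(which(fve_all >= fve_threshold)[1], pos)
  }

  phi <- eig$vectors[, seq_len(k), drop = FALSE] / ws
  # deterministic sign: positive integral, falling back to largest element
  for (j in seq_len(k)) {
    s_int <- sum(w * phi[, j])
    s_use <- if (abs(s_int) > 1e-8 * sqrt(sum(w * phi[, j]^2))) sign(s_int)
             else sign(phi[which.max(abs(phi[, j])), j])
    if (s_use < 0) phi[, j] <- -phi[, j]
  }

  lam_k <- lam[seq_len(k)]
  scores <- sweep(centered %*% (w * phi), 2L, sqrt(pmax(lam_k, 1e-12)), `/`)
  total_var <- sum(pmax(lam, 0))

  structure(list(
    mean_curve = mu,
    eigenvalues = lam_k,
    eigenfunctions = phi,
    scores_std = scores,
    features = pnorm(scores),
    fve = cumsum(pmax(lam_k, 0)) / total_var,
    grid = grid,
    quad_weights = w,
    n_components = k
  ), class = "fkmr_fpca")
}

#' Project new curves onto a fitted FPCA basis
#'
#' Computes standardized scores and probit features for new subjects using
#' the training mean curve, eigenfunctions and eigenvalues; nothing is
#' re-estimated, so test-set features are comparable with the training ones.
#'
#' @param fpca A fitted [fit_fpca()] object.
#' @param new_curves `n' x m` matrix on the same grid as the fit.
#' @param grid The sampling grid of `new_curves`; must equal the training
#'   grid.
#' @return List with `scores_std` and `features` matrices for the new
#'   subjects.
#' @export
project_scores <- function(fpca, new_curves, grid = fpca$grid) {
  assert_that(inherits(fpca, "fkmr_fpca"), "fpca must come from fit_fpca()")
  new_curves <- as.matrix(new_curves)
  assert_that(ncol(new_curves) == length(fpca$grid) &&
                length(grid) == length(fpca$grid) &&
                max(abs(grid - fpca$grid)) < 1e-10,
              "grid mismatch: new curves must be sampled on the training grid")
  centered <- sweep(new_curves, 2L, fpca$mean_curve)
  scores <- sweep(centered %*% (fpca$quad_weights * fpca$eigenfunctions),
                  2L, sqrt(pmax(fpca$eigenvalues, 1e-12)), `/`)
  list(scores_std = scores, features = pnorm(scores))
}

#' Bind per-functional feature matrices into grouped feature blocks
#'
#' Column-concatenates the FPC feature matrices of the `p` functional
#' predictors into one `n x s` grand matrix and records the contiguous
#' group structure used by the group penalties.
#'
#' @param feature_list Named or unnamed list of `n x s_l` matrices with a
#'   common row count.
#' @return List of class `"fkmr_blocks"` with `matrix` (`n x s`),
#'   `group_sizes`, `group_labels` and `group_index` (length-`s` integer
#'   vector mapping columns to groups).
#' @export
build_feature_blocks <- function(feature_list) {
  assert_that(is.list(feature_list) && length(feature_list) >= 1L,
              "feature_list must be a nonempty list of matrices")
  mats <- lapply(feature_list, as.matrix)
  nr <- vapply(mats, nrow, integer(1))
  assert_that(length(unique(nr)) == 1L,
              "all feature matrices must have the same number of rows")
  labels <- names(feature_list)
  if (is.null(labels) || any(labels == ""))
    labels <- paste0("Z", seq_along(mats))
  sizes <- vapply(mats, ncol, integer(1))
  grand <- do.call(cbind, mats)
  colnames(grand) <- unlist(lapply(seq_along(mats), function(l)
    paste0("zeta_", l, "_", seq_len(sizes[l]))))
  structure(list(
    matrix = grand,
    group_sizes = unname(sizes),
    group_labels = labels,
    group_index = rep(seq_along(sizes), times = sizes)
  ), class = "fkmr_blocks")
}

#' Extract FPC features from long-format curves
#'
#' Tidy front end that pivots a long curve table into per-functional
#' matrices, fits FPCA per functional predictor on the subjects listed in
#' `train_index` (all subjects by default), projects every subject, and
#' returns grouped feature blocks plus a features tibble.
#'
#' @param curves Long tibble/data frame with columns `subject_id`,
#'   `functional_id`, `t`, `value`; all subjects of a functional must share
#'   the grid.
#' @param n_components Components per functional predictor (scalar, or
#'   `NULL` to use `fve_threshold`).
#' @param fve_threshold See [fit_fpca()].
#' @param train_index Subject ids used to estimate the FPCA basis; others
#'   are projected.
#' @return List of class `"fkmr_features"` with `blocks`
#'   ([build_feature_blocks()] output over all subjects, rows in
#'   `subject_id` order), `fpca` (per-functional fits), `features` (tibble:
#'   `subject_id` then one `zeta_<l>_<j>` column per feature) and
#'   `subject_id`.
#' @export
fpca_features <- function(curves, n_components = NULL, fve_threshold = 0.995,
                          train_index = NULL) {
  assert_that(all(c("subject_id", "functional_id", "t", "value") %in%
                    names(curves)),
              "curves must have columns subject_id, functional_id, t, value")
  parsed <- curves_to_matrices(curves)
  subjects <- parsed$subjects
  if (is.null(train_index)) train_index <- subjects
  tr <- match(train_index, subjects)
  assert_that(!anyNA(tr), "train_index contains unknown subject ids")

  fits <- lapply(parsed$matrices, function(mat)
    fit_fpca(mat[tr, , drop = FALSE], parsed$grid,
             n_components = n_components, fve_threshold = fve_threshold))
  feats <- lapply(seq_along(fits), function(l)
    project_scores(fits[[l]], parsed$matrices[[l]])$features)
  names(feats) <- names(parsed$matrices)
  blocks <- build_feature_blocks(feats)
  features <- tibble::as_tibble(as.data.frame(blocks$matrix))
  features <- dplyr::bind_cols(tibble::tibble(subject_id = subjects), features)
  structure(list(blocks = blocks, fpca = fits, features = features,
                 subject_id = subjects), class = "fkmr_features")
}

# long tibble -> list of n x m matrices (one per functional) + common grid
curves_to_matrices <- function(curves) {
  curves <- dplyr::arrange(tibble::as_tibble(curves),
                           .data$functional_id, .data$subject_id, .data$t)
  split_fun <- split(curves, curves$functional_id)
  subjects <- sort(unique(curves$subject_id))
  grid <- NULL
  mats <- lapply(split_fun, function(df) {
    counts <- table(df$subject_id)
    if (length(unique(as.integer(counts))) != 1L)
      abort_fkmr("ragged grid: subject %s has %d points but others differ",
                 names(counts)[which.min(counts)], min(counts))
    m <- as.integer(counts[1])
    g <- df$t[seq_len(m)]
    gm <- matrix(df$value, ncol = m, byrow = TRUE)
    tmat <- matrix(df$t, ncol = m, byrow = TRUE)
    if (max(abs(sweep(tmat, 2L, g))) > 1e-10)
      abort_fkmr("subjects of functional %s do not share a common grid",
                 df$functional_id[1])
    rownames(gm) <- unique(df$subject_id)
    gm <- gm[as.character(subjects), , drop = FALSE]
    if (is.null(grid)) grid <<- g
    else if (length(g) != length(grid) || max(abs(g - grid)) > 1e-10)
      abort_fkmr("functional predictors are sampled on different grids")
    gm
  })
  list(matrices = mats, grid = grid, subjects = subjects)
}
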