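#' Orthonormal Fourier basis on the unit interval
#'
#' The system is ordered as \eqn{\phi_1 \equiv 1},
#' \eqn{\phi_{2k}(t) = \sqrt{2}\sin(2\pi k t)},
#' \eqn{\phi_{2k+1}(t) = \sqrt{2}\cos(2\pi k t)}, which is orthonormal in
#' \eqn{L^2[0,1]}.
#'
#' @param j Basis index (integer, `j >= 1`).
#' @param t Numeric vector of evaluation points in `[0, 1]`.
#' @return Numeric vector `phi_j(t)` of the same length as `t`.
#' @export
#' @examples
#' fourier_basis(1, seq(0, 1, length.out = 5))
#' fourier_basis(2, 0.25) # sqrt(2) * sin(pi/2)
fourier_basis <- function(j, t) {
  assert_that(is_count(j), "basis index j must be a positive integer, got %s",
              format(j))
  assert_that(all(t >= -1e-12 & t <= 1 + 1e-12),
              "evaluation points must lie in [0, 1]")
  if (j == 1L) return(rep(1, length(t)))
  k <- j %/% 2L
  if (j %% 2L == 0L) sqrt(2) * sin(2 * pi * k * t) else sqrt(2) * cos(2 * pi * k * t)
}

#' Scenario configuration for the built-in simulation designs
#'
#' Two benchmark designs are provided. Scenario 1 has a single functional
#' predictor built from 15 Fourier components with sparsity in the FPC
#' features; Scenario 2 has four functional predictors of 9 components each,
#' with sparsity both across functional predictors and within the signal
#' ones. Curves follow a Karhunen-Loeve expansion
#' \eqn{Z_\ell(t) = \sum_j \varsigma_j \xi_{j\ell} \phi_j(t)} with
#' \eqn{\varsigma_j = 45 \times 0.64^j} and standard-normal scores
#' \eqn{\xi_{j\ell}}; features are the probit transforms
#' \eqn{\zeta_{j\ell} = \Phi(\xi_{j\ell})}. The outcome is
#' \eqn{y_i = 2 x_i + h(\zeta_i) + \epsilon_i} with scenario-specific `h`
#' (see [true_h()]), \eqn{x_i \sim N(0,1)} and \eqn{\epsilon_i \sim N(0,1)}.
#'
#' @param scenario 1 or 2.
#' @param n_subjects Number of subjects (curves) to generate.
#' @param n_grid Number of sampling points per curve (default 100).
#' @param jitter_var Variance of the Gaussian jitter added to the equally
#'   spaced time grid (default 0.001); the jittered grid is shared by all
#'   subjects of a replicate.
#' @param n_basis Number of Fourier components per functional predictor;
#'   defaults to 15 for Scenario 1 and 9 for Scenario 2.
#' @param eigen_scale,eigen_decay Scale and geometric decay of the
#'   component standard deviations \eqn{\varsigma_j = scale \times decay^j}.
#' @param noise_sd Standard deviation of the outcome noise (default 1).
#' @param train_frac Fraction of subjects assigned to the training split
#'   (default 0.75; the first `round(train_frac * n)` subjects).
#' @return A list of class `"fkmr_scenario"` with the validated settings.
#' @export
scenario_config <- function(scenario = 2, n_subjects = 1000, n_grid = 100,
                            jitter_var = 0.001, n_basis = NULL,
                            eigen_scale = 45, eigen_decay = 0.64,
                            noise_sd = 1, train_frac = 0.75) {
  assert_that(scenario %in% c(1, 2), "scenario must be 1 or 2")
  assert_that(is_count(n_subjects), "n_subjects must be a positive integer")
  assert_that(is_count(n_grid) && n_grid >= 2, "n_grid must be >= 2")
  assert_that(jitter_var >= 0, "jitter_var must be nonnegative")
  assert_that(eigen_decay > 0 && eigen_decay < 1, "eigen_decay must be in (0,1)")
  assert_that(noise_sd > 0, "noise_sd must be positive")
  if (is.null(n_basis)) n_basis <- if (scenario == 1) 15L else 9L
  assert_that(is_count(n_basis), "n_basis must be a positive integer")
  structure(list(
    scenario = as.integer(scenario), n_subjects = as.integer(n_subjects),
    n_grid = as.integer(n_grid), jitter_var = jitter_var,
    n_basis = as.integer(n_basis), n_functionals = if (scenario == 1) 1L else 4L,
    eigen_scale = eigen_scale, eigen_decay = eigen_decay,
    noise_sd = noise_sd, train_frac = train_frac
  ), class = "fkmr_scenario")
}

#' Jittered common time grid
#'
#' Equally spaced points on `[0, 1]` perturbed by independent
#' `N(0, jitter_var)` deviations, clipped back to `[0, 1]` and sorted. All
#' subjects of a replicate share the grid.
#'
#' @param config A [scenario_config()] object.
#' @return Sorted numeric vector of length `config$n_grid` in `[0, 1]`.
#' @export
sample_time_grid <- function(config) {
  assert_that(inherits(config, "fkmr_scenario"), "config must come from scenario_config()")
  base <- seq(0, 1, length.out = config$n_grid)
  if (config$jitter_var == 0) return(base)
  g <- base + rnorm(config$n_grid, sd = sqrt(config$jitter_var))
  g <- sort(pmin(1, pmax(0, g)))
  untie_grid(g)
}

# clipping at 0/1 can stack points; spread tied runs evenly toward the next
# distinct value (backwards for a tied run at the upper end) so the grid is
# strictly increasing
untie_grid <- function(g) {
  m <- length(g)
  i <- 1L
  while (i < m) {
    j <- i
    while (j < m && g[j + 1L] == g[i]) j <- j + 1L
    if (j > i) {
      k <- j - i + 1L
      if (j < m) {
        g[i:j] <- g[i] + (g[j + 1L] - g[i]) * (0:(k - 1L)) / k
      } else {
        lo <- if (i > 1L) g[i - 1L] else g[i] - 1e-6 * k
        g[i:j] <- lo + (g[j] - lo) * (1:k) / k
      }
    }
    i <- j + 1L
  }
  g
}

#' True nonlinear effect of the signal features
#'
#' Evaluates the scenario's data-generating function `h` on a feature
#' matrix, excluding the scalar-covariate term and the noise. Scenario 1
#' (15 features of one functional; signals are features 2 and 9):
#' \deqn{h = 20\cos(2\pi\zeta_2) - 10\sin(2\pi\zeta_9) + \zeta_2\zeta_9.}
#' Scenario 2 (4 blocks of 9; signals are features 1, 3, 4 of block 1 and
#' 2, 7 of block 2):
#' \deqn{h = \zeta_{11}+\zeta_{31}+\zeta_{41}+\zeta_{22}+\zeta_{72}
#'   + 10\cos(2\pi\zeta_{11}) - 10\zeta_{22}^2 + 10\zeta_{72}^2
#'   - 10\zeta_{31}^2 + 10 e^{-\zeta_{31}}\zeta_{41}
#'   - 8\sin(2\pi\zeta_{72})\cos(2\pi\zeta_{31}) + 20\zeta_{11}\zeta_{72}.}
#'
#' @param scenario 1 or 2.
#' @param zeta Numeric matrix of features in `[0, 1]`, one row per subject,
#'   with 15 columns (Scenario 1) or 36 columns (Scenario 2, blocks of 9).
#' @return Numeric vector `h(zeta_i)`, one value per row.
#' @export
true_h <- function(scenario, zeta) {
  zeta <- as.matrix(zeta)
  assert_that(all(zeta >= 0 & zeta <= 1), "zeta entries must lie in [0, 1]")
  if (scenario == 1) {
    assert_that(ncol(zeta) == 15L, "Scenario 1 expects 15 feature columns, got %d",
                ncol(zeta))
    z2 <- zeta[, 2L]; z9 <- zeta[, 9L]
    20 * cos(2 * pi * z2) - 10 * sin(2 * pi * z9) + z2 * z9
  } else if (scenario == 2) {
    assert_that(ncol(zeta) == 36L, "Scenario 2 expects 36 feature columns, got %d",
                ncol(zeta))
    z11 <- zeta[, 1L]; z31 <- zeta[, 3L]; z41 <- zeta[, 4L]
    z22 <- zeta[, 9L + 2L]; z72 <- zeta[, 9L + 7L]
    z11 + z31 + z41 + z22 + z72 +
      10 * cos(2 * pi * z11) - 10 * z22^2 + 10 * z72^2 - 10 * z31^2 +
      10 * exp(-z31) * z41 - 8 * sin(2 * pi * z72) * cos(2 * pi * z31) +
      20 * z11 * z72
  } else {
    abort_fkmr("unknown scenario %s", format(scenario))
  }
}

# index sets of signal features/groups for a scenario, in grand-vector order
signal_sets <- function(config) {
  if (config$scenario == 1) {
    list(features = c(2L, 9L), groups = 1L)
  } else {
    list(features = c(1L, 3L, 4L, config$n_basis + 2L, config$n_basis + 7L),
         groups = c(1L, 2L))
  }
}

#' Simulate a benchmark dataset
#'
#' Draws one replicate of the scenario defined by `config`: standard-normal
#' scores per component and functional, probit-transformed features, curves
#' from the Karhunen-Loeve expansion on a jittered common grid, a scalar
#' covariate, and the outcome \eqn{y_i = 2 x_i + h(\zeta_i) + \epsilon_i}.
#' Subjects are split train/test in simulation order (the paths are iid, so
#' the assignment carries no information).
#'
#' @param config A [scenario_config()] object, or a scenario number that is
#'   passed to [scenario_config()].
#' @param seed Integer seed; the whole replicate is reproducible given it.
#' @param ... Passed to [scenario_config()] when `config` is a number.
#' @return A list of class `"fkmr_sim"` with elements
#'   \describe{
#'     \item{curves}{long tibble `(subject_id, functional_id, t, value)`}
#'     \item{curve_matrices}{list of `n x m` matrices, one per functional}
#'     \item{grid}{the shared time grid}
#'     \item{scalars}{tibble `(subject_id, x, y)`}
#'     \item{true_zeta}{`n x s` matrix of the generating features}
#'     \item{true_h}{numeric vector `h(zeta_i)`}
#'     \item{signal_features, signal_groups}{index sets of the true signals}
#'     \item{group_sizes}{feature-block sizes `(s_1, ..., s_p)`}
#'     \item{train_index, test_index}{the subject split}
#'     \item{config}{the scenario configuration}
#'   }
#' @export
#' @examples
#' sim <- simulate_dataset(scenario_config(1, n_subjects = 20), seed = 1)
#' dim(sim$true_zeta)
simulate_dataset <- function(config, seed = NULL, ...) {
  if (!inherits(config, "fkmr_scenario")) config <- scenario_config(config, ...)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects; m <- config$n_grid
  s_l <- config$n_basis; p <- config$n_functionals
  grid <- sample_time_grid(config)
  sig <- config$eigen_scale * config$eigen_decay^(seq_len(s_l))
  basis <- vapply(seq_len(s_l), fourier_basis, numeric(m), t = grid) # m x s_l

  xi <- array(rnorm(n * s_l * p), dim = c(n, s_l, p))
  curve_matrices <- vector("list", p)
  for (l in seq_len(p)) {
    curve_matrices[[l]] <- (xi[, , l] %*% (sig * t(basis)))
  }
  names(curve_matrices) <- paste0("Z", seq_len(p))
  zeta <- do.call(cbind, lapply(seq_len(p), function(l) pnorm(xi[, , l])))
  colnames(zeta) <- unlist(lapply(seq_len(p), function(l)
    paste0("zeta_", l, "_", seq_len(s_l))))

  x <- rnorm(n)
  h <- true_h(config$scenario, zeta)
  y <- 2 * x + h + rnorm(n, sd = config$noise_sd)

  n_train <- round(config$train_frac * n)
  sets <- signal_sets(config)

  curves <- purrr::imap(curve_matrices, function(mat, id) {
    tibble::tibble(subject_id = rep(seq_len(n), each = m),
                   functional_id = id,
                   t = rep(grid, times = n),
                   value = as.vector(t(mat)))
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$subject_id, .data$functional_id, .data$t)

  structure(list(
    curves = curves,
    curve_matrices = curve_matrices,
    grid = grid,
    scalars = tibble::tibble(subject_id = seq_len(n), x = x, y = y),
    true_zeta = zeta,
    true_h = h,
    signal_features = sets$features,
    signal_groups = sets$groups,
    group_sizes = rep(s_l, p),
    train_index = seq_len(n_train),
    test_index = if (n_train < n) seq.int(n_train + 1L, n) else integer(0),
    config = config
  ), class = "fkmr_sim")
}
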