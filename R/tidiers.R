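#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an FKMR fit
#'
#' One row per FPC feature: the reported scaling magnitude
#' \eqn{|\hat\gamma_j|}, its functional group, and whether the feature is
#' selected at the fit's zero threshold.
#'
#' @param x An `"fkmr_fit"`.
#' @param ... Unused.
#' @return Tibble with columns `feature`, `group`, `gamma`, `selected`.
#' @export
tidy.fkmr_fit <- function(x, ...) {
  gi <- rep(seq_along(x$groups), times = x$groups)
  tibble::tibble(
    feature = x$feature_names %||% paste0("feature_", seq_along(x$gamma)),
    group = x$group_labels[gi],
    gamma = x$gamma,
    selected = seq_along(x$gamma) %in% x$selected$features
  )
}

#' Glance at an FKMR fit
#'
#' @param x An `"fkmr_fit"`.
#' @param ... Unused.
#' @return One-row tibble: penalty settings, variance components, selected
#'   counts, convergence.
#' @export
glance.fkmr_fit <- function(x, ...) {
  tibble::tibble(
    penalty = x$penalty$family, delta = x$delta,
    lambda1 = x$lambda1, lambda2 = x$lambda2,
    tau = x$tau, sigma2 = x$sigma2,
    n = length(x$alpha), s = length(x$gamma),
    n_selected = length(x$selected$features),
    n_groups_selected = length(x$selected$groups),
    n_outer_iterations = x$n_outer_iterations,
    converged = x$converged
  )
}

#' Tidy a replicate study
#'
#' One row per replicate and method with the accuracy metrics; selection
#' indicator list-columns are dropped (see [selection_frequencies()]).
#'
#' @param x An `"fkmr_replicates"`.
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.fkmr_replicates <- function(x, ...) {
  dplyr::select(x$results, -"selected_features", -"selected_groups")
}

#' Summarize a replicate study per method
#'
#' Means of the accuracy metrics over replicates plus selection sensitivity
#' and specificity at the feature level.
#'
#' @param x An `"fkmr_replicates"`.
#' @param ... Unused.
#' @return Tibble, one row per method.
#' @export
glance.fkmr_replicates <- function(x, ...) {
  truth <- x$truth$signal_features
  x$results |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(df, key) {
      sel <- do.call(rbind, df$selected_features)
      sm <- selection_metrics(sel, truth)
      tibble::tibble(
        n_replicates = nrow(df),
        raq2 = mean(df$raq2), rq2 = mean(df$rq2), beta = mean(df$beta),
        intercept = mean(df$intercept), slope = mean(df$slope),
        r2 = mean(df$r2), k = mean(df$k),
        sensitivity = sm$sensitivity, specificity = sm$specificity
      )
    }) |>
    dplyr::ungroup()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
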