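#' Write and read long-format curve tables
#'
#' Curves are exchanged as CSV in long format with columns `subject_id`,
#' `functional_id`, `t`, `value`; every subject of a functional predictor
#' must be sampled on the same grid (`t` is dimensionless on `[0, 1]`;
#' rescale real time axes before import).
#'
#' @param curves Long tibble of curves (e.g. `simulate_dataset()$curves`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  assert_that(all(c("subject_id", "functional_id", "t", "value") %in% names(curves)),
              "curves must have columns subject_id, functional_id, t, value")
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @return `read_curves`: list with `matrices` (per-functional `n x m`),
#'   `grid`, `subjects` and the long `curves` tibble.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(c("subject_id", "functional_id", "t", "value"), names(df))
  assert_that(length(missing_cols) == 0L,
              "missing column(s): %s", paste(missing_cols, collapse = ", "))
  curves <- tibble::as_tibble(df)
  parsed <- curves_to_matrices(curves)
  c(parsed, list(curves = curves))
}

fit_schema_version <- 1L

#' Save and load an FKMR fit as JSON
#'
#' All fields needed to reproduce predictions (coefficients, scaling,
#' training features, penalty settings) are stored at full double
#' precision, together with a schema version, the package version and a
#' configuration digest for provenance.
#'
#' @param fit An `"fkmr_fit"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_fit <- function(fit, path) {
  assert_that(inherits(fit, "fkmr_fit"), "fit must be an fkmr_fit object")
  payload <- list(
    schema_version = fit_schema_version,
    package_version = as.character(utils::packageVersion("fkmr")),
    config_hash = config_digest(fit),
    beta = fit$beta, alpha = fit$alpha, gamma = fit$gamma,
    lambda1 = fit$lambda1, lambda2 = fit$lambda2, delta = fit$delta,
    tau = fit$tau, sigma2 = fit$sigma2,
    penalty_family = fit$penalty$family, mcp_a = fit$penalty$mcp_a,
    groups = fit$groups, group_labels = fit$group_labels,
    feature_names = fit$feature_names,
    bandwidth_p = fit$bandwidth_p, tol_select = fit$tol_select,
    algorithm = fit$algorithm, converged = fit$converged,
    objective_trace = fit$objective_trace,
    n_outer_iterations = fit$n_outer_iterations,
    Z_train = fit$Z_train
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_fit
#' @return `load_fit`: the reconstructed `"fkmr_fit"`.
#' @export
load_fit <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("schema_version", "beta", "alpha", "gamma", "lambda1",
                "lambda2", "groups", "bandwidth_p", "Z_train")
  missing_fields <- setdiff(required, names(payload))
  assert_that(length(missing_fields) == 0L,
              "fit file is missing field(s): %s",
              paste(missing_fields, collapse = ", "))
  assert_that(identical(as.integer(payload$schema_version), fit_schema_version),
              "unsupported fit schema version %s", payload$schema_version)
  Z <- as.matrix(payload$Z_train)
  colnames(Z) <- payload$feature_names
  spec <- penalty_spec(payload$penalty_family, groups = payload$groups,
                       delta = payload$delta %||% 0.05,
                       mcp_a = payload$mcp_a %||% 3)
  sel <- selected_features(payload$gamma, payload$groups,
                           payload$tol_select %||% 1e-6)
  new_fkmr_fit(
    beta = payload$beta, alpha = payload$alpha, gamma = payload$gamma,
    lambda1 = payload$lambda1, lambda2 = payload$lambda2,
    delta = payload$delta %||% 0.05, penalty = spec,
    tau = payload$tau, sigma2 = payload$sigma2,
    h_hat = NULL, fitted = NULL,
    objective_trace = payload$objective_trace,
    selected = sel, feature_names = payload$feature_names,
    group_labels = payload$group_labels, groups = payload$groups,
    Z_train = Z, bandwidth_p = payload$bandwidth_p,
    algorithm = payload$algorithm,
    n_outer_iterations = payload$n_outer_iterations,
    converged = payload$converged, tol_select = payload$tol_select %||% 1e-6
  )
}

config_digest <- function(fit) {
  key <- paste(fit$penalty$family, fit$delta, fit$lambda1, fit$lambda2,
               paste(fit$groups, collapse = ","), fit$bandwidth_p, sep = "|")
  # small stable polynomial digest; avoids a dependency on a hash package
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
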