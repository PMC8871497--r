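# small simulated fixtures shared across test files; everything is built in
# code under fixed seeds

tiny_scenario1 <- function(n = 60, seed = 101) {
  simulate_dataset(scenario_config(1, n_subjects = n), seed = seed)
}

tiny_scenario2 <- function(n = 120, seed = 202) {
  simulate_dataset(scenario_config(2, n_subjects = n), seed = seed)
}

# deterministic low-dimensional kernel-machine instance for solver tests;
# the outcome carries a genuine kernel-distributed effect h ~ N(0, 2K)
toy_kernel_problem <- function(n = 30, s = 4, seed = 7) {
  set.seed(seed)
  Z <- matrix(runif(n * s), n, s)
  alpha <- rnorm(n, sd = 0.3)
  x <- matrix(rnorm(n), n, 1)
  K <- kernel_matrix(Z, 1)
  h <- sqrt(2) * drop(crossprod(chol(K + diag(1e-8, n)), rnorm(n)))
  y <- drop(2 * x) + h + rnorm(n)
  list(Z = Z, alpha = alpha, x = x, y = y, n = n, s = s)
}
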