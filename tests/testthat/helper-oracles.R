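# Independent dense-Gaussian oracles: determinant/inverse based, no Cholesky,
# deliberately separate from the package's solve paths.

oracle_log_dmvnorm <- function(y, mu, S) {
  n <- length(y)
  r <- y - mu
  as.numeric(
    -0.5 * t(r) %*% solve(S, r) -
      0.5 * determinant(S, logarithm = TRUE)$modulus -
      0.5 * n * log(2 * pi)
  )
}

# latent posterior by the textbook precision formula (K^-1 + D^-1)^-1
oracle_latent_posterior <- function(K, tau2_per_sample, m) {
  D <- diag(tau2_per_sample, length(m))
  M <- solve(solve(K) + solve(D))
  list(mean = as.vector(M %*% solve(D, m)), cov = M)
}

# conditional of component `new` given the rest, from the joint covariance
oracle_conditional <- function(Kjoint, z_obs, new_idx) {
  obs <- setdiff(seq_len(nrow(Kjoint)), new_idx)
  Koo <- Kjoint[obs, obs, drop = FALSE]
  Kno <- Kjoint[new_idx, obs, drop = FALSE]
  Knn <- Kjoint[new_idx, new_idx]
  list(
    mean = as.vector(Kno %*% solve(Koo, z_obs)),
    var = as.numeric(Knn - Kno %*% solve(Koo, t(Kno)))
  )
}

# small two-group dataset with well-separated inputs (invertible kernels)
toy_data <- function(n = 6, seed = 42, tau2 = c(0.1, 0.3), beta = c(0, 0),
                     a = 1, b = 1, sigma2 = 1) {
  simulate_mggp(
    n_per_group = c(ceiling(n / 2), floor(n / 2)),
    sigma2 = sigma2, a = a, b = b, tau2 = tau2, beta = beta, seed = seed
  )
}

rand_params <- function() {
  list(
    sigma2 = exp(runif(1, log(0.1), log(10))),
    a = exp(runif(1, log(0.01), log(10))),
    b = exp(runif(1, log(0.1), log(3))),
    c = runif(1, 0.5, 3),
    nu = sample(c(0.5, 1.5, 2.5), 1)
  )
}
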