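test_that("collapsed likelihood matches closed forms and the dense oracle", {
  gs <- mggp_groups("A")
  k <- mggp_kernel("mg_rbf", gs, sigma2 = 1.3, a = 1, b = 1)
  d1 <- tibble::tibble(x1 = 0, group = "A", y = 0)
  expect_equal(
    log_marginal_likelihood(d1, k, tau2 = 0.4),
    -0.5 * log(2 * pi * (1.3 + 0.4))
  )

  d <- toy_data(n = 8, seed = 9)
  kern <- attr(d, "kernel")
  ll <- log_marginal_likelihood(d, kern, tau2 = c(0.1, 0.3))
  gd <- as_grouped_data(d)
  K <- kernel_matrix(kern, gd$X, gd$group, jitter = 0)
  tau_s <- ifelse(gd$group == "g1", 0.1, 0.3)
  expect_equal(ll, oracle_log_dmvnorm(gd$y, rep(0, 8), K + diag(tau_s)),
    tolerance = 1e-8
  )
  skip_if_not_installed("mvtnorm")
  expect_equal(
    ll,
    mvtnorm::dmvnorm(gd$y, rep(0, 8), K + diag(tau_s), log = TRUE),
    tolerance = 1e-8
  )
})

test_that("likelihood is invariant to permuting the samples", {
  d <- toy_data(n = 8, seed = 10)
  kern <- attr(d, "kernel")
  ll <- log_marginal_likelihood(d, kern, tau2 = 0.2, beta = c(0.5, -0.5))
  set.seed(1)
  dperm <- d[sample(nrow(d)), ]
  expect_equal(
    log_marginal_likelihood(dperm, kern, tau2 = 0.2, beta = c(0.5, -0.5)),
    ll
  )
})

test_that("likelihood at a -> 0 matches the union process", {
  d <- toy_data(n = 30, seed = 11)
  gs <- attr(d, "kernel")$groups
  ugp <- baseline_kernel("ugp", gs, sigma2 = 1, b = 1)
  mg <- mggp_kernel("mg_rbf", gs, sigma2 = 1, a = 1e-5, b = 1)
  expect_equal(
    log_marginal_likelihood(d, mg, tau2 = 0.1),
    log_marginal_likelihood(d, ugp, tau2 = 0.1),
    tolerance = 1e-4
  )
})

test_that("latent posterior matches the dense precision-form oracle", {
  d <- toy_data(n = 8, seed = 12, beta = c(1, -1))
  kern <- attr(d, "kernel")
  gd <- as_grouped_data(d)
  tau2 <- c(g1 = 0.15, g2 = 0.25)
  lp <- latent_posterior(d, kern, tau2 = tau2, beta = c(1, -1))
  K <- kernel_matrix(kern, gd$X, gd$group, jitter = 0)
  tau_s <- unname(tau2[gd$group])
  m <- gd$y - as.vector(gd$F %*% c(1, -1))
  orac <- oracle_latent_posterior(K, tau_s, m)
  expect_equal(lp$mean, orac$mean, tolerance = 1e-8)
  expect_equal(lp$cov, orac$cov, tolerance = 1e-8)
})

test_that("latent posterior limits: no information and interpolation", {
  d <- toy_data(n = 8, seed = 13)
  kern <- attr(d, "kernel")
  gd <- as_grouped_data(d)
  K <- kernel_matrix(kern, gd$X, gd$group, jitter = 0)
  # tau2 -> infinity: prior mean 0, prior covariance K
  lp_inf <- latent_posterior(d, kern, tau2 = 1e12)
  expect_lt(max(abs(lp_inf$mean)), 1e-8)
  expect_equal(lp_inf$cov, K, tolerance = 1e-6, ignore_attr = TRUE)
  # tau2 -> 0: posterior mean interpolates the residual
  lp0 <- latent_posterior(d, kern, tau2 = 1e-10)
  expect_equal(lp0$mean, gd$y, tolerance = 1e-4)
})

test_that("latent prediction: reproduction, prior reversion, dense oracle", {
  d <- toy_data(n = 6, seed = 14)
  kern <- attr(d, "kernel")
  z <- d$z_true
  # conditioning at a training point reproduces the latent value
  pr <- predict_latent(d, kern, z, d[2, ], jitter = 0)
  expect_equal(pr$.mean, z[2], tolerance = 1e-6)
  expect_lt(pr$.var, 1e-8)
  # far from all data: prior mean 0 and prior variance sigma^2
  far <- tibble::tibble(x1 = 500, group = "g1")
  pf <- predict_latent(d, kern, z, far, jitter = 0)
  expect_equal(pf$.mean, 0, tolerance = 1e-8)
  expect_equal(pf$.var, kern$sigma2, tolerance = 1e-6)
  # joint-conditioning oracle at a new interior point
  new <- tibble::tibble(x1 = 0.123, group = "g2")
  pn <- predict_latent(d, kern, z, new, jitter = 0)
  gd <- as_grouped_data(d)
  Xj <- rbind(gd$X, 0.123)
  gj <- c(gd$group, "g2")
  Kj <- kernel_matrix(kern, Xj, gj, X2 = Xj, groups2 = gj)
  orac <- oracle_conditional(Kj, z, nrow(Xj))
  expect_equal(pn$.mean, orac$mean, tolerance = 1e-8)
  expect_equal(pn$.var, orac$var, tolerance = 1e-8)
  # posterior variance bounded by the prior variance
  expect_lte(pn$.var, kern$sigma2 + 1e-10)
  expect_error(predict_latent(d, kern, z, tibble::tibble(x1 = 0, group = "zz")))
})

test_that("point prediction: reproduction, unseen groups, dense oracle", {
  d <- toy_data(n = 8, seed = 15, beta = c(2, -1))
  kern <- attr(d, "kernel")
  # test set = train set with no jitter reproduces the responses
  pr <- predict_gp_mean(d, kern, d, jitter = 0)
  expect_equal(pr$.pred, d$y, tolerance = 1e-6)
  # a separate-GP prediction for a group with no training data reverts to
  # the group-centered mean (zero on the centered scale)
  gs3 <- mggp_groups(c("g1", "g2", "g3"))
  sgp <- baseline_kernel("sgp", gs3, sigma2 = 1, b = 1)
  pr3 <- predict_gp_mean(d, sgp, tibble::tibble(x1 = 0, group = "g3"))
  expect_equal(pr3$.pred_centered, 0)
  expect_equal(pr3$.pred, 0)
  # dense linear-solve oracle with the noise variant
  gd <- as_grouped_data(d)
  K <- kernel_matrix(kern, gd$X, gd$group, jitter = 0)
  tau_s <- rep(0.2, 8)
  new <- tibble::tibble(x1 = c(-0.4, 0.9), group = c("g1", "g2"))
  kx <- kernel_matrix(kern, as.matrix(new$x1), new$group,
    X2 = gd$X,
    groups2 = gd$group
  )
  centers <- tapply(gd$y, gd$group, mean)
  yc <- gd$y - centers[gd$group]
  mu_orac <- as.numeric(kx %*% solve(K + diag(tau_s), yc)) +
    as.numeric(centers[new$group])
  prn <- predict_gp_mean(d, kern, new, include_noise = TRUE, tau2 = 0.2)
  expect_equal(prn$.pred, mu_orac, tolerance = 1e-8)
})

test_that("per-group centering uses training means only", {
  d <- toy_data(n = 10, seed = 16, beta = c(5, -5))
  kern <- attr(d, "kernel")
  test <- d[1:2, ]
  test$y <- test$y + 100 # test responses must not influence the centering
  pr1 <- predict_gp_mean(d, kern, test[, c("x1", "group")])
  pr2 <- predict_gp_mean(d, kern, test)
  expect_equal(pr1$.pred, pr2$.pred)
})

test_that("mean squared error is the plain average of squared residuals", {
  expect_equal(prediction_mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(prediction_mse(c(0, 2), c(0, 0)), 2)
  set.seed(17)
  y <- rnorm(20)
  mu <- rnorm(20)
  expect_equal(prediction_mse(y, mu), sum((y - mu)^2) / 20)
  expect_error(prediction_mse(1:3, 1:2))
})

test_that("grouped data round-trips through delimited text", {
  d <- toy_data(n = 6, seed = 18)
  path <- tempfile(fileext = ".csv")
  write_grouped_data(d[, c("x1", "group", "y")], path)
  d2 <- read_grouped_data(path)
  expect_equal(as.data.frame(d2), as.data.frame(d[, c("x1", "group", "y")]),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  gd <- as_grouped_data(d2)
  expect_equal(gd$n_j, c(g1 = 3L, g2 = 3L))
  expect_equal(colSums(gd$F), c(g1 = 3, g2 = 3))
  expect_true(all(rowSums(gd$F) == 1))
})
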