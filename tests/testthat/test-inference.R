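test_that("analytic likelihood gradients agree with finite differences", {
  d <- toy_data(n = 20, seed = 19, beta = c(1, -2))
  gd <- as_grouped_data(d)
  ctx <- mggp:::make_lik_context(gd, "mg_rbf", 1, shared_tau2 = FALSE)
  v <- list(sigma2 = 1.4, a = 0.7, b = 1.2, tau2_g1 = 0.12, tau2_g2 = 0.33)
  beta <- c(0.8, -1.5)
  free_pos <- names(v)
  out <- mggp:::ctx_loglik(ctx, v, beta,
    grad = TRUE, free_pos = free_pos,
    free_beta = TRUE
  )
  h <- 1e-6
  for (i in seq_along(free_pos)) {
    vp <- v
    vm <- v
    vp[[i]] <- v[[i]] * exp(h)
    vm[[i]] <- v[[i]] * exp(-h)
    fd <- (mggp:::ctx_loglik(ctx, vp, beta)$value -
      mggp:::ctx_loglik(ctx, vm, beta)$value) / (2 * h)
    expect_equal(out$grad[i], fd,
      tolerance = 1e-5,
      info = paste("param", free_pos[i])
    )
  }
  for (j in 1:2) {
    bp <- beta
    bm <- beta
    bp[j] <- beta[j] + h
    bm[j] <- beta[j] - h
    fd <- (mggp:::ctx_loglik(ctx, v, bp)$value -
      mggp:::ctx_loglik(ctx, v, bm)$value) / (2 * h)
    expect_equal(out$grad[length(free_pos) + j], fd, tolerance = 1e-5)
  }
})

test_that("hierarchical-GP gradients also match finite differences", {
  d <- toy_data(n = 16, seed = 20)
  gd <- as_grouped_data(d)
  ctx <- mggp:::make_lik_context(gd, "hgp", 1, shared_tau2 = TRUE)
  v <- list(sigma2 = 0.6, b = 0.9, tau2 = 0.2)
  out <- mggp:::ctx_loglik(ctx, v, c(0, 0),
    grad = TRUE,
    free_pos = names(v)
  )
  h <- 1e-6
  for (i in seq_along(v)) {
    vp <- v
    vm <- v
    vp[[i]] <- v[[i]] * exp(h)
    vm[[i]] <- v[[i]] * exp(-h)
    fd <- (mggp:::ctx_loglik(ctx, vp, c(0, 0))$value -
      mggp:::ctx_loglik(ctx, vm, c(0, 0))$value) / (2 * h)
    expect_equal(out$grad[i], fd, tolerance = 1e-5, info = names(v)[i])
  }
})

test_that("maximum likelihood respects pins, positivity and restarts", {
  d <- toy_data(n = 40, seed = 21)
  f <- fit_mle(d, "mg_rbf",
    fixed = list(sigma2 = 1, b = 1, tau2 = 0.1),
    restarts = 2
  )
  expect_s3_class(f, "mggp_mle")
  expect_true(all(unlist(f$estimates) > 0))
  expect_equal(f$estimates$sigma2, 1)
  expect_equal(f$free, "a")
  expect_true(f$converged)
  expect_equal(f$n_restarts_used, 2)
  # the profiled similarity estimate lands near the generating value 1
  expect_gt(f$estimates$a, 0.2)
  expect_lt(f$estimates$a, 5)
  expect_error(
    fit_mle(d, "mg_rbf",
      fixed = list(sigma2 = 1, a = 1, b = 1, tau2 = 0.1)
    ),
    "at least one parameter"
  )
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "fixed") %in% names(td)))
  expect_equal(glance(f)$logLik, f$logLik)
})

test_that("profile likelihood over a peaks near truth and hits both limits", {
  d <- toy_data(n = 60, seed = 22)
  gs <- attr(d, "kernel")$groups
  prof <- profile_loglik_a(d, fixed = list(sigma2 = 1, b = 1, tau2 = 0.1))
  expect_equal(names(prof), c("a", "log_lik"))
  # peak at the grid point nearest the generating a = 1
  expect_equal(prof$a[which.max(prof$log_lik)], 1)
  # a -> 0 endpoint matches the union-GP likelihood
  ll_ugp <- log_marginal_likelihood(
    d, baseline_kernel("ugp", gs, sigma2 = 1, b = 1),
    tau2 = 0.1
  )
  expect_lt(abs(prof$log_lik[prof$a == 1e-5] - ll_ugp), 1e-3)
  # large-a endpoint approaches the separate-GP likelihood
  ll_sgp <- log_marginal_likelihood(
    d, baseline_kernel("sgp", gs, sigma2 = 1, b = 1),
    tau2 = 0.1
  )
  prof_hi <- profile_loglik_a(d,
    a_grid = 1e6,
    fixed = list(sigma2 = 1, b = 1, tau2 = 0.1)
  )
  expect_lt(abs(prof_hi$log_lik - ll_sgp), 1e-3)
  # the reoptimizing mode returns one value per grid point
  prof2 <- profile_loglik_a(d,
    a_grid = c(0.1, 1), reoptimize = TRUE,
    fixed = list(sigma2 = 1, tau2 = 0.1), restarts = 1
  )
  expect_equal(nrow(prof2), 2)
})

test_that("prior-only MCMC reproduces the inverse-gamma prior quantiles", {
  d <- toy_data(n = 10, seed = 23)
  fit <- bayes_fit(d,
    chains = 2, warmup = 100, iter = 1000, seed = 3,
    likelihood = FALSE
  )
  qa <- quantile(fit$draws$a, c(0.25, 0.5, 0.75))
  qs <- quantile(fit$draws$sigma2, c(0.25, 0.5, 0.75))
  # closed-form inverse-gamma quantiles: 1/qgamma(1 - p, shape, rate = scale)
  expect_equal(unname(qa), 1 / qgamma(c(0.75, 0.5, 0.25), 5, rate = 5),
    tolerance = 0.12
  )
  expect_equal(unname(qs), 1 / qgamma(c(0.75, 0.5, 0.25), 1, rate = 1),
    tolerance = 0.25
  )
  # beta draws follow their normal prior
  expect_equal(mean(fit$draws$beta_g1), 0, tolerance = 0.15)
  expect_equal(sd(fit$draws$beta_g1), 1, tolerance = 0.15)
  # noise prior sits on the SD scale: sqrt(tau2) draws are IG(5, 5)
  qt <- quantile(sqrt(fit$draws$tau2_g1), c(0.25, 0.5, 0.75))
  expect_equal(unname(qt), 1 / qgamma(c(0.75, 0.5, 0.25), 5, rate = 5),
    tolerance = 0.12
  )
  # and the variance-scale option puts IG(5, 5) on tau2 itself
  fitv <- bayes_fit(d,
    priors = mggp_priors(tau_prior_on = "variance"),
    chains = 2, warmup = 100, iter = 1000, seed = 3, likelihood = FALSE
  )
  qv <- quantile(fitv$draws$tau2_g1, c(0.25, 0.5, 0.75))
  expect_equal(unname(qv), 1 / qgamma(c(0.75, 0.5, 0.25), 5, rate = 5),
    tolerance = 0.12
  )
})

test_that("MCMC is deterministic given the seed and reports diagnostics", {
  d <- toy_data(n = 16, seed = 24)
  f1 <- bayes_fit(d, chains = 2, warmup = 50, iter = 60, seed = 7)
  f2 <- bayes_fit(d, chains = 2, warmup = 50, iter = 60, seed = 7)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(c("rhat", "ess", "mcse") %in% names(f1$diagnostics)))
  expect_true(all(f1$diagnostics$ess > 0))
  # positivity of every retained draw
  for (p in c("a", "b", "sigma2", "tau2_g1", "tau2_g2")) {
    expect_true(all(f1$draws[[p]] > 0), info = p)
  }
  td <- tidy(f1)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_s3_class(glance(f1), "tbl_df")
})

test_that("posterior predictive draws concentrate at near-noiseless training points", {
  d <- toy_data(n = 30, seed = 25, tau2 = c(1e-6, 1e-6), beta = c(1, 2))
  fit <- bayes_fit(d,
    chains = 2, warmup = 150, iter = 200, seed = 11,
    fixed = list(tau2_g1 = 1e-6, tau2_g2 = 1e-6)
  )
  pd <- sample_latent_and_predict(fit, d, d[3, c("x1", "group")], ndraws = 50)
  expect_equal(mean(pd$y), d$y[3], tolerance = 0.2)
  expect_lt(sd(pd$y), 0.2)
})

test_that("pairwise similarity enumerates, skips and orders group pairs", {
  # counts and skip flags without fitting
  d52 <- tibble::tibble(
    x1 = rnorm(52 * 3),
    group = rep(paste0("t", 1:52), each = 3),
    y = rnorm(52 * 3)
  )
  pw <- pairwise_a(d52, fit = FALSE)
  expect_equal(nrow(pw), 1326)
  expect_true(all(!pw$skipped))
  # a group below the minimum size is flagged
  dsmall <- dplyr::bind_rows(
    toy_data(n = 12, seed = 26),
    tibble::tibble(x1 = c(0, 1), group = "g3", y = c(0, 0.5), z_true = 0)
  )
  pw2 <- pairwise_a(dsmall, fit = FALSE, min_n = 3)
  expect_equal(nrow(pw2), 3)
  expect_equal(sum(pw2$skipped), 2)
  # similar groups prefer smaller a than dissimilar ones
  set.seed(27)
  gs3 <- mggp_groups(c("g1", "g2", "g3"),
    distances = matrix(c(0, 0.05, 1, 0.05, 0, 1, 1, 1, 0), 3)
  )
  dsim <- simulate_mggp(
    model = "mggp", n_per_group = c(40, 40, 40),
    labels = gs3$labels, distances = gs3$d, a = 2, b = 1,
    sigma2 = 1, tau2 = 0.05, seed = 28
  )
  pw3 <- pairwise_a(dsim, fixed = list(), restarts = 2, seed = 29)
  a12 <- pw3$a_hat[pw3$group1 == "g1" & pw3$group2 == "g2"]
  expect_lt(a12, max(pw3$a_hat))
  m <- pairwise_a_matrix(pw3)
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m["g1", "g2"], a12)
  expect_equal(m, t(m))
})
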