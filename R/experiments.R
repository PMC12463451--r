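# replicate seed stream: deterministic, bounded below 2^30
replicate_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2^30 - 1, n)
}

new_experiment <- function(type, results, config, summary = NULL) {
  structure(
    list(type = type, results = results, config = config, summary = summary),
    class = "mggp_experiment"
  )
}

#' @export
print.mggp_experiment <- function(x, ...) {
  cat("<mggp_experiment> type=", x$type, ", ",
    nrow(x$results), " result rows\n",
    sep = ""
  )
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Model-comparison study: log marginal likelihood across process models
#'
#' Generates two-group data from each of the candidate processes (separate,
#' union, hierarchical, multi-group) and evaluates the collapsed log
#' marginal likelihood of every dataset under every model, with parameters
#' pinned to the generating truth and the multi-group model swept over a
#' grid of group-similarity scales `a`. In the expected regimes the
#' multi-group likelihood matches the union model as `a -> 0`, matches the
#' separate model for large `a`, and on multi-group data peaks near the
#' generating `a`, exceeding all baselines there.
#'
#' @param n_per_group Samples per group (two groups).
#' @param a_grid Grid of `a` values for the multi-group model.
#' @param replicates Number of simulation replicates.
#' @param sigma2,a,b,tau2 Generating truth (`a` is used only when
#'   generating from the multi-group model).
#' @param gen_models Generating processes to include.
#' @param p Input dimension.
#' @param seed Integer seed; each replicate uses a derived seed.
#' @return An `mggp_experiment` with a results tibble
#'   (`gen_model`, `replicate`, `fit_model`, `a`, `log_lik`); `a` is `NA`
#'   for the baselines. Use [ggplot2::autoplot()] for the likelihood-curve
#'   figure.
#' @export
run_model_comparison <- function(n_per_group = 100, a_grid = 10^seq(-5, 2),
                                 replicates = 20, sigma2 = 1, a = 1, b = 1,
                                 tau2 = 0.1,
                                 gen_models = c("sgp", "ugp", "hgp", "mggp"),
                                 p = 1L, seed = 1) {
  seeds <- replicate_seeds(seed, length(gen_models) * replicates)
  gs <- mggp_groups(c("g1", "g2"))
  fits <- list(
    sgp = baseline_kernel("sgp", gs, p = p, sigma2 = sigma2, b = b),
    ugp = baseline_kernel("ugp", gs, p = p, sigma2 = sigma2, b = b),
    hgp = baseline_kernel("hgp", gs, p = p, sigma2 = sigma2, b = b)
  )
  rows <- list()
  ctr <- 0L
  for (g in gen_models) {
    for (r in seq_len(replicates)) {
      ctr <- ctr + 1L
      d <- simulate_mggp(
        model = g, n_per_group = rep(n_per_group, 2), p = p,
        sigma2 = sigma2, a = a, b = b, tau2 = tau2, seed = seeds[ctr]
      )
      for (fm in names(fits)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gen_model = g, replicate = r, fit_model = fm, a = NA_real_,
          log_lik = log_marginal_likelihood(d, fits[[fm]], tau2 = tau2)
        )
      }
      prof <- profile_loglik_a(d,
        a_grid = a_grid, groups = gs,
        fixed = list(sigma2 = sigma2, b = b, tau2 = tau2)
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gen_model = g, replicate = r, fit_model = "mggp",
        a = prof$a, log_lik = prof$log_lik
      )
    }
  }
  new_experiment(
    "model_comparison", dplyr::bind_rows(rows),
    list(
      n_per_group = n_per_group, a_grid = a_grid, replicates = replicates,
      sigma2 = sigma2, a = a, b = b, tau2 = tau2, p = p, seed = seed
    )
  )
}

#' Recovery of the group-similarity scale by maximum likelihood
#'
#' Simulates two-group data from the multi-group RBF process at several
#' true values of `a` and re-estimates `a` by maximizing the collapsed
#' likelihood in each replicate. By default the remaining parameters are
#' pinned to their generating values (profile estimation of `a`); set
#' `pin_others = FALSE` to optimize all parameters jointly. The summary
#' reports the median and interquartile range of \eqn{\hat a} per true
#' value and whether the medians are monotone nondecreasing in the truth.
#'
#' @inheritParams run_model_comparison
#' @param true_a Vector of generating `a` values.
#' @param pin_others Pin `b`, `sigma2`, `tau2` to truth while estimating
#'   `a`?
#' @param restarts Optimizer restarts per fit.
#' @return An `mggp_experiment` with per-replicate `a_hat` values and a
#'   per-truth summary (median/quartiles, `monotone` flag in `$summary`).
#' @export
run_mle_recovery <- function(true_a = c(1e-3, 1e-2, 1e-1, 1),
                             replicates = 10, n_per_group = 100,
                             sigma2 = 1, b = 1, tau2 = 0.1, p = 1L,
                             pin_others = TRUE, restarts = 2, seed = 1) {
  seeds <- replicate_seeds(seed, length(true_a) * replicates)
  rows <- list()
  ctr <- 0L
  for (ta in true_a) {
    for (r in seq_len(replicates)) {
      ctr <- ctr + 1L
      d <- simulate_mggp(
        model = "mggp", n_per_group = rep(n_per_group, 2),
        p = p, sigma2 = sigma2, a = ta, b = b, tau2 = tau2,
        seed = seeds[ctr]
      )
      fixed <- if (pin_others) {
        list(sigma2 = sigma2, b = b, tau2 = tau2)
      } else {
        list()
      }
      f <- fit_mle(d, "mg_rbf",
        fixed = fixed, restarts = restarts,
        seed = seeds[ctr]
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        true_a = ta, replicate = r, a_hat = f$estimates$a,
        sigma2_hat = f$estimates$sigma2, b_hat = f$estimates$b,
        log_lik = f$logLik
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  summ <- results |>
    dplyr::group_by(.data$true_a) |>
    dplyr::summarise(
      median_a_hat = stats::median(.data$a_hat),
      q25 = stats::quantile(.data$a_hat, 0.25),
      q75 = stats::quantile(.data$a_hat, 0.75),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$true_a)
  summ$monotone <- !is.unsorted(summ$median_a_hat)
  new_experiment(
    "mle_recovery", results,
    list(
      true_a = true_a, replicates = replicates, n_per_group = n_per_group,
      sigma2 = sigma2, b = b, tau2 = tau2, pin_others = pin_others,
      seed = seed
    ),
    summary = summ
  )
}

model_family <- function(model, mggp_family = "mg_rbf") {
  if (model == "mggp") mggp_family else model
}

#' Held-out prediction benchmark across process models
#'
#' Generates grouped data from each requested process, splits each dataset
#' into training and test halves (stratified by group), fits every
#' candidate model to the training half by maximum likelihood, predicts the
#' held-out responses by the conditional mean on group-centered data, and
#' records the mean squared error.
#'
#' @inheritParams run_model_comparison
#' @param gen_models Generating processes.
#' @param fit_models Models whose predictors are evaluated on each dataset.
#' @param split_fraction Fraction of each group used for training.
#' @param fit_mode `"pinned"` (default) conditions every model's predictor
#'   on the training half with kernel parameters set to the generating
#'   values (`sigma2`, `b`, `tau2`, and `a` for the multi-group model), the
#'   same convention as the likelihood comparison; `"mle"` re-estimates
#'   each model's parameters on the training half by maximum likelihood
#'   first.
#' @param centering `"dataset"` (default) removes each group's mean from
#'   the full dataset before splitting — the protocol of centering the
#'   data for each group around their mean; `"training"` centers by
#'   training-set group means only (no information flows from the test
#'   half).
#' @param include_noise Add the noise variance to the training covariance
#'   when conditioning (default `TRUE`; set `FALSE` for the pure
#'   interpolation formula).
#' @param restarts Optimizer restarts per fit (`fit_mode = "mle"`).
#' @param mggp_family Multi-group kernel family for the `"mggp"` model.
#' @return An `mggp_experiment` with tibble columns `gen_model`,
#'   `fit_model`, `replicate`, `mse`, plus a mean-MSE summary.
#' @export
run_prediction_benchmark <- function(gen_models = c("sgp", "ugp", "hgp", "mggp"),
                                     fit_models = c("sgp", "ugp", "hgp", "mggp"),
                                     n_per_group = 30, replicates = 20,
                                     split_fraction = 0.5, sigma2 = 1, a = 1,
                                     b = 1, tau2 = 0.1, p = 1L,
                                     fit_mode = c("pinned", "mle"),
                                     centering = c("dataset", "training"),
                                     include_noise = TRUE, restarts = 1,
                                     mggp_family = "mg_rbf", seed = 1) {
  fit_mode <- match.arg(fit_mode)
  centering <- match.arg(centering)
  seeds <- replicate_seeds(seed, length(gen_models) * replicates)
  rows <- list()
  ctr <- 0L
  for (g in gen_models) {
    for (r in seq_len(replicates)) {
      ctr <- ctr + 1L
      d <- simulate_mggp(
        model = g, n_per_group = rep(n_per_group, 2), p = p,
        sigma2 = sigma2, a = a, b = b, tau2 = tau2, seed = seeds[ctr]
      )
      if (centering == "dataset") {
        d$y <- d$y - stats::ave(d$y, d$group)
      }
      train_id <- split_by_group(d$group, split_fraction)
      train <- d[train_id, ]
      test <- d[!train_id, ]
      gs <- mggp_groups(unique(d$group))
      for (fm in fit_models) {
        fam <- model_family(fm, mggp_family)
        if (fit_mode == "mle") {
          f <- fit_mle(train, fam,
            groups = gs, restarts = restarts,
            seed = seeds[ctr]
          )
          kern <- f$kernel
          tau2_pred <- f$tau2
        } else {
          kern <- if (fm == "mggp") {
            mggp_kernel(fam, gs, p = p, sigma2 = sigma2, a = a, b = b)
          } else {
            baseline_kernel(fm, gs, p = p, sigma2 = sigma2, b = b)
          }
          tau2_pred <- tau2
        }
        pr <- predict_gp_mean(train, kern, test,
          include_noise = include_noise, tau2 = tau2_pred,
          center = centering == "training"
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gen_model = g, fit_model = fm, replicate = r,
          mse = prediction_mse(test$y, pr$.pred)
        )
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summ <- results |>
    dplyr::group_by(.data$gen_model, .data$fit_model) |>
    dplyr::summarise(mean_mse = mean(.data$mse), .groups = "drop")
  new_experiment(
    "prediction_benchmark", results,
    list(
      gen_models = gen_models, fit_models = fit_models,
      n_per_group = n_per_group, replicates = replicates,
      split_fraction = split_fraction, sigma2 = sigma2, a = a, b = b,
      tau2 = tau2, fit_mode = fit_mode, include_noise = include_noise,
      seed = seed
    ),
    summary = summ
  )
}

#' Prediction with imbalanced groups and an informative group metric
#'
#' Three-group design in which groups 1 and 2 are similar (group distance
#' `d_similar`) and group 3 is dissimilar to both (`d_dissimilar`). Data
#' are generated from the multi-group RBF process over this metric; the
#' sample sizes of groups 2 and 3 are fixed while group 1's size varies.
#' Each model is fit to a training half and evaluated by the held-out mean
#' squared error restricted to group 1 — the regime where sharing strength
#' from a similar group should pay off most at small group-1 sample sizes.
#'
#' @inheritParams run_prediction_benchmark
#' @param n1_grid Group-1 sample sizes to sweep.
#' @param n23 Sample size of groups 2 and 3.
#' @param d_similar,d_dissimilar Group distances encoding the similarity
#'   structure.
#' @return An `mggp_experiment` with tibble columns `n1`, `fit_model`,
#'   `replicate`, `mse_group1`; the config echoes the fixed `n2`, `n3`.
#' @export
run_imbalanced_groups <- function(n1_grid = c(5, 10, 30, 50), n23 = 50,
                                  fit_models = c("sgp", "ugp", "hgp", "mggp"),
                                  replicates = 20, sigma2 = 1, a = 1, b = 1,
                                  tau2 = 0.1, p = 1L, d_similar = 0.1,
                                  d_dissimilar = 1, split_fraction = 0.5,
                                  fit_mode = c("pinned", "mle"),
                                  centering = c("dataset", "training"),
                                  include_noise = TRUE, restarts = 1,
                                  mggp_family = "mg_rbf", seed = 1) {
  fit_mode <- match.arg(fit_mode)
  centering <- match.arg(centering)
  labels <- c("g1", "g2", "g3")
  dmat <- matrix(d_dissimilar, 3, 3, dimnames = list(labels, labels))
  dmat[1, 2] <- dmat[2, 1] <- d_similar
  diag(dmat) <- 0
  gs <- mggp_groups(labels, dmat)
  seeds <- replicate_seeds(seed, length(n1_grid) * replicates)
  rows <- list()
  ctr <- 0L
  for (n1 in n1_grid) {
    for (r in seq_len(replicates)) {
      ctr <- ctr + 1L
      d <- simulate_mggp(
        model = "mggp", n_per_group = c(n1, n23, n23),
        labels = labels, distances = dmat, p = p, sigma2 = sigma2,
        a = a, b = b, tau2 = tau2, seed = seeds[ctr]
      )
      if (centering == "dataset") {
        d$y <- d$y - stats::ave(d$y, d$group)
      }
      train_id <- split_by_group(d$group, split_fraction)
      train <- d[train_id, ]
      test <- d[!train_id & d$group == "g1", ]
      for (fm in fit_models) {
        fam <- model_family(fm, mggp_family)
        if (fit_mode == "mle") {
          f <- fit_mle(train, fam,
            groups = gs, restarts = restarts,
            seed = seeds[ctr]
          )
          kern <- f$kernel
          tau2_pred <- f$tau2
        } else {
          kern <- if (fm == "mggp") {
            mggp_kernel(fam, gs, p = p, sigma2 = sigma2, a = a, b = b)
          } else {
            baseline_kernel(fm, gs, p = p, sigma2 = sigma2, b = b)
          }
          tau2_pred <- tau2
        }
        pr <- predict_gp_mean(train, kern, test,
          include_noise = include_noise, tau2 = tau2_pred,
          center = centering == "training"
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          n1 = n1, fit_model = fm, replicate = r,
          mse_group1 = prediction_mse(test$y, pr$.pred)
        )
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summ <- results |>
    dplyr::group_by(.data$n1, .data$fit_model) |>
    dplyr::summarise(mean_mse = mean(.data$mse_group1), .groups = "drop")
  new_experiment(
    "imbalanced_groups", results,
    list(
      n1_grid = n1_grid, n2 = n23, n3 = n23, fit_models = fit_models,
      replicates = replicates, sigma2 = sigma2, a = a, b = b, tau2 = tau2,
      d_similar = d_similar, d_dissimilar = d_dissimilar,
      fit_mode = fit_mode, seed = seed
    ),
    summary = summ
  )
}

#' Bayesian recovery study: credible-interval coverage
#'
#' Simulates two-group datasets with group-specific intercepts and noise
#' variances, runs the fully Bayesian fit on each, and records posterior
#' 50/2.5/97.5 percentiles per parameter together with an indicator of
#' whether the central 95% interval covers the generating truth.
#'
#' @inheritParams run_model_comparison
#' @param beta Generating group intercepts (length 2).
#' @param tau2 Generating per-group noise variances (length 2).
#' @param priors An [mggp_priors()].
#' @param chains,warmup,iter MCMC settings per replicate.
#' @return An `mggp_experiment` with tibble columns `replicate`,
#'   `parameter`, `truth`, `q2.5`, `q50`, `q97.5`, `covered`, plus a
#'   per-parameter coverage summary.
#' @export
run_bayes_study <- function(replicates = 10, n_per_group = 100,
                            beta = c(1, 2), tau2 = c(0.1, 0.3),
                            sigma2 = 1, a = 1, b = 1, p = 1L,
                            priors = mggp_priors(), chains = 4,
                            warmup = 300, iter = 1000, seed = 1) {
  seeds <- replicate_seeds(seed, replicates)
  labels <- c("g1", "g2")
  truth <- c(
    a = a, b = b, sigma2 = sigma2,
    tau2_g1 = tau2[1], tau2_g2 = tau2[2],
    beta_g1 = beta[1], beta_g2 = beta[2]
  )
  rows <- list()
  for (r in seq_len(replicates)) {
    d <- simulate_mggp(
      model = "mggp", n_per_group = rep(n_per_group, 2),
      labels = labels, p = p, sigma2 = sigma2, a = a, b = b,
      tau2 = tau2, beta = beta, seed = seeds[r]
    )
    fit <- bayes_fit(d,
      priors = priors, chains = chains, warmup = warmup,
      iter = iter, seed = seeds[r]
    )
    td <- tidy.mggp_post(fit)
    td <- td[td$term %in% names(truth), ]
    tr <- unname(truth[td$term])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      replicate = r,
      parameter = td$term,
      truth = tr,
      q2.5 = td$conf.low, q50 = td$estimate, q97.5 = td$conf.high,
      covered = td$conf.low <= tr & tr <= td$conf.high,
      rhat_warning = fit$convergence_warning
    )
  }
  results <- dplyr::bind_rows(rows)
  summ <- results |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      coverage = mean(.data$covered),
      n_covered = sum(.data$covered),
      .groups = "drop"
    )
  new_experiment(
    "bayes_study", results,
    list(
      replicates = replicates, n_per_group = n_per_group, beta = beta,
      tau2 = tau2, sigma2 = sigma2, a = a, b = b, chains = chains,
      warmup = warmup, iter = iter, seed = seed
    ),
    summary = summ
  )
}
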