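#' Plot an experiment report
#'
#' Dispatches on the experiment type: likelihood-profile curves with 95%
#' normal-approximation confidence bands for the model comparison,
#' boxplots of \eqn{\hat a} for the recovery study, mean-squared-error
#' boxplots for the prediction benchmarks, and per-parameter interval
#' plots for the Bayesian coverage study.
#'
#' @param object An `mggp_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mggp_experiment <- function(object, ...) {
  res <- object$results
  switch(object$type,
    model_comparison = {
      mg <- res |>
        dplyr::filter(.data$fit_model == "mggp") |>
        dplyr::group_by(.data$gen_model, .data$a) |>
        dplyr::summarise(
          mean_ll = mean(.data$log_lik),
          se = stats::sd(.data$log_lik) / sqrt(dplyr::n()),
          .groups = "drop"
        )
      base <- res |>
        dplyr::filter(.data$fit_model != "mggp") |>
        dplyr::group_by(.data$gen_model, .data$fit_model) |>
        dplyr::summarise(mean_ll = mean(.data$log_lik), .groups = "drop")
      ggplot2::ggplot(mg, ggplot2::aes(x = .data$a, y = .data$mean_ll)) +
        ggplot2::geom_ribbon(
          ggplot2::aes(
            ymin = .data$mean_ll - 1.96 * .data$se,
            ymax = .data$mean_ll + 1.96 * .data$se
          ),
          alpha = 0.2
        ) +
        ggplot2::geom_line() +
        ggplot2::geom_hline(
          data = base,
          ggplot2::aes(yintercept = .data$mean_ll, colour = .data$fit_model),
          linetype = 2
        ) +
        ggplot2::scale_x_log10() +
        ggplot2::facet_wrap(~gen_model, scales = "free_y") +
        ggplot2::labs(
          x = "group-similarity scale a",
          y = "log marginal likelihood",
          colour = "baseline"
        )
    },
    mle_recovery = {
      ggplot2::ggplot(
        res,
        ggplot2::aes(x = factor(.data$true_a), y = .data$a_hat)
      ) +
        ggplot2::geom_boxplot() +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "true a", y = expression(hat(a)))
    },
    prediction_benchmark = {
      ggplot2::ggplot(
        res,
        ggplot2::aes(x = .data$fit_model, y = .data$mse)
      ) +
        ggplot2::geom_boxplot() +
        ggplot2::facet_wrap(~gen_model, scales = "free_y") +
        ggplot2::labs(x = "fitted model", y = "held-out MSE")
    },
    imbalanced_groups = {
      ggplot2::ggplot(
        res,
        ggplot2::aes(
          x = factor(.data$n1), y = .data$mse_group1,
          fill = .data$fit_model
        )
      ) +
        ggplot2::geom_boxplot() +
        ggplot2::labs(x = "group-1 sample size", y = "group-1 held-out MSE")
    },
    bayes_study = {
      ggplot2::ggplot(
        res,
        ggplot2::aes(x = factor(.data$replicate), y = .data$q50)
      ) +
        ggplot2::geom_pointrange(
          ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5)
        ) +
        ggplot2::geom_hline(
          ggplot2::aes(yintercept = .data$truth),
          linetype = 2, colour = "red"
        ) +
        ggplot2::facet_wrap(~parameter, scales = "free_y") +
        ggplot2::labs(x = "replicate", y = "posterior median and 95% CI")
    },
    stop("no plot method for experiment type ", object$type, call. = FALSE)
  )
}

#' Plot posterior marginal distributions
#'
#' @param object An `mggp_post`.
#' @param ... Unused.
#' @return A ggplot object of per-parameter marginal densities by chain.
#' @export
autoplot.mggp_post <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws, -c(".chain", ".iter"),
    names_to = "parameter", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$value, colour = factor(.data$.chain))
  ) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(colour = "chain", x = NULL, y = "posterior density")
}

#' Plot a likelihood profile over the group-similarity scale
#'
#' @param profile A tibble from [profile_loglik_a()].
#' @return A ggplot object.
#' @export
plot_profile_loglik <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$a, y = .data$log_lik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "group-similarity scale a", y = "log marginal likelihood")
}

#' Plot posterior predictive bands per group
#'
#' Summarizes predictive draws from [sample_latent_and_predict()] into a
#' mean curve with a band of twice the predictive standard deviation,
#' overlaid on the training points.
#'
#' @param pred_draws Tibble from [sample_latent_and_predict()].
#' @param newdata The prediction grid the draws were made at (must have a
#'   single feature column `x1`).
#' @param data Optional training data to overlay.
#' @return A ggplot object.
#' @export
plot_predictive_bands <- function(pred_draws, newdata, data = NULL) {
  nd <- newdata
  nd$.row <- seq_len(nrow(nd))
  summ <- pred_draws |>
    dplyr::group_by(.data$.row, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$y), sd = stats::sd(.data$y),
      .groups = "drop"
    ) |>
    dplyr::left_join(nd[, c(".row", "x1")], by = ".row")
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$x1, colour = .data$group)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean - 2 * .data$sd,
        ymax = .data$mean + 2 * .data$sd, fill = .data$group
      ),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linetype = 2) +
    ggplot2::labs(x = "x", y = "predictive response")
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data,
      ggplot2::aes(x = .data$x1, y = .data$y, colour = .data$group),
      inherit.aes = FALSE, size = 0.8
    )
  }
  p
}
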