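#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a maximum-likelihood fit
#'
#' @param x An `mggp_mle` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and `fixed` (whether
#'   the parameter was pinned during optimization).
#' @export
tidy.mggp_mle <- function(x, ...) {
  est <- unlist(x$estimates)
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    fixed = !(names(est) %in% x$free)
  )
  if (any(startsWith(x$free, "beta_")) || any(x$beta != 0)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("beta_", names(x$beta)),
      estimate = unname(x$beta),
      fixed = !(paste0("beta_", names(x$beta)) %in% x$free)
    ))
  }
  out
}

#' @rdname tidy.mggp_mle
#' @export
glance.mggp_mle <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik,
    converged = x$converged,
    n_restarts = x$n_restarts_used,
    family = x$family
  )
}

#' Tidy a posterior fit
#'
#' Posterior summaries in the 50 (2.5; 97.5) percentile convention.
#'
#' @param x An `mggp_post` object from [bayes_fit()].
#' @param probs Interval probabilities; default central 95%.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior median),
#'   `conf.low`, `conf.high`, `rhat`, `ess`.
#' @export
tidy.mggp_post <- function(x, probs = c(0.025, 0.975), ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".iter"))
  qs <- vapply(
    pars,
    function(p) {
      stats::quantile(x$draws[[p]], c(probs[1], 0.5, probs[2]))
    },
    numeric(3)
  )
  dg <- x$diagnostics
  tibble::tibble(
    term = pars,
    estimate = qs[2, ],
    conf.low = qs[1, ],
    conf.high = qs[3, ],
    rhat = dg$rhat[match(pars, dg$parameter)],
    ess = dg$ess[match(pars, dg$parameter)]
  )
}

#' @rdname tidy.mggp_post
#' @export
glance.mggp_post <- function(x, ...) {
  tibble::tibble(
    chains = x$chains,
    iter = x$iter,
    n_draws = nrow(x$draws),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    convergence_warning = x$convergence_warning
  )
}
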