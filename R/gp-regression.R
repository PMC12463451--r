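#' Grouped data for multi-group GP regression
#'
#' The package-wide tabular convention: a data frame with numeric feature
#' columns `x1, ..., xp` (a single column may be named `x` or `x1`), a
#' `group` column of labels and a numeric response `y`. These helpers
#' extract the pieces the linear algebra needs and build the block design
#' matrix of group-specific intercepts.
#'
#' @param data A data frame in the convention above.
#' @param groups Optional [mggp_groups()] fixing the label set and metric;
#'   defaults to the labels in order of first appearance with the discrete
#'   metric.
#' @return A list with `X` (n x p matrix), `group` (character), `y`
#'   (numeric or NULL), `gs` ([mggp_groups()]), `F` (n x k intercept design)
#'   and `n_j` (named per-group counts).
#' @keywords internal
#' @export
as_grouped_data <- function(data, groups = NULL) {
  stopifnot(is.data.frame(data), "group" %in% names(data))
  xn <- grep("^x[0-9]*$", names(data), value = TRUE)
  if (!length(xn)) stop("no feature columns x1..xp (or x) found", call. = FALSE)
  xn <- xn[order(nchar(xn), xn)]
  X <- as.matrix(data[xn])
  storage.mode(X) <- "double"
  grp <- as.character(data$group)
  if (is.null(groups)) {
    groups <- mggp_groups(unique(grp))
  } else if (!inherits(groups, "mggp_groups")) {
    groups <- mggp_groups(groups)
  }
  idx <- group_index(groups, grp)
  Fm <- matrix(0, nrow(X), groups$k,
    dimnames = list(NULL, groups$labels)
  )
  Fm[cbind(seq_along(idx), idx)] <- 1
  list(
    X = X,
    group = grp,
    y = if ("y" %in% names(data)) as.numeric(data$y) else NULL,
    gs = groups,
    F = Fm,
    n_j = stats::setNames(
      as.integer(tabulate(idx, groups$k)),
      groups$labels
    )
  )
}

#' Read / write grouped datasets as delimited text
#'
#' @param path File path.
#' @param delim Delimiter.
#' @return A tibble with columns `x1..xp`, `group`, `y`.
#' @export
read_grouped_data <- function(path, delim = ",") {
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE
  )
}

#' @rdname read_grouped_data
#' @param data A grouped data frame.
#' @export
write_grouped_data <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

# per-sample noise variances from a scalar or per-group (named or ordered)
# tau2 specification
tau2_for_samples <- function(tau2, gd) {
  k <- gd$gs$k
  if (length(tau2) == 1) {
    tau2v <- rep(tau2, k)
  } else if (length(tau2) == k) {
    tau2v <- if (!is.null(names(tau2))) {
      unname(tau2[gd$gs$labels])
    } else {
      as.numeric(tau2)
    }
  } else {
    stop("`tau2` must be a scalar or one value per group", call. = FALSE)
  }
  if (any(!is.finite(tau2v)) || any(tau2v <= 0)) {
    stop("noise variances must be positive", call. = FALSE)
  }
  tau2v[group_index(gd$gs, gd$group)]
}

chol_or_fail <- function(S) {
  tryCatch(chol(S), error = function(e) {
    ev <- min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    stop(
      "Cholesky factorization failed (minimum eigenvalue ", format(ev), ")",
      call. = FALSE
    )
  })
}

# log N(y | mu, S) via Cholesky
dmvnorm_chol <- function(y, mu, S) {
  L <- chol_or_fail(S)
  r <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * sum(r^2) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
}

#' Collapsed log marginal likelihood
#'
#' The log density \eqn{\log N(y \mid F\beta, K_\theta + D_\tau)} of the
#' responses after integrating out the latent process: `F` is the
#' block design of group-specific intercepts, \eqn{K_\theta} the kernel
#' matrix at the observed (input, group) points and \eqn{D_\tau} the
#' diagonal noise matrix with per-group variances. All solves use the
#' Cholesky factor of \eqn{K_\theta + D_\tau}.
#'
#' @param data Grouped data frame (`x1..xp`, `group`, `y`).
#' @param kernel An [mggp_kernel()]; its group space fixes the label set.
#' @param tau2 Noise variance: scalar (shared) or one value per group
#'   (named by label or in label order).
#' @param beta Group intercepts, length `k`; defaults to all zero.
#' @param jitter Diagonal jitter passed to [kernel_matrix()]; defaults to 0
#'   here because `tau2 > 0` already regularizes the matrix.
#' @return The log marginal likelihood (scalar).
#' @export
log_marginal_likelihood <- function(data, kernel, tau2, beta = NULL,
                                    jitter = 0) {
  gd <- as_grouped_data(data, kernel$groups)
  if (is.null(gd$y)) stop("`data` must contain a response column `y`", call. = FALSE)
  if (is.null(beta)) beta <- rep(0, gd$gs$k)
  stopifnot(length(beta) == gd$gs$k)
  K <- kernel_matrix(kernel, gd$X, gd$group, jitter = jitter)
  S <- K + diag(tau2_for_samples(tau2, gd), nrow(K))
  dmvnorm_chol(gd$y, as.vector(gd$F %*% beta), S)
}

#' Posterior of the latent process at the observed points
#'
#' Conditional law of the latent vector `Z` given data and parameters. With
#' residual \eqn{m = y - F\beta} and noise matrix \eqn{D_\tau}, the
#' posterior is Gaussian with covariance \eqn{M = (K_\theta^{-1} +
#' D_\tau^{-1})^{-1}} and mean \eqn{M D_\tau^{-1} m}. Both are computed in
#' the equivalent stable forms \eqn{M = K - K (K + D_\tau)^{-1} K} and
#' \eqn{\mathrm{mean} = K (K + D_\tau)^{-1} m}, avoiding any inverse of
#' \eqn{K_\theta} itself.
#'
#' @inheritParams log_marginal_likelihood
#' @return A list with `mean` (n-vector) and `cov` (n x n matrix).
#' @export
latent_posterior <- function(data, kernel, tau2, beta = NULL, jitter = 0) {
  gd <- as_grouped_data(data, kernel$groups)
  if (is.null(gd$y)) stop("`data` must contain a response column `y`", call. = FALSE)
  if (is.null(beta)) beta <- rep(0, gd$gs$k)
  K <- kernel_matrix(kernel, gd$X, gd$group, jitter = jitter)
  m <- gd$y - as.vector(gd$F %*% beta)
  S <- K + diag(tau2_for_samples(tau2, gd), nrow(K))
  L <- chol_or_fail(S)
  # A = (K + D)^{-1} K via two triangular solves
  A <- backsolve(L, backsolve(L, K, transpose = TRUE))
  M <- K - K %*% A
  M <- (M + t(M)) / 2
  attr(M, "jitter") <- NULL
  list(
    mean = as.vector(K %*% backsolve(L, backsolve(L, m, transpose = TRUE))),
    cov = M
  )
}

#' Noise-free conditional of the latent process at new points
#'
#' Given latent values `Z` at the training points, the latent process at a
#' new (input, group) point is Gaussian with mean
#' \eqn{k_0^\top K_\theta^{-1} Z} and variance
#' \eqn{K\{(x_0,c_0),(x_0,c_0)\} - k_0^\top K_\theta^{-1} k_0}, where
#' \eqn{k_0} collects the cross-covariances to the training points.
#'
#' @param data Training grouped data frame (features and groups; `y` not
#'   required).
#' @param kernel An [mggp_kernel()].
#' @param z Latent values at the training points (n-vector).
#' @param newdata Data frame of new points (`x1..xp`, `group`).
#' @param jitter Diagonal jitter for the training kernel matrix.
#' @return A tibble with columns `.mean` and `.var`, one row per new point.
#' @export
predict_latent <- function(data, kernel, z, newdata, jitter = NULL) {
  gd <- as_grouped_data(data, kernel$groups)
  nd <- as_grouped_data(newdata, kernel$groups)
  stopifnot(length(z) == nrow(gd$X))
  K <- kernel_matrix(kernel, gd$X, gd$group, jitter = jitter)
  Kx <- kernel_matrix(kernel, nd$X, nd$group, X2 = gd$X, groups2 = gd$group)
  L <- chol_or_fail(K)
  alpha <- backsolve(L, backsolve(L, z, transpose = TRUE))
  V <- backsolve(L, t(Kx), transpose = TRUE) # L^{-T} t(Kx); var = k00 - colSums(V^2)
  k00 <- kernel_value(kernel, nd$X, nd$group, nd$X, nd$group)
  tibble::tibble(
    .mean = as.vector(Kx %*% alpha),
    .var = pmax(k00 - colSums(V^2), 0)
  )
}

#' GP point predictions by the noise-free conditional mean
#'
#' Point prediction \eqn{\mu^\star = K_{X^\star X} K_{XX}^{-1} y} for
#' held-out samples, after centering the responses of each group around
#' the training-set group mean (test responses in a group unseen during
#' training are centered at 0, so their prediction reverts to the group
#' mean). Set `include_noise = TRUE` to add the noise variance `tau2` to
#' the diagonal of \eqn{K_{XX}}, i.e. to condition on noisy observations
#' rather than interpolate them.
#'
#' @param data Training grouped data frame with response `y`.
#' @param kernel An [mggp_kernel()].
#' @param newdata Data frame of prediction points (`x1..xp`, `group`).
#' @param include_noise Add `tau2` to the training covariance diagonal?
#'   Defaults to `FALSE` (pure interpolation of the training responses).
#' @param tau2 Noise variance(s), required when `include_noise = TRUE`.
#' @param center Center responses per group before conditioning (default
#'   `TRUE`).
#' @param jitter Diagonal jitter for the training kernel matrix.
#' @return A tibble with `.pred` (original response scale) and
#'   `.pred_centered` (the conditional mean on the group-centered scale).
#' @export
predict_gp_mean <- function(data, kernel, newdata, include_noise = FALSE,
                            tau2 = NULL, center = TRUE, jitter = NULL) {
  gd <- as_grouped_data(data, kernel$groups)
  nd <- as_grouped_data(newdata, kernel$groups)
  if (is.null(gd$y)) stop("training data must contain `y`", call. = FALSE)
  centers <- stats::setNames(rep(0, gd$gs$k), gd$gs$labels)
  if (center) {
    means <- tapply(gd$y, gd$group, mean)
    centers[names(means)] <- means
  }
  yc <- gd$y - centers[gd$group]
  K <- kernel_matrix(kernel, gd$X, gd$group, jitter = jitter)
  if (include_noise) {
    if (is.null(tau2)) stop("`tau2` is required when include_noise = TRUE", call. = FALSE)
    K <- K + diag(tau2_for_samples(tau2, gd), nrow(K))
  }
  Kx <- kernel_matrix(kernel, nd$X, nd$group, X2 = gd$X, groups2 = gd$group)
  L <- chol_or_fail(K)
  mu <- as.vector(Kx %*% backsolve(L, backsolve(L, yc, transpose = TRUE)))
  tibble::tibble(
    .pred = mu + unname(centers[nd$group]),
    .pred_centered = mu
  )
}

#' Mean squared prediction error
#'
#' \eqn{E = n^{\star-1} \sum_i (y_i - \mu_i^\star)^2} over held-out samples.
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return The mean squared error.
#' @export
prediction_mse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  mean((y_true - y_pred)^2)
}
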