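#' Simulate grouped data from a multi-group Gaussian process
#'
#' Draws a dataset from the generative model
#' \deqn{y(x; c_j) = \beta_j + Z(x; c_j) + \epsilon, \qquad
#'   \epsilon \sim N(0, \tau_j^2),}
#' where `Z` is a zero-mean GP over \eqn{R^p \times \mathcal{C}} with the
#' requested covariance family. The latent vector is drawn jointly over all
#' points from its exact finite-dimensional Gaussian law (Cholesky of the
#' assembled kernel matrix), so cross-group dependence is faithfully
#' represented. Inputs are sampled uniformly on per-group intervals
#' (default `[-5, 5]` for every group; per-group offsets create the
#' disjoint-support designs used in the partially-observed-coordinates
#' setting).
#'
#' @param model Generating covariance family: `"mggp"` (multi-group RBF or
#'   the family in `family`), `"sgp"`, `"ugp"`, `"hgp"`, or `"separable"`.
#' @param n_per_group Integer vector of per-group sample sizes (recycled to
#'   `k` if scalar).
#' @param labels Group labels; default `g1..gk` with `k =
#'   length(n_per_group)`.
#' @param p Input dimension.
#' @param sigma2,a,b,c,nu Kernel parameters of the generating process (see
#'   [mggp_kernel()]); `a` is used only by the multi-group families.
#' @param family Multi-group family used when `model = "mggp"`.
#' @param tau2 Noise variance, scalar or per group.
#' @param beta Per-group intercepts; default all zero.
#' @param distances Optional group distance matrix (encodes which groups are
#'   similar); default discrete metric.
#' @param x_range Length-2 numeric range for input sampling, or a list of
#'   per-group ranges.
#' @param group_cov Group covariance matrix for `model = "separable"`.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A tibble with columns `x1..xp`, `group`, `y` and `z_true` (the
#'   latent draw), with the generating [mggp_kernel()] in attribute
#'   `"kernel"` and the noise/intercept truth in attribute `"truth"`.
#' @examples
#' d <- simulate_mggp(n_per_group = c(10, 10), a = 1, seed = 1)
#' head(d)
#' @export
simulate_mggp <- function(model = c("mggp", "sgp", "ugp", "hgp", "separable"),
                          n_per_group = c(100, 100), labels = NULL, p = 1L,
                          sigma2 = 1, a = 1, b = 1, c = 1, nu = 1.5,
                          family = "mg_rbf", tau2 = 0.1, beta = NULL,
                          distances = NULL, x_range = c(-5, 5),
                          group_cov = NULL, seed = NULL) {
  model <- match.arg(model)
  k <- max(length(n_per_group), length(labels))
  n_per_group <- rep_len(as.integer(n_per_group), k)
  stopifnot(all(n_per_group >= 1))
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  gs <- mggp_groups(labels, distances)
  if (is.null(beta)) beta <- rep(0, k)
  stopifnot(length(beta) == k)
  kern <- switch(model,
    mggp = mggp_kernel(family, gs,
      p = p, sigma2 = sigma2, a = a, b = b,
      c = c, nu = nu
    ),
    separable = mggp_kernel("separable", gs,
      p = p, sigma2 = sigma2, b = b,
      group_cov = group_cov
    ),
    baseline_kernel(model, gs, p = p, sigma2 = sigma2, b = b)
  )
  if (!is.null(seed)) set.seed(seed)
  ranges <- if (is.list(x_range)) {
    stopifnot(length(x_range) == k)
    x_range
  } else {
    rep(list(x_range), k)
  }
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(
      stats::runif(n_per_group[j] * p, ranges[[j]][1], ranges[[j]][2]),
      ncol = p
    )
  }))
  grp <- rep(labels, n_per_group)
  K <- kernel_matrix(kern, X, grp)
  z <- as.vector(t(chol(K)) %*% stats::rnorm(nrow(X)))
  tau2v <- if (length(tau2) == 1) rep(tau2, k) else rep_len(tau2, k)
  noise_sd <- sqrt(tau2v[match(grp, labels)])
  y <- beta[match(grp, labels)] + z + stats::rnorm(length(z), sd = noise_sd)
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(X),
    paste0("x", seq_len(p))
  ))
  out$group <- grp
  out$y <- y
  out$z_true <- z
  attr(out, "kernel") <- kern
  attr(out, "truth") <- list(
    model = model, sigma2 = sigma2, a = a, b = b, c = c, nu = nu,
    tau2 = tau2v, beta = beta
  )
  out
}

# stratified train/test split by group; returns logical train indicator
split_by_group <- function(group, fraction = 0.5) {
  train <- logical(length(group))
  for (g in unique(group)) {
    idx <- which(group == g)
    n_tr <- max(1L, floor(length(idx) * fraction))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}
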