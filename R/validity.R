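#' Frequency grid for spectral validity checks
#'
#' Regular grid of frequencies covering the effective support of the
#' Gaussian spectral densities of the multi-group RBF family. With feature
#' scale `b`, the densities are proportional to
#' \eqn{\exp(-\pi^2 \|\omega\|^2 / b^2)}, so the default span of `5 * b`
#' per axis captures essentially all mass.
#'
#' @param p Frequency dimension (1 or 2; higher dimensions make dense grids
#'   impractical and are rejected).
#' @param b Feature scale setting the span.
#' @param n Points per axis.
#' @param span Half-width of the grid in units of `b`.
#' @return A matrix with `p` columns, one frequency per row.
#' @export
spectral_grid <- function(p = 1L, b = 1, n = 201L, span = 5) {
  stopifnot(p >= 1, b > 0, n >= 3)
  if (p > 2) {
    stop("dense frequency grids are only supported for p <= 2", call. = FALSE)
  }
  ax <- seq(-span * b, span * b, length.out = n)
  if (p == 1) matrix(ax, ncol = 1) else as.matrix(expand.grid(ax, ax))
}

#' Spectral densities of the multi-group RBF kernel
#'
#' For the multi-group squared-exponential kernel on \eqn{R^p \times
#' \{c_1, c_2\}} with the discrete group metric, the within-group slice
#' \eqn{K_w(r) = \sigma^2 \exp(-b^2 r^2)} and the cross-group slice
#' \eqn{K_c(r) = \sigma^2 (a^2+1)^{-p/2} \exp\{-b^2 r^2/(a^2+1)\}} have
#' closed-form Fourier transforms
#' \deqn{\rho_w(\omega) = \sigma^2 (\pi/b^2)^{p/2}
#'   \exp(-\pi^2 \|\omega\|^2 / b^2), \qquad
#'   \rho_c(\omega) = \sigma^2 (\pi/b^2)^{p/2}
#'   \exp\{-\pi^2 (a^2+1) \|\omega\|^2 / b^2\}.}
#' Dominance \eqn{\rho_w \ge \rho_c} everywhere — which holds for every
#' \eqn{a \ge 0} — certifies positive definiteness of the two-group
#' stationary process.
#'
#' @param sigma2,a,b Kernel parameters (`b > 0` required).
#' @param p Input dimension.
#' @param omegas Optional frequency matrix (rows are frequencies); defaults
#'   to [spectral_grid()].
#' @return A tibble with the frequency coordinates `omega1..omegap` and
#'   columns `rho_w`, `rho_c`.
#' @export
rbf_spectral_densities <- function(sigma2 = 1, a = 1, b = 1, p = 1L,
                                   omegas = NULL) {
  if (b <= 0) stop("b must be positive: the spectral density is degenerate at b = 0", call. = FALSE)
  stopifnot(sigma2 > 0, a >= 0)
  if (is.null(omegas)) omegas <- spectral_grid(p = p, b = b)
  omegas <- if (is.matrix(omegas)) omegas else matrix(omegas, ncol = 1)
  stopifnot(ncol(omegas) == p)
  w2 <- rowSums(omegas^2)
  pref <- sigma2 * (pi / b^2)^(p / 2)
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(omegas),
    paste0("omega", seq_len(p))
  ))
  out$rho_w <- pref * exp(-pi^2 * w2 / b^2)
  out$rho_c <- pref * exp(-pi^2 * (a^2 + 1) * w2 / b^2)
  out
}

spectral_tol <- function(..., tol = 1e-10) {
  tol * max(1e-300, ..., na.rm = TRUE)
}

#' Two-group stationary validity certificate
#'
#' A stationary process on \eqn{R^p \times \{c_1, c_2\}} defined by a
#' within-group spectral density \eqn{\rho_w} and a cross-group density
#' \eqn{\rho_c} is positive definite if and only if
#' \eqn{\rho_w(\omega) \ge \rho_c(\omega)} at every frequency. The check is
#' performed on the supplied grid with a small relative tolerance, since a
#' strict pointwise inequality is unverifiable in floating point.
#'
#' @param grid A data frame with columns `rho_w` and `rho_c` (e.g. from
#'   [rbf_spectral_densities()]).
#' @param tol Relative tolerance (scaled by the maximum density value).
#' @return `TRUE` if dominance holds on the whole grid.
#' @export
check_two_group_stationary <- function(grid, tol = 1e-10) {
  stopifnot(all(c("rho_w", "rho_c") %in% names(grid)))
  eps <- spectral_tol(grid$rho_w, grid$rho_c, tol = tol)
  all(grid$rho_w >= grid$rho_c - eps)
}

#' Semi-stationary (two-group, heterogeneous) validity certificate
#'
#' With group-specific within-group densities \eqn{\rho_0, \rho_1} and
#' cross density \eqn{\rho_c}, the process is positive definite if and only
#' if \eqn{\rho_0(\omega)\rho_1(\omega) \ge \rho_c(\omega)^2} at every
#' frequency.
#'
#' @param grid A data frame with columns `rho_0`, `rho_1`, `rho_c`.
#' @param tol Relative tolerance (applied to the products).
#' @return `TRUE` if the determinant condition holds on the whole grid.
#' @export
check_semistationary <- function(grid, tol = 1e-10) {
  stopifnot(all(c("rho_0", "rho_1", "rho_c") %in% names(grid)))
  lhs <- grid$rho_0 * grid$rho_1
  rhs <- grid$rho_c^2
  eps <- spectral_tol(lhs, rhs, tol = tol)
  all(lhs >= rhs - eps)
}

#' k-group spectral validity certificate
#'
#' A semi-stationary process on \eqn{R^p \times \mathcal{C}} with pairwise
#' spectral densities \eqn{\rho_{ij}(\omega)} is positive definite if and
#' only if the \eqn{k \times k} matrix \eqn{\rho(\omega)} is positive
#' semi-definite at every frequency; this is the matrix analogue of the
#' two-group dominance condition and is checked by eigendecomposition.
#'
#' @param rho_matrices A list of symmetric `k x k` matrices, or a 3-d array
#'   with the frequency index last.
#' @param tol Relative eigenvalue tolerance (scaled by the largest density).
#' @return `TRUE` if every matrix is PSD within tolerance.
#' @export
check_k_group <- function(rho_matrices, tol = 1e-10) {
  if (is.array(rho_matrices) && length(dim(rho_matrices)) == 3) {
    rho_matrices <- lapply(
      seq_len(dim(rho_matrices)[3]),
      function(i) rho_matrices[, , i]
    )
  }
  mx <- max(vapply(rho_matrices, function(m) max(abs(m)), 0), 1e-300)
  all(vapply(rho_matrices, function(m) {
    min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values) >=
      -tol * mx
  }, logical(1)))
}

#' Eigenvalue certificate for an assembled covariance matrix
#'
#' Direct numerical check that a matrix is positive semi-definite up to a
#' relative tolerance — the general-purpose oracle used for kernels without
#' closed-form spectral densities.
#'
#' @param K Symmetric matrix.
#' @param tol Relative tolerance (scaled by the largest diagonal entry).
#' @return `TRUE` if the minimum eigenvalue is above `-tol * max(diag(K))`.
#' @export
is_psd_matrix <- function(K, tol = 1e-8) {
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(diag(K), 1e-300)
}
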