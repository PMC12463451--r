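#' Multi-group covariance functions
#'
#' Constructs a covariance function on \eqn{R^p \times \mathcal{C}}, the
#' product of a `p`-dimensional input space and a finite set of groups.
#' The multi-group families (`"mg_rbf"`, `"mg_matern"`, `"mg_exponential"`,
#' `"gneiting"`) are nonseparable Gneiting-class constructions
#' \deqn{K\{(x, c_i), (x', c_j)\} =
#'   \frac{\sigma^2}{\psi(d_{ij}^2)^{p/2}}
#'   \, \varphi\!\left(\frac{\|x - x'\|^2}{\psi(d_{ij}^2)}\right),}
#' where \eqn{d_{ij}} is the distance between groups \eqn{c_i} and
#' \eqn{c_j}, \eqn{\varphi} is completely monotone and \eqn{\psi} is positive
#' with a completely monotone derivative. Validity requires the group Gram
#' matrix of [mggp_groups()] to be positive semi-definite.
#'
#' The named families are:
#' \describe{
#'   \item{`mg_rbf`}{\eqn{\sigma^2 (a^2 d_{ij}^2 + 1)^{-p/2}
#'     \exp\{-b^2 \|x-x'\|^2 / (a^2 d_{ij}^2 + 1)\}} — the multi-group
#'     squared-exponential. `a` is the group-similarity scale: `a = 0`
#'     ignores groups (union GP limit), large `a` decouples groups
#'     (separate-GP limit).}
#'   \item{`mg_matern`}{the multi-group Matern: with \eqn{u = a^2 d_{ij}^2 + 1},
#'     \eqn{v = a^2 d_{ij}^2 + c} and \eqn{z = b \sqrt{u/v}\, \|x - x'\|},
#'     \eqn{\sigma^2 c^{p/2} u^{-\nu} v^{-p/2} M_\nu(z)} where
#'     \eqn{M_\nu(z) = 2^{1-\nu} \Gamma(\nu)^{-1} z^\nu K_\nu(z)} is the
#'     normalized Matern correlation (\eqn{M_\nu(0) = 1}). It reduces to the
#'     multi-group exponential at \eqn{\nu = 1/2}, factorizes into a
#'     (space) x (group) product at \eqn{c = 1}, and is the standard Matern
#'     within a group (\eqn{d_{ij} = 0}).}
#'   \item{`mg_exponential`}{the \eqn{\nu = 1/2} special case in closed form.}
#'   \item{`gneiting`}{the generic construction with \eqn{\varphi, \psi}
#'     chosen via [monotone_pair()].}
#'   \item{`separable`}{\eqn{K_{R^p}(x, x') \, C_{ij}} with an RBF spatial
#'     factor and a group covariance matrix `C` (see
#'     [homogeneous_group_cov()]).}
#'   \item{`sgp`}{separate GPs: RBF within a group, zero across groups.}
#'   \item{`ugp`}{union GP: one RBF ignoring group labels.}
#'   \item{`hgp`}{hierarchical GP: \eqn{K_0(x,x') + 1\{c_i = c_j\} K_1(x,x')}
#'     with RBF components `k0`, `k1`.}
#' }
#'
#' @param family Kernel family; see Details.
#' @param groups An [mggp_groups()] object (or a character vector of labels,
#'   which implies the discrete metric).
#' @param p Input dimension.
#' @param sigma2 Spatial variance \eqn{\sigma^2 > 0}.
#' @param a Group similarity scale \eqn{a \ge 0} (Gneiting families).
#' @param b Feature (inverse length) scale \eqn{b \ge 0}.
#' @param c Separability scale \eqn{c > 0} (Matern/exponential families).
#' @param nu Matern smoothness \eqn{\nu > 0}; fixed, not optimized, by
#'   default.
#' @param fns A [monotone_pair()] for `family = "gneiting"`.
#' @param group_cov A `k x k` group covariance matrix (or the result of
#'   [homogeneous_group_cov()]) for `family = "separable"`.
#' @param k0,k1 Lists `list(sigma2=, b=)` for the two RBF components of the
#'   hierarchical GP; default splits `sigma2` equally.
#'
#' @return An object of class `mggp_kernel`.
#' @examples
#' gs <- mggp_groups(c("A", "B"))
#' k <- mggp_kernel("mg_rbf", gs, p = 1, sigma2 = 1, a = 1, b = 1)
#' kernel_value(k, 0, "A", 0, "B") # 1/sqrt(2): cross-group damping at a = 1
#' @export
mggp_kernel <- function(family = c(
                          "mg_rbf", "mg_matern", "mg_exponential",
                          "gneiting", "separable", "hgp", "sgp", "ugp"
                        ),
                        groups, p = 1L, sigma2 = 1, a = 1, b = 1, c = 1,
                        nu = 1.5, fns = NULL, group_cov = NULL,
                        k0 = NULL, k1 = NULL) {
  family <- match.arg(family)
  if (!inherits(groups, "mggp_groups")) groups <- mggp_groups(groups)
  stopifnot(sigma2 > 0, a >= 0, b >= 0, p >= 1)
  if (family %in% c("mg_matern", "mg_exponential")) {
    stopifnot(c > 0)
    if (family == "mg_matern") stopifnot(nu > 0)
  }
  if (family == "gneiting") {
    if (is.null(fns) || !inherits(fns, "mggp_monotone_pair")) {
      stop("`family = \"gneiting\"` requires `fns = monotone_pair(...)`",
        call. = FALSE
      )
    }
  }
  if (family == "separable") {
    if (is.null(group_cov)) group_cov <- homogeneous_group_cov(groups$k, 0.5)
    if (is.list(group_cov)) {
      if (isFALSE(group_cov$valid)) {
        stop("supplied homogeneous group covariance is not positive ",
          "semi-definite (b outside [-1/(k-1), 1])",
          call. = FALSE
        )
      }
      group_cov <- group_cov$C
    }
    group_cov <- as.matrix(group_cov)
    stopifnot(nrow(group_cov) == groups$k, ncol(group_cov) == groups$k)
    ev <- eigen(group_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(diag(group_cov))) {
      stop("group covariance matrix C is not positive semi-definite",
        call. = FALSE
      )
    }
  }
  if (family == "hgp") {
    # default: both components are the same RBF (shared sigma2 and b), so
    # the within-group covariance is 2 sigma2 and the cross-group is sigma2
    if (is.null(k0)) k0 <- list(sigma2 = sigma2, b = b)
    if (is.null(k1)) k1 <- list(sigma2 = sigma2, b = b)
  }
  structure(
    list(
      family = family, groups = groups, p = as.integer(p),
      sigma2 = sigma2, a = a, b = b, c = c, nu = nu,
      fns = fns, group_cov = group_cov, k0 = k0, k1 = k1
    ),
    class = "mggp_kernel"
  )
}

#' @export
print.mggp_kernel <- function(x, ...) {
  cat("<mggp_kernel> family=", x$family, ", p=", x$p,
    ", k=", x$groups$k, "\n",
    sep = ""
  )
  pars <- switch(x$family,
    mg_rbf = c("sigma2", "a", "b"),
    mg_matern = c("sigma2", "a", "b", "c", "nu"),
    mg_exponential = c("sigma2", "a", "b", "c"),
    gneiting = "sigma2",
    c("sigma2", "b")
  )
  cat("  ", paste(sprintf("%s=%.4g", pars, unlist(x[pars])), collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Completely monotone / Bernstein function pairs for the Gneiting class
#'
#' Menu of scalar functions entering the generic multi-group construction:
#' completely monotone candidates \eqn{\varphi} and positive functions
#' \eqn{\psi} with completely monotone derivative.
#'
#' Available `phi` families (hyperparameters in `phi_pars`):
#' \describe{
#'   \item{`powexp`}{\eqn{\exp(-c t^{\gamma})}, `c > 0`, `0 < gamma <= 1`.}
#'   \item{`matern`}{\eqn{2^{1-\nu}\Gamma(\nu)^{-1} (c t^{1/2})^{\nu}
#'     K_\nu(c t^{1/2})}, `c, nu > 0`.}
#'   \item{`cauchy`}{\eqn{(1 + c t^{\gamma})^{-\nu}}.}
#'   \item{`hyperbolic`}{\eqn{2^{\nu} \{\exp(c t^{1/2}) + \exp(-c t^{1/2})\}^{-\nu}}.}
#' }
#' Available `psi` families (hyperparameters in `psi_pars`):
#' \describe{
#'   \item{`power`}{\eqn{(a t^{\alpha} + 1)^{\beta}}, `a > 0`,
#'     `0 < alpha, beta <= 1`.}
#'   \item{`log`}{\eqn{\log(a t^{\alpha} + b)/\log(b)}, `b > 1`.}
#'   \item{`ratio`}{\eqn{(a t^{\alpha} + \beta) / \{\beta (a t^{\alpha} + 1)\}},
#'     `0 < beta <= 1`.}
#' }
#'
#' @param phi,psi Family names.
#' @param phi_pars,psi_pars Named lists of hyperparameters; unset entries
#'   take the defaults `c = 1, gamma = 1, nu = 1` and
#'   `a = 1, alpha = 1, beta = 1, b = 2`.
#' @return An object of class `mggp_monotone_pair` with callable elements
#'   `phi(t)` and `psi(t)`.
#' @examples
#' fns <- monotone_pair("powexp", "power")
#' fns$phi(0) # 1
#' fns$psi(0) # 1
#' @export
monotone_pair <- function(phi = c("powexp", "matern", "cauchy", "hyperbolic"),
                          psi = c("power", "log", "ratio"),
                          phi_pars = list(), psi_pars = list()) {
  phi <- match.arg(phi)
  psi <- match.arg(psi)
  pp <- utils::modifyList(list(c = 1, gamma = 1, nu = 1), phi_pars)
  sp <- utils::modifyList(list(a = 1, alpha = 1, beta = 1, b = 2), psi_pars)
  stopifnot(pp$c > 0, pp$gamma > 0, pp$gamma <= 1, pp$nu > 0)
  stopifnot(sp$a > 0, sp$alpha > 0, sp$alpha <= 1, sp$beta > 0, sp$beta <= 1)
  if (psi == "log") stopifnot(sp$b > 1)
  phi_fun <- switch(phi,
    powexp = function(t) exp(-pp$c * t^pp$gamma),
    matern = function(t) matern_norm(pp$c * sqrt(t), pp$nu),
    cauchy = function(t) (1 + pp$c * t^pp$gamma)^(-pp$nu),
    hyperbolic = function(t) {
      s <- pp$c * sqrt(t)
      2^pp$nu * (exp(s) + exp(-s))^(-pp$nu)
    }
  )
  psi_fun <- switch(psi,
    power = function(t) (sp$a * t^sp$alpha + 1)^sp$beta,
    log = function(t) log(sp$a * t^sp$alpha + sp$b) / log(sp$b),
    ratio = function(t) (sp$a * t^sp$alpha + sp$beta) /
      (sp$beta * (sp$a * t^sp$alpha + 1))
  )
  structure(
    list(
      phi = phi_fun, psi = psi_fun,
      phi_family = phi, psi_family = psi,
      phi_pars = pp, psi_pars = sp
    ),
    class = "mggp_monotone_pair"
  )
}

# normalized Matern correlation M_nu(z) = 2^(1-nu)/Gamma(nu) z^nu K_nu(z),
# with the z -> 0 limit 1; Bessel overflow for large z is routed to 0.
matern_norm <- function(z, nu) {
  out <- numeric(length(z))
  small <- z < 1e-12
  out[small] <- 1
  zz <- z[!small]
  if (length(zz)) {
    # besselK underflows to 0 for large z; the product limit is 0 there
    v <- 2^(1 - nu) / gamma(nu) * zz^nu * besselK(zz, nu)
    v[!is.finite(v) & zz > 1] <- 0
    if (any(!is.finite(v))) {
      bad <- zz[!is.finite(v)][1]
      stop(
        "non-finite Matern evaluation at nu = ", nu, ", argument = ", bad,
        call. = FALSE
      )
    }
    out[!small] <- v
  }
  out
}

# squared Euclidean cross-distances between rows of X1 and X2
pdist2 <- function(X1, X2) {
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  s1 <- rowSums(X1^2)
  s2 <- rowSums(X2^2)
  d2 <- outer(s1, s2, "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  d2
}

# elementwise kernel evaluation given squared spatial distances R2 and
# group index matrices I, J (same shape)
kernel_eval <- function(kernel, R2, I, J) {
  fam <- kernel$family
  p <- kernel$p
  s2 <- kernel$sigma2
  if (fam %in% c("mg_rbf", "mg_matern", "mg_exponential", "gneiting")) {
    D <- kernel$groups$d[cbind(as.vector(I), as.vector(J))]
    D <- array(D, dim = dim(R2))
  }
  switch(fam,
    mg_rbf = {
      u <- kernel$a^2 * D^2 + 1
      s2 / u^(p / 2) * exp(-kernel$b^2 * R2 / u)
    },
    mg_matern = {
      u <- kernel$a^2 * D^2 + 1
      v <- kernel$a^2 * D^2 + kernel$c
      z <- kernel$b * sqrt(u / v) * sqrt(R2)
      s2 * kernel$c^(p / 2) * u^(-kernel$nu) * v^(-p / 2) *
        array(matern_norm(as.vector(z), kernel$nu), dim = dim(R2))
    },
    mg_exponential = {
      u <- kernel$a^2 * D^2 + 1
      v <- kernel$a^2 * D^2 + kernel$c
      s2 * kernel$c^(p / 2) / (sqrt(u) * v^(p / 2)) *
        exp(-kernel$b * sqrt(u / v) * sqrt(R2))
    },
    gneiting = {
      ps <- kernel$fns$psi(D^2)
      if (any(ps <= 0)) {
        stop("psi evaluated to a non-positive value; not a valid Gneiting pair",
          call. = FALSE
        )
      }
      s2 / ps^(p / 2) * kernel$fns$phi(R2 / ps)
    },
    separable = {
      Cg <- kernel$group_cov[cbind(as.vector(I), as.vector(J))]
      s2 * exp(-kernel$b^2 * R2) * array(Cg, dim = dim(R2))
    },
    sgp = {
      same <- (I == J)
      s2 * exp(-kernel$b^2 * R2) * same
    },
    ugp = s2 * exp(-kernel$b^2 * R2),
    hgp = {
      same <- (I == J)
      kernel$k0$sigma2 * exp(-kernel$k0$b^2 * R2) +
        same * kernel$k1$sigma2 * exp(-kernel$k1$b^2 * R2)
    }
  )
}

#' Evaluate a multi-group kernel at pairs of points
#'
#' @param kernel An [mggp_kernel()].
#' @param x1,x2 Numeric vectors (single points of length `p`) or matrices
#'   with `p` columns (one point per row; recycled against each other).
#' @param group1,group2 Group labels for the points.
#' @return Numeric vector of covariances.
#' @export
kernel_value <- function(kernel, x1, group1, x2, group2) {
  x1 <- if (is.matrix(x1)) x1 else matrix(x1, ncol = kernel$p)
  x2 <- if (is.matrix(x2)) x2 else matrix(x2, ncol = kernel$p)
  n <- max(nrow(x1), nrow(x2), length(group1), length(group2))
  xi <- x1[rep_len(seq_len(nrow(x1)), n), , drop = FALSE]
  xj <- x2[rep_len(seq_len(nrow(x2)), n), , drop = FALSE]
  gi <- group_index(kernel$groups, rep_len(group1, n))
  gj <- group_index(kernel$groups, rep_len(group2, n))
  R2 <- matrix(rowSums((xi - xj)^2), ncol = 1)
  as.vector(kernel_eval(
    kernel, R2, matrix(gi, ncol = 1),
    matrix(gj, ncol = 1)
  ))
}

#' Assemble a covariance matrix over (input, group) points
#'
#' Builds the `n x n` covariance matrix of the latent multi-group process at
#' the supplied points, adds `jitter` to the diagonal, and (for the symmetric
#' case) verifies Cholesky factorizability, escalating the jitter by factors
#' of 10 up to `1e-4 * sigma2` before failing with the minimum eigenvalue.
#'
#' @param kernel An [mggp_kernel()].
#' @param X Numeric matrix (`n x p`) or vector (`p = 1`) of inputs.
#' @param groups Group labels, length `n`.
#' @param X2,groups2 Optional second point set; if supplied the
#'   (rectangular) cross-covariance matrix is returned and no jitter is
#'   added.
#' @param jitter Initial diagonal jitter; default `1e-8 * sigma2`.
#' @return Covariance matrix, with the final jitter recorded in attribute
#'   `"jitter"` for the symmetric case.
#' @export
kernel_matrix <- function(kernel, X, groups, X2 = NULL, groups2 = NULL,
                          jitter = NULL) {
  X <- if (is.matrix(X)) X else matrix(X, ncol = kernel$p)
  gi <- group_index(kernel$groups, groups)
  stopifnot(nrow(X) == length(gi), all(is.finite(X)))
  if (!is.null(X2)) {
    X2 <- if (is.matrix(X2)) X2 else matrix(X2, ncol = kernel$p)
    gj <- group_index(kernel$groups, groups2)
    R2 <- pdist2(X, X2)
    I <- matrix(gi, nrow(X), nrow(X2))
    J <- matrix(gj, nrow(X), nrow(X2), byrow = TRUE)
    return(kernel_eval(kernel, R2, I, J))
  }
  n <- nrow(X)
  R2 <- pdist2(X, X)
  I <- matrix(gi, n, n)
  K <- kernel_eval(kernel, R2, I, t(I))
  K <- (K + t(K)) / 2
  if (is.null(jitter)) jitter <- 1e-8 * kernel$sigma2
  stopifnot(jitter >= 0)
  eps <- jitter
  repeat {
    ok <- tryCatch(
      {
        chol(K + diag(eps, n))
        TRUE
      },
      error = function(e) FALSE
    )
    if (ok) break
    if (eps == 0) eps <- 1e-8 * kernel$sigma2 else eps <- eps * 10
    if (eps > 1e-4 * kernel$sigma2) {
      ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
      stop(
        "covariance matrix is not positive definite even after jitter ",
        "escalation (minimum eigenvalue ", format(ev), ")",
        call. = FALSE
      )
    }
  }
  out <- K + diag(eps, n)
  attr(out, "jitter") <- eps
  out
}

#' Convenience constructors for the baseline processes
#'
#' Separate (`sgp`: independent RBF GPs per group, zero cross-covariance),
#' union (`ugp`: a single RBF GP ignoring group labels) and hierarchical
#' (`hgp`: shared RBF component plus a same-group RBF bonus) baselines,
#' all expressed as `mggp_kernel` objects.
#'
#' @inheritParams mggp_kernel
#' @param model One of `"sgp"`, `"ugp"`, `"hgp"`.
#' @return An [mggp_kernel()].
#' @export
baseline_kernel <- function(model = c("sgp", "ugp", "hgp"), groups, p = 1L,
                            sigma2 = 1, b = 1, k0 = NULL, k1 = NULL) {
  model <- match.arg(model)
  mggp_kernel(model,
    groups = groups, p = p, sigma2 = sigma2, b = b,
    k0 = k0, k1 = k1
  )
}

#' Write a covariance matrix as delimited text
#'
#' Debugging aid: dumps a kernel matrix with row/column indices.
#' @param K Matrix.
#' @param path Output path.
#' @param delim Delimiter.
#' @export
write_kernel_matrix <- function(K, path, delim = ",") {
  utils::write.table(K,
    file = path, sep = delim, row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a kernel configuration from a YAML-like key: value file
#'
#' Reads a flat `key: value` text configuration describing a kernel
#' (`family`, `p`, `sigma2`, `a`, `b`, `c`, `nu`, optional comma-separated
#' `labels`) and builds the corresponding [mggp_kernel()].
#'
#' @param path Path to the configuration file.
#' @return An [mggp_kernel()].
#' @export
read_kernel_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  cfg <- stats::setNames(as.list(vals), keys)
  labels <- if (!is.null(cfg$labels)) {
    trimws(strsplit(cfg$labels, ",")[[1]])
  } else {
    c("g1", "g2")
  }
  num <- function(key, default) {
    if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
  }
  mggp_kernel(
    family = if (is.null(cfg$family)) "mg_rbf" else cfg$family,
    groups = mggp_groups(labels),
    p = as.integer(num("p", 1)),
    sigma2 = num("sigma2", 1), a = num("a", 1), b = num("b", 1),
    c = num("c", 1), nu = num("nu", 1.5)
  )
}
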