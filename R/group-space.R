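#' Build a group space from labels and a distance matrix
#'
#' A group space represents the finite set of groups \eqn{\mathcal{C} =
#' \{c_1, \dots, c_k\}} over which a multi-group Gaussian process is defined,
#' together with a metric `d` between groups and the Gram matrix
#' \deqn{G_{ij} = \tfrac{1}{2}\{d(c_1, c_i) + d(c_1, c_j) - d(c_i, c_j)\}}
#' derived from it. Positive semi-definiteness of `G` is the validity
#' certificate for the Gneiting-class multi-group covariance functions built
#' on top of `d`; construction fails if `G` has an eigenvalue below
#' `-tol * max(diag-scale)`.
#'
#' When `distances` is omitted the noninformative discrete metric
#' \eqn{d_{ij} = 1 - \delta_{ij}} is used, under which all groups are
#' equidistant and the Gram matrix takes the block form with
#' \eqn{\tilde G = \tfrac12 I_{k-1} + \tfrac12 \mathbf{1}\mathbf{1}^\top}.
#'
#' @param labels Character (or coercible) vector of distinct group labels.
#'   Order is preserved; the first label is the anchor group of the Gram
#'   matrix (positive semi-definiteness does not depend on the anchor).
#' @param distances Optional `k x k` symmetric nonnegative matrix of group
#'   distances with zero diagonal. Defaults to the discrete metric.
#' @param tol Relative eigenvalue tolerance used in the PSD certificate.
#'
#' @return An object of class `mggp_groups`: a list with elements `labels`,
#'   `d` (distance matrix), `G` (Gram matrix), `base_index` (anchor index,
#'   always 1) and `k`.
#'
#' @examples
#' gs <- mggp_groups(c("A", "B"))
#' gs$G # matrix(c(0, 0, 0, 1), 2, 2)
#'
#' # an informative metric: groups A and B close, C far from both
#' d <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
#' )
#' mggp_groups(c("A", "B", "C"), d)
#' @export
mggp_groups <- function(labels, distances = NULL, tol = 1e-8) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("group labels must be distinct", call. = FALSE)
  }
  k <- length(labels)
  if (k < 1) stop("need at least one group label", call. = FALSE)
  if (is.null(distances)) {
    d <- 1 - diag(k)
  } else {
    d <- as.matrix(distances)
    if (!is.numeric(d) || nrow(d) != k || ncol(d) != k) {
      stop("`distances` must be a numeric ", k, " x ", k, " matrix", call. = FALSE)
    }
    if (any(abs(diag(d)) > 0)) {
      stop("`distances` must have a zero diagonal", call. = FALSE)
    }
    if (!isSymmetric(unname(d), tol = 1e-10)) {
      stop("`distances` must be symmetric", call. = FALSE)
    }
    if (any(d < 0)) {
      stop("`distances` must be nonnegative", call. = FALSE)
    }
  }
  dimnames(d) <- list(labels, labels)
  G <- gram_from_distances(d, base_index = 1L)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(diag(G), 1)
  if (min(ev) < -tol * scale) {
    stop(
      "Gram matrix derived from `distances` is not positive semi-definite ",
      "(minimum eigenvalue ", format(min(ev)), "); the metric does not ",
      "support a valid multi-group covariance function",
      call. = FALSE
    )
  }
  structure(
    list(labels = labels, d = d, G = G, base_index = 1L, k = k),
    class = "mggp_groups"
  )
}

# G_ij = (d(c1,ci) + d(c1,cj) - d(ci,cj)) / 2 for an arbitrary anchor c1
gram_from_distances <- function(d, base_index = 1L) {
  d1 <- d[base_index, ]
  G <- (outer(d1, d1, "+") - d) / 2
  (G + t(G)) / 2
}

#' @export
print.mggp_groups <- function(x, ...) {
  cat("<mggp_groups> ", x$k, " group(s): ",
    paste(utils::head(x$labels, 8), collapse = ", "),
    if (x$k > 8) ", ..." else "", "\n",
    sep = ""
  )
  discrete <- isTRUE(all.equal(unname(x$d), 1 - diag(x$k)))
  cat(
    "  metric: ", if (discrete) "discrete (all groups equidistant)" else "user-supplied",
    "; Gram matrix certified PSD\n",
    sep = ""
  )
  invisible(x)
}

group_index <- function(gs, labels) {
  idx <- match(as.character(labels), gs$labels)
  if (anyNA(idx)) {
    stop(
      "unknown group label(s): ",
      paste(unique(labels[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  idx
}

#' Homogeneous group covariance matrix
#'
#' A homogeneous covariance on a set of `k` groups depends only on whether two
#' labels coincide: the within-group value is fixed to 1 (variance is carried
#' by the spatial scale \eqn{\sigma^2} elsewhere) and every across-group entry
#' equals `b`. The resulting matrix \eqn{C = (1-b) I + b \mathbf{1}\mathbf{1}^\top}
#' is positive semi-definite exactly when \eqn{-1/(k-1) \le b \le 1}, i.e.
#' across-group association may not dominate within-group association.
#'
#' @param k Number of groups (>= 1).
#' @param b Across-group covariance value.
#' @return A list with elements `C` (the `k x k` matrix), `b`,
#'   `within_group_value` (always 1), and `valid` (logical; `TRUE` iff
#'   `-1/(k-1) <= b <= 1`). Invalid `b` does not raise; callers decide.
#' @examples
#' homogeneous_group_cov(3, 0.5)$valid # TRUE
#' homogeneous_group_cov(3, -0.6)$valid # FALSE: below -1/(k-1) = -0.5
#' @export
homogeneous_group_cov <- function(k, b) {
  stopifnot(k >= 1)
  C <- matrix(b, k, k)
  diag(C) <- 1
  lower <- if (k > 1) -1 / (k - 1) else -Inf
  list(
    C = C,
    b = b,
    within_group_value = 1,
    valid = (b >= lower && b <= 1)
  )
}

#' Smallest valid across-group value by brute-force eigenvalue search
#'
#' Scans a grid of candidate across-group values `b` in `[-2, 1]` and returns
#' the smallest one for which the `k x k` homogeneous covariance matrix has
#' minimum eigenvalue above `-tol`. The check is a direct numerical
#' eigendecomposition of each candidate matrix; the closed-form bound
#' \eqn{b \ge -1/(k-1)} is deliberately not used, so this function serves as
#' an independent oracle for it.
#'
#' @param k Number of groups (>= 2).
#' @param grid_step Grid resolution over `[-2, 1]`.
#' @param tol Absolute eigenvalue tolerance.
#' @return The smallest grid value of `b` giving a PSD matrix.
#' @examples
#' min_valid_b(2) # ~ -1
#' min_valid_b(5) # ~ -0.25
#' @export
min_valid_b <- function(k, grid_step = 1e-3, tol = 1e-8) {
  stopifnot(k >= 2, grid_step > 0)
  grid <- seq(-2, 1, by = grid_step)
  for (b in grid) {
    C <- matrix(b, k, k)
    diag(C) <- 1
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) >= -tol) {
      return(b)
    }
  }
  stop("no valid b found on the grid", call. = FALSE) # unreachable: b = 1 is PSD
}

#' Read / write a group distance matrix
#'
#' Plain-text interchange for group metrics: a delimited file with a header
#' row of group labels followed by `k` rows of distances.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return `read_group_distances()` returns a named `k x k` matrix;
#'   `write_group_distances()` returns `path` invisibly.
#' @export
read_group_distances <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  storage.mode(m) <- "double"
  m
}

#' @rdname read_group_distances
#' @param d A `k x k` distance matrix with column names giving the labels.
#' @export
write_group_distances <- function(d, path, delim = ",") {
  utils::write.table(d,
    file = path, sep = delim, row.names = FALSE,
    col.names = TRUE, quote = FALSE
  )
  invisible(path)
}

#' Enumerate unordered group pairs
#'
#' @param labels Character vector of group labels (or an `mggp_groups`).
#' @return A tibble with columns `group1`, `group2`, one row per unordered
#'   pair; `k(k-1)/2` rows for `k` labels.
#' @examples
#' nrow(group_pairs(letters[1:5])) # 10
#' @export
group_pairs <- function(labels) {
  if (inherits(labels, "mggp_groups")) labels <- labels$labels
  labels <- as.character(labels)
  k <- length(labels)
  if (k < 2) {
    return(tibble::tibble(group1 = character(), group2 = character()))
  }
  idx <- utils::combn(k, 2)
  tibble::tibble(group1 = labels[idx[1, ]], group2 = labels[idx[2, ]])
}
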