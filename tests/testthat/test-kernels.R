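gs2 <- mggp_groups(c("A", "B"))

test_that("multi-group RBF matches hand-evaluated values", {
  k <- mggp_kernel("mg_rbf", gs2, p = 1, sigma2 = 1.7, a = 2, b = 0.5)
  # same point, same group: sigma^2
  expect_equal(kernel_value(k, 0.3, "A", 0.3, "A"), 1.7)
  # same point, different groups at sigma2 = a = b = 1, p = 1: 1/sqrt(2)
  k1 <- mggp_kernel("mg_rbf", gs2, p = 1, sigma2 = 1, a = 1, b = 1)
  expect_equal(kernel_value(k1, 0.4, "A", 0.4, "B"), 1 / sqrt(2),
    tolerance = 1e-12
  )
  # a = 0: the union-GP RBF for every group pair
  k0 <- mggp_kernel("mg_rbf", gs2, p = 1, sigma2 = 2, a = 0, b = 1.3)
  x <- seq(-2, 2, length.out = 7)
  for (gpair in list(c("A", "A"), c("A", "B"))) {
    expect_equal(
      kernel_value(k0, x, gpair[1], rev(x), gpair[2]),
      2 * exp(-1.3^2 * (x - rev(x))^2),
      tolerance = 1e-12
    )
  }
  expect_error(kernel_value(k1, 0, "A", 0, "Z"), "unknown group")
})

test_that("multi-group Matern reduces to the exponential at nu = 1/2", {
  set.seed(1)
  for (rep in 1:5) {
    pr <- rand_params()
    km <- mggp_kernel("mg_matern", gs2,
      p = 2, sigma2 = pr$sigma2, a = pr$a,
      b = pr$b, c = pr$c, nu = 0.5
    )
    ke <- mggp_kernel("mg_exponential", gs2,
      p = 2, sigma2 = pr$sigma2,
      a = pr$a, b = pr$b, c = pr$c
    )
    X1 <- matrix(rnorm(20), ncol = 2)
    X2 <- matrix(rnorm(20), ncol = 2)
    g1 <- sample(c("A", "B"), 10, TRUE)
    g2 <- sample(c("A", "B"), 10, TRUE)
    expect_equal(
      kernel_value(km, X1, g1, X2, g2),
      kernel_value(ke, X1, g1, X2, g2),
      tolerance = 1e-10
    )
  }
})

test_that("Matern/exponential families factorize exactly at c = 1", {
  # separability = (spatial factor) x (group factor): swapping the group
  # pair between two different spatial lags leaves the product unchanged
  set.seed(2)
  gs3 <- mggp_groups(c("A", "B", "C"))
  pairs <- expand.grid(ci = gs3$labels, cj = gs3$labels,
    stringsAsFactors = FALSE
  )
  for (fam in c("mg_matern", "mg_exponential")) {
    sep <- mggp_kernel(fam, gs3,
      p = 1, sigma2 = 1.4, a = 0.8, b = 1.1,
      c = 1, nu = 1.5
    )
    nonsep <- mggp_kernel(fam, gs3,
      p = 1, sigma2 = 1.4, a = 0.8, b = 1.1,
      c = 3, nu = 1.5
    )
    r1 <- 0.37
    r2 <- 1.91
    viol <- function(k) {
      worst <- 0
      for (i in seq_len(nrow(pairs))) {
        for (j in seq_len(nrow(pairs))) {
          lhs <- kernel_value(k, r1, pairs$ci[i], 0, pairs$cj[i]) *
            kernel_value(k, r2, pairs$ci[j], 0, pairs$cj[j])
          rhs <- kernel_value(k, r1, pairs$ci[j], 0, pairs$cj[j]) *
            kernel_value(k, r2, pairs$ci[i], 0, pairs$cj[i])
          worst <- max(worst, abs(lhs - rhs) / abs(rhs))
        }
      }
      worst
    }
    expect_lt(viol(sep), 1e-10)
    expect_gt(viol(nonsep), 1e-3) # the factorization is specific to c = 1
  }
})

test_that("within a group the Matern family is the standard Matern", {
  k <- mggp_kernel("mg_matern", gs2, p = 1, sigma2 = 2, a = 3, b = 0.7, c = 1, nu = 1.5)
  r <- seq(0.1, 3, length.out = 10)
  z <- 0.7 * r # normalized Matern at nu = 3/2 is (1 + z) exp(-z)
  expect_equal(
    kernel_value(k, r, "A", rep(0, 10), "A"),
    2 * (1 + z) * exp(-z),
    tolerance = 1e-10
  )
  # continuity at x -> x'
  expect_equal(kernel_value(k, 1e-9, "A", 0, "B"),
    kernel_value(k, 0, "A", 0, "B"),
    tolerance = 1e-6
  )
  # degenerate same point, same group: sigma^2
  expect_equal(kernel_value(k, 0.2, "A", 0.2, "A"), 2)
})

test_that("generic Gneiting construction reproduces the multi-group RBF", {
  a <- 1.3
  b <- 0.8
  s2 <- 1.9
  fns <- monotone_pair("powexp", "power",
    phi_pars = list(c = b^2, gamma = 1),
    psi_pars = list(a = a^2, alpha = 1, beta = 1)
  )
  kg <- mggp_kernel("gneiting", gs2, p = 2, sigma2 = s2, fns = fns)
  kr <- mggp_kernel("mg_rbf", gs2, p = 2, sigma2 = s2, a = a, b = b)
  set.seed(3)
  X1 <- matrix(rnorm(16), ncol = 2)
  X2 <- matrix(rnorm(16), ncol = 2)
  g1 <- sample(c("A", "B"), 8, TRUE)
  g2 <- sample(c("A", "B"), 8, TRUE)
  expect_equal(
    kernel_value(kg, X1, g1, X2, g2),
    kernel_value(kr, X1, g1, X2, g2),
    tolerance = 1e-12
  )
  # symmetry in the two arguments
  expect_equal(
    kernel_value(kg, X1, g1, X2, g2),
    kernel_value(kg, X2, g2, X1, g1),
    tolerance = 1e-12
  )
  # d = 0 with psi(0) = 1: sigma^2 * phi(r^2); p = 2 so the scalar input
  # is the point (1.5, 1.5)
  expect_equal(
    kernel_value(kg, 1.5, "A", 0, "A"),
    s2 * fns$phi(2 * 1.5^2),
    tolerance = 1e-12
  )
})

test_that("monotone-pair candidates satisfy shape spot checks", {
  tgrid <- seq(0, 5, length.out = 50)
  for (phi in c("powexp", "matern", "cauchy", "hyperbolic")) {
    for (psi in c("power", "log", "ratio")) {
      fns <- monotone_pair(phi, psi,
        phi_pars = list(c = 0.9, gamma = 0.8, nu = 1.2),
        psi_pars = list(a = 1.1, alpha = 0.7, beta = 0.9, b = 3)
      )
      pv <- fns$phi(tgrid)
      sv <- fns$psi(tgrid)
      expect_true(all(pv > 0), info = paste(phi, "positive"))
      expect_true(all(diff(pv) <= 1e-12), info = paste(phi, "nonincreasing"))
      expect_true(all(sv > 0), info = paste(psi, "positive"))
      expect_true(all(diff(sv) >= -1e-12), info = paste(psi, "nondecreasing"))
    }
  }
})

test_that("baseline processes have the defining cross-group structure", {
  gsb <- mggp_groups(c("A", "B"))
  sgp <- baseline_kernel("sgp", gsb, sigma2 = 1.5, b = 1)
  ugp <- baseline_kernel("ugp", gsb, sigma2 = 1.5, b = 1)
  hgp <- baseline_kernel("hgp", gsb,
    k0 = list(sigma2 = 0.6, b = 1),
    k1 = list(sigma2 = 0.9, b = 2)
  )
  expect_equal(kernel_value(sgp, 0.1, "A", 0.4, "B"), 0)
  expect_equal(kernel_value(sgp, 0.1, "A", 0.1, "A"), 1.5)
  expect_equal(kernel_value(ugp, 2, "A", 2, "B"), 1.5)
  expect_equal(kernel_value(hgp, 1, "A", 1, "A"), 0.6 + 0.9)
  expect_equal(kernel_value(hgp, 1, "A", 1, "B"), 0.6)
})

test_that("assembled covariance matrices are PSD across families", {
  set.seed(4)
  fams <- c(
    "mg_rbf", "mg_matern", "mg_exponential", "gneiting", "separable",
    "sgp", "ugp", "hgp"
  )
  for (fam in fams) {
    for (rep in 1:10) {
      pr <- rand_params()
      p <- sample(1:3, 1)
      k <- sample(c(2, 3, 5), 1)
      gs <- mggp_groups(paste0("g", 1:k))
      kern <- switch(fam,
        gneiting = mggp_kernel("gneiting", gs,
          p = p, sigma2 = pr$sigma2,
          fns = monotone_pair("cauchy", "power",
            phi_pars = list(c = pr$b, gamma = 0.9, nu = pr$nu),
            psi_pars = list(a = pr$a, alpha = 0.8, beta = 0.9)
          )
        ),
        separable = mggp_kernel("separable", gs,
          p = p, sigma2 = pr$sigma2,
          b = pr$b,
          group_cov = homogeneous_group_cov(k, runif(1, -1 / (k - 1), 1))
        ),
        mggp_kernel(fam, gs,
          p = p, sigma2 = pr$sigma2, a = pr$a, b = pr$b,
          c = pr$c, nu = pr$nu
        )
      )
      n <- sample(10:40, 1)
      X <- matrix(runif(n * p, -3, 3), ncol = p)
      g <- sample(gs$labels, n, TRUE)
      K <- kernel_matrix(kern, X, g, X2 = X, groups2 = g) # raw, no jitter
      expect_true(is_psd_matrix(K, tol = 1e-8),
        info = paste("family", fam, "rep", rep)
      )
    }
  }
})

test_that("group-similarity limits recover the union and separate processes", {
  set.seed(5)
  n <- 20
  X <- matrix(runif(n, -3, 3), ncol = 1)
  g <- rep(c("A", "B"), each = 10)
  ugp <- baseline_kernel("ugp", gs2, sigma2 = 1, b = 1)
  Ku <- kernel_matrix(ugp, X, g, X2 = X, groups2 = g)
  Ka0 <- kernel_matrix(
    mggp_kernel("mg_rbf", gs2, sigma2 = 1, a = 1e-9, b = 1),
    X, g,
    X2 = X, groups2 = g
  )
  expect_lt(max(abs(Ka0 - Ku)), 1e-12)

  Kbig <- kernel_matrix(
    mggp_kernel("mg_rbf", gs2, sigma2 = 1, a = 1e6, b = 1),
    X, g,
    X2 = X, groups2 = g
  )
  cross <- Kbig[g == "A", g == "B"]
  expect_lt(max(abs(cross)), 1e-6)
  within <- Kbig[g == "A", g == "A"]
  expect_equal(within, Ku[g == "A", g == "A"], tolerance = 1e-12)
})

test_that("jitter escalation and failure reporting work", {
  # duplicated points: singular RBF matrix needs jitter for Cholesky
  k <- mggp_kernel("mg_rbf", gs2, sigma2 = 1, a = 1, b = 1)
  X <- matrix(c(0, 0, 1), ncol = 1)
  g <- c("A", "A", "B")
  K <- kernel_matrix(k, X, g)
  expect_true(attr(K, "jitter") > 0)
  expect_silent(chol(K))
  expect_equal(unname(kernel_matrix(k, matrix(0), "A", jitter = 0)[1, 1]), 1)
  # an invalid homogeneous group factor is refused at construction
  expect_error(
    mggp_kernel("separable", gs2,
      group_cov = homogeneous_group_cov(2, -1.5)
    ),
    "positive semi-definite"
  )
})

test_that("kernel configuration files round-trip through the reader", {
  path <- tempfile(fileext = ".txt")
  writeLines(c(
    "family: mg_rbf", "p: 2", "sigma2: 1.5", "a: 0.5", "b: 2",
    "labels: A, B, C"
  ), path)
  k <- read_kernel_config(path)
  expect_equal(k$family, "mg_rbf")
  expect_equal(k$p, 2L)
  expect_equal(k$sigma2, 1.5)
  expect_equal(k$groups$labels, c("A", "B", "C"))
})
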