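test_that("default hyperparameters follow the data-driven rules", {
  set.seed(21)
  X <- matrix(rnorm(40, sd = 2), 20, 2)
  pr <- niw_default_prior(X)
  expect_equal(pr$mu0, colMeans(X))
  expect_equal(pr$lambda0, 1)
  expect_equal(pr$nu0, ncol(X))
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(pr$Psi0, (ncol(X) - 1) * solve(crossprod(Xc)), tolerance = 1e-12)

  # p = 1 collapses the (p - 1) factor: default refuses, asks for Psi0
  expect_error(niw_default_prior(matrix(c(-1, 1), 2, 1)), "Psi0")
  expect_error(niw_default_prior(matrix(1:2, 1, 2)), "at least 2")
})

test_that("posterior updates match the closed-form conjugate formulas", {
  pr <- niw_prior(mu0 = c(1, -1), lambda0 = 1, Psi0 = diag(2), nu0 = 2)

  post0 <- niw_posterior(pr, NULL)
  expect_equal(post0$mu1, pr$mu0)
  expect_equal(post0$Psi1, pr$Psi0)
  expect_equal(post0$lambda1, pr$lambda0)
  expect_equal(post0$nu1, pr$nu0)

  x <- c(3, 5)
  post1 <- niw_posterior(pr, matrix(x, 1, 2))
  expect_equal(post1$mu1, (pr$mu0 + x) / 2)
  expect_equal(post1$lambda1, 2)
  expect_equal(post1$nu1, 3)
  # single point: no scatter, only the shrinkage term
  expect_equal(post1$Psi1, diag(2) + 0.5 * tcrossprod(x - pr$mu0))

  # scalar oracle in p = 1
  pr1 <- niw_prior(mu0 = 0.5, lambda0 = 2, Psi0 = matrix(3), nu0 = 4)
  xs <- c(1, 3)
  post2 <- niw_posterior(pr1, matrix(xs, 2, 1))
  xbar <- 2
  expect_equal(post2$mu1, (2 * 0.5 + 2 * xbar) / 4)
  expect_equal(drop(post2$Psi1),
               3 + sum((xs - xbar)^2) + (2 * 2 / 4) * (xbar - 0.5)^2)
})

test_that("batch and sequential updates agree and order does not matter", {
  set.seed(8)
  for (i in 1:100) {
    p <- sample(1:3, 1)
    n_k <- sample(1:8, 1)
    pr <- niw_prior(rnorm(p), runif(1, .5, 3), crossprod(matrix(rnorm(p * p), p)) + diag(p),
                    p + runif(1, 0, 2))
    Xk <- random_cluster(n_k, p)
    batch <- niw_posterior(pr, Xk)
    # one observation at a time, treating each posterior as the next prior
    seq_pr <- pr
    for (r in seq_len(n_k)) {
      po <- niw_posterior(seq_pr, Xk[r, , drop = FALSE])
      seq_pr <- list(mu0 = po$mu1, lambda0 = po$lambda1, Psi0 = po$Psi1,
                     nu0 = po$nu1)
    }
    expect_equal(seq_pr$mu0, batch$mu1, tolerance = 1e-10)
    expect_equal(seq_pr$lambda0, batch$lambda1, tolerance = 1e-10)
    expect_equal(seq_pr$Psi0, batch$Psi1, tolerance = 1e-10)
    expect_equal(seq_pr$nu0, batch$nu1, tolerance = 1e-10)

    perm_post <- niw_posterior(pr, Xk[sample.int(n_k), , drop = FALSE])
    expect_equal(perm_post$Psi1, batch$Psi1, tolerance = 1e-12)
    expect_true(all(eigen(batch$Psi1, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("the posterior predictive is a proper, symmetric density", {
  pr <- niw_prior(mu0 = 0.3, lambda0 = 1.5, Psi0 = matrix(2), nu0 = 3)
  post <- niw_posterior(pr, matrix(c(-1, 0, 2), 3, 1))

  # quadrature: the p = 1 density integrates to 1
  grid <- seq(-60, 60, by = 0.01)
  dens <- vapply(grid, function(g) exp(log_predictive(g, post)), numeric(1))
  expect_equal(sum(dens) * 0.01, 1, tolerance = 1e-2)

  # elliptical symmetry about mu1
  for (v in c(0.3, 1.7, 4)) {
    expect_equal(log_predictive(post$mu1 + v, post),
                 log_predictive(post$mu1 - v, post))
  }

  # large-df limit approaches the Gaussian with matched mean and variance
  post_big <- niw_posterior(pr, matrix(rnorm(4000, 1, 2), ncol = 1))
  df <- post_big$nu1 - 1 + 1
  s2 <- drop(post_big$Psi1) * (post_big$lambda1 + 1) /
    (post_big$lambda1 * df) * df / (df - 2)
  x0 <- post_big$mu1 + 0.7
  expect_equal(log_predictive(x0, post_big),
               dnorm(x0, post_big$mu1, sqrt(s2), log = TRUE), tolerance = 1e-3)
})

test_that("the sampler's compiled predictive matches the R reference", {
  set.seed(17)
  for (i in 1:20) {
    p <- sample(1:3, 1)
    pr <- niw_prior(rnorm(p), runif(1, .5, 2),
                    crossprod(matrix(rnorm(p * p), p)) + diag(p), p + 1)
    n_k <- sample(0:6, 1)
    Xk <- if (n_k > 0) random_cluster(n_k, p) else matrix(numeric(0), 0, p)
    x <- rnorm(p)
    r_val <- log_predictive(x, niw_posterior(pr, Xk))
    cpp_val <- tipclust:::logpred_niw_cpp(x, Xk, pr$mu0, pr$lambda0,
                                          pr$Psi0, pr$nu0)
    expect_equal(cpp_val, r_val, tolerance = 1e-12)
  }
})
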