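#' Default Normal-Inverse-Wishart hyperparameters
#'
#' Data-driven defaults for the conjugate NIW prior on each cluster's mean and
#' covariance: the location is the grand mean, the precision scale is 1, the
#' degrees of freedom equal the dimension, and the scale matrix is
#' (p - 1) times the inverse of the global centered scatter matrix.
#'
#' For p = 1 the (p - 1) factor collapses the scale matrix to zero, so the
#' default is undefined and a user-supplied `Psi0` is required.
#'
#' @param X n x p data matrix, n >= 2.
#' @return list with `mu0` (p-vector), `lambda0`, `Psi0` (p x p), `nu0`.
#' @export
niw_default_prior <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 rows to set default hyperparameters", call. = FALSE)
  if (p < 2)
    stop("default scale matrix is degenerate for p = 1; supply Psi0 explicitly",
         call. = FALSE)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  scatter <- crossprod(Xc)
  inv <- tryCatch(solve(scatter), error = function(e)
    stop("global scatter matrix is singular; add a ridge or supply Psi0",
         call. = FALSE))
  Psi0 <- (p - 1) * inv
  Psi0 <- 0.5 * (Psi0 + t(Psi0))
  list(mu0 = xbar, lambda0 = 1, Psi0 = Psi0, nu0 = p)
}

#' Build (or validate) an NIW prior
#'
#' @param mu0 location p-vector.
#' @param lambda0 positive precision scale.
#' @param Psi0 p x p symmetric positive-definite scale matrix.
#' @param nu0 degrees of freedom, > p - 1.
#' @return validated prior list.
#' @export
niw_prior <- function(mu0, lambda0, Psi0, nu0) {
  Psi0 <- as.matrix(Psi0)
  p <- length(mu0)
  stopifnot(lambda0 > 0, nrow(Psi0) == p, ncol(Psi0) == p, nu0 > p - 1)
  if (max(abs(Psi0 - t(Psi0))) > 1e-8 * (1 + max(abs(Psi0))))
    stop("Psi0 must be symmetric", call. = FALSE)
  ev <- eigen(0.5 * (Psi0 + t(Psi0)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Psi0 must be positive definite", call. = FALSE)
  list(mu0 = as.numeric(mu0), lambda0 = lambda0,
       Psi0 = 0.5 * (Psi0 + t(Psi0)), nu0 = nu0)
}

#' Conjugate NIW posterior update for one cluster
#'
#' Standard closed-form update: the posterior location is a precision-weighted
#' average of prior location and cluster mean, the scale matrix accrues the
#' within-cluster scatter plus a shrinkage term for the mean shift, and the
#' counts add to `lambda0` and `nu0`. With zero observations the posterior is
#' the prior.
#'
#' @param prior list from [niw_prior()] / [niw_default_prior()].
#' @param cluster_data n_k x p matrix of the cluster's members (possibly 0
#'   rows).
#' @return list with `mu1`, `lambda1`, `Psi1`, `nu1`, `n_k`, `xbar_k`.
#' @export
niw_posterior <- function(prior, cluster_data) {
  p <- length(prior$mu0)
  if (is.null(cluster_data) || length(cluster_data) == 0) {
    cluster_data <- matrix(numeric(0), nrow = 0, ncol = p)
  }
  cluster_data <- matrix(as.numeric(cluster_data), ncol = p)
  n_k <- nrow(cluster_data)
  if (n_k == 0) {
    return(list(mu1 = prior$mu0, lambda1 = prior$lambda0, Psi1 = prior$Psi0,
                nu1 = prior$nu0, n_k = 0L, xbar_k = rep(NA_real_, p)))
  }
  xbar <- colMeans(cluster_data)
  Xc <- sweep(cluster_data, 2, xbar)
  scatter <- crossprod(Xc)
  lambda1 <- prior$lambda0 + n_k
  dv <- xbar - prior$mu0
  Psi1 <- prior$Psi0 + scatter +
    (prior$lambda0 * n_k / lambda1) * tcrossprod(dv)
  list(mu1 = (prior$lambda0 * prior$mu0 + n_k * xbar) / lambda1,
       lambda1 = lambda1,
       Psi1 = 0.5 * (Psi1 + t(Psi1)),
       nu1 = prior$nu0 + n_k,
       n_k = as.integer(n_k),
       xbar_k = xbar)
}

#' Log posterior-predictive density under a cluster's NIW posterior
#'
#' The NIW posterior predictive is a multivariate Student-t with
#' `nu1 - p + 1` degrees of freedom, location `mu1`, and scale
#' `Psi1 * (lambda1 + 1) / (lambda1 * (nu1 - p + 1))`. For an empty cluster
#' this is the prior predictive.
#'
#' @param x p-vector to score.
#' @param post posterior list from [niw_posterior()] (or a prior, for the
#'   prior predictive).
#' @return finite log-density.
#' @export
log_predictive <- function(x, post) {
  mu <- if (!is.null(post$mu1)) post$mu1 else post$mu0
  lam <- if (!is.null(post$lambda1)) post$lambda1 else post$lambda0
  Psi <- if (!is.null(post$Psi1)) post$Psi1 else post$Psi0
  nu <- if (!is.null(post$nu1)) post$nu1 else post$nu0
  p <- length(mu)
  df <- nu - p + 1
  if (df <= 0) stop("predictive degrees of freedom must be positive", call. = FALSE)
  Sigma <- Psi * (lam + 1) / (lam * df)
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("predictive scale matrix is not positive definite", call. = FALSE))
  z <- backsolve(R, x - mu, transpose = TRUE)
  quad <- sum(z^2)
  lgamma((df + p) / 2) - lgamma(df / 2) - (p / 2) * log(df * pi) -
    sum(log(diag(R))) - ((df + p) / 2) * log1p(quad / df)
}
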