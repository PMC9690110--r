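#' Simulate Gaussian clusters with inverse-Wishart covariances
#'
#' Draws K cluster means from N_p(0, mean_scale * I), K covariances from an
#' inverse-Wishart(iw_scale, iw_df), and then each subject from its cluster's
#' Gaussian. This is the generative design used throughout the package's
#' simulation studies: heavy-ish random covariances around widely dispersed
#' means.
#'
#' @param sizes integer vector of per-cluster subject counts.
#' @param p dimension.
#' @param mean_scale variance multiplier of the mean prior (default 10).
#' @param iw_scale p x p SPD scale matrix of the inverse-Wishart (identity).
#' @param iw_df inverse-Wishart degrees of freedom (default p + 1).
#' @param seed integer seed; the draw is fully reproducible.
#' @return object of class `sim_clusters`: list with `X` (n x p matrix),
#'   `labels` (integer truth), `means`, `covs`, and the generating `spec`.
#' @export
#' @examples
#' d <- simulate_clusters(sizes = c(20, 25, 30, 35), p = 2, seed = 1)
#' table(d$labels)
simulate_clusters <- function(sizes, p, mean_scale = 10,
                              iw_scale = diag(p), iw_df = p + 1, seed = NULL) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 1), p >= 1, iw_df > p - 1)
  if (!is.null(seed)) set.seed(seed)
  K <- length(sizes)
  means <- lapply(seq_len(K), function(k) rnorm(p, 0, sqrt(mean_scale)))
  covs <- lapply(seq_len(K), function(k) rinvwishart(iw_scale, iw_df))
  n <- sum(sizes)
  X <- matrix(NA_real_, n, p)
  labels <- rep(seq_len(K), sizes)
  row <- 1L
  for (k in seq_len(K)) {
    X[row:(row + sizes[k] - 1L), ] <-
      MASS::mvrnorm(sizes[k], mu = means[[k]], Sigma = covs[[k]])
    row <- row + sizes[k]
  }
  rownames(X) <- as.character(seq_len(n))
  structure(list(X = X, labels = labels, means = means, covs = covs,
                 spec = list(sizes = sizes, p = p, mean_scale = mean_scale,
                             iw_scale = iw_scale, iw_df = iw_df, seed = seed)),
            class = "sim_clusters")
}

# Inverse-Wishart(Psi, nu) draw: invert a Wishart(Psi^-1, nu) draw.
rinvwishart <- function(Psi, nu) {
  W <- stats::rWishart(1, df = nu, Sigma = solve(Psi))[, , 1]
  S <- solve(W)
  0.5 * (S + t(S))
}

#' @export
as.data.frame.sim_clusters <- function(x, ...) {
  df <- as.data.frame(x$X)
  names(df) <- paste0("V", seq_len(ncol(x$X)))
  df$.cluster <- x$labels
  df
}

#' @export
print.sim_clusters <- function(x, ...) {
  cat("Simulated Gaussian clusters: n =", nrow(x$X), " p =", ncol(x$X),
      " K* =", length(x$spec$sizes), "\n")
  cat("sizes:", paste(x$spec$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Scenario presets for the simulation studies
#'
#' `"sim1"` is the well-separated design (four clusters of 20/25/30/35 points
#' in two dimensions, generated until the separation filter passes);
#' `"sim2"` is the overlapped design (sizes 20/25/30/45, no separation
#' requirement).
#'
#' @param preset `"sim1"` or `"sim2"`.
#' @param seed integer seed.
#' @param min_centroid_gap pooled-Mahalanobis gap required between every pair
#'   of realized cluster means for `"sim1"`.
#' @param max_tries how many incremented seeds to try for `"sim1"`.
#' @return a `sim_clusters` object; for `"sim1"` the attribute
#'   `"seeds_skipped"` records seeds whose realization failed the filter.
#' @export
sim_preset <- function(preset = c("sim1", "sim2"), seed = 1,
                       min_centroid_gap = 6, max_tries = 1000) {
  preset <- match.arg(preset)
  if (preset == "sim2") {
    return(simulate_clusters(sizes = c(20, 25, 30, 45), p = 2, seed = seed))
  }
  skipped <- integer(0)
  s <- as.integer(seed)
  for (i in seq_len(max_tries)) {
    d <- simulate_clusters(sizes = c(20, 25, 30, 35), p = 2, seed = s)
    if (separation_filter(d, min_centroid_gap)) {
      attr(d, "seeds_skipped") <- skipped
      return(d)
    }
    skipped <- c(skipped, s)
    s <- s + 1L
  }
  stop("no well-separated realization found in ", max_tries, " seeds", call. = FALSE)
}

#' Well-separation filter on a simulated dataset
#'
#' TRUE when every pair of realized cluster means is at least
#' `min_centroid_gap` apart in Mahalanobis distance under the pooled
#' within-cluster covariance of the drawn cluster covariances.
#'
#' @param data a `sim_clusters` object.
#' @param min_centroid_gap nonnegative gap threshold (pooled-Mahalanobis
#'   units).
#' @return logical scalar.
#' @export
separation_filter <- function(data, min_centroid_gap = 6) {
  stopifnot(inherits(data, "sim_clusters"))
  K <- length(data$means)
  if (K < 2) stop("separation requires at least two clusters", call. = FALSE)
  if (min_centroid_gap <= 0) return(TRUE)
  sizes <- data$spec$sizes
  pooled <- Reduce(`+`, Map(function(S, w) w * S, data$covs,
                            as.list(sizes / sum(sizes))))
  Pinv <- solve(pooled)
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) {
      dv <- data$means[[a]] - data$means[[b]]
      if (sqrt(drop(t(dv) %*% Pinv %*% dv)) < min_centroid_gap) return(FALSE)
    }
  }
  TRUE
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions (up to
#' label names), around 0 for independent ones.
#'
#' @param c1,c2 label vectors of equal length.
#' @return numeric scalar.
#' @export
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
adjusted_rand <- function(c1, c2) {
  if (length(c1) != length(c2)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(c1, c2)
  a <- sum(choose(tab, 2))
  b1 <- sum(choose(rowSums(tab), 2))
  b2 <- sum(choose(colSums(tab), 2))
  C <- choose(length(c1), 2)
  expected <- b1 * b2 / C
  denom <- (b1 + b2) / 2 - expected
  if (denom == 0) return(ifelse(a == expected, 1, 0))
  (a - expected) / denom
}
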