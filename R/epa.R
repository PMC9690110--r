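#' Ewens-Pitman Attraction conditional seating probabilities
#'
#' Probability that the subject at position `i_pos` of the seating permutation
#' joins each existing cluster or opens a new one. An existing cluster S gets
#' weight `((i-1 - delta*q) / (alpha + i-1)) * sum_{s in S} lambda(i, s) /
#' sum(all seated)`, a new cluster gets `(alpha + delta*q) / (alpha + i-1)`,
#' where q is the number of clusters among the already-seated subjects. With
#' `delta = 0` and constant similarity this is exactly the Chinese Restaurant
#' Process.
#'
#' @param L similarity matrix.
#' @param perm seating permutation of subject indices.
#' @param i_pos position (>= 2) in the permutation being seated.
#' @param partial_labels cluster labels (contiguous from 1) of
#'   `perm[1..i_pos-1]`, in seating order.
#' @param alpha mass parameter (> -delta).
#' @param delta discount in \[0, 1).
#' @return probability vector of length q + 1; the last entry is the new
#'   cluster.
#' @export
epa_conditional <- function(L, perm, i_pos, partial_labels, alpha, delta = 0) {
  stopifnot(i_pos >= 2, length(partial_labels) == i_pos - 1,
            delta >= 0, delta < 1, alpha > -delta)
  i <- perm[i_pos]
  seated <- perm[seq_len(i_pos - 1)]
  q <- length(unique(partial_labels))
  sims <- L[i, seated]
  denom <- sum(sims)
  if (denom <= 0) stop("zero total similarity to seated subjects", call. = FALSE)
  im1 <- i_pos - 1
  w <- vapply(seq_len(q), function(k) {
    ((im1 - delta * q) / (alpha + im1)) * sum(sims[partial_labels == k]) / denom
  }, numeric(1))
  p_new <- (alpha + delta * q) / (alpha + im1)
  c(w, p_new)
}

#' Sample the CRP/EPA mass parameter from West's approximate posterior
#'
#' Given the current number of clusters K, draws
#' `alpha ~ Gamma(a + K - 1, rate = b + gamma + log(n))` where gamma is the
#' Euler-Mascheroni constant. With `a = b = 1` (the default used throughout)
#' the prior on alpha is standard exponential.
#'
#' @param n_clusters current cluster count (>= 1).
#' @param n subject count.
#' @param a,b gamma prior parameters.
#' @return one positive draw.
#' @export
sample_alpha_west <- function(n_clusters, n, a = 1, b = 1) {
  shape <- a + n_clusters - 1
  if (shape <= 0) stop("gamma shape must be positive", call. = FALSE)
  rate <- b + euler_gamma() + log(n)
  stats::rgamma(1, shape = shape, rate = rate)
}

euler_gamma <- function() -digamma(1)

#' Run the EPA (or CRP) baseline sampler
#'
#' Each iteration draws a fresh uniform seating permutation, reseats all
#' subjects sequentially by the EPA conditional times (optionally) the NIW
#' posterior predictive of the already-seated members, then updates the mass
#' parameter alpha from West's approximate posterior given the new cluster
#' count. `prior = "crp"` fixes constant similarity (and `delta = 0`), the
#' exact Chinese Restaurant Process special case.
#'
#' @inheritParams run_tip
#' @param prior `"epa"` or `"crp"`.
#' @param delta discount parameter (0 in all the package's studies).
#' @param alpha_init mass parameter used for the first sweep.
#' @param fixed_alpha keep alpha at this value instead of sampling it.
#' @param a,b West posterior prior parameters.
#' @return a `tip_fit` whose `log_info` also records the alpha trace.
#' @export
run_epa <- function(X = NULL, distances = NULL, metric = "euclidean",
                    burn_in = 1000, samples = 1000, seed = NULL,
                    prior = c("epa", "crp"), delta = 0, alpha_init = 1,
                    fixed_alpha = NULL, a = 1, b = 1,
                    use_likelihood = !is.null(X), niw = NULL) {
  prior <- match.arg(prior)
  if (prior == "crp") delta <- 0
  inp <- prepare_inputs(X, distances, metric, use_likelihood, niw,
                        constant_similarity = (prior == "crp"))
  n <- inp$n
  stopifnot(samples >= 1, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  alpha <- if (is.null(fixed_alpha)) alpha_init else fixed_alpha

  total <- burn_in + samples
  draws <- matrix(NA_integer_, samples, n)
  K_trace <- integer(total)
  alpha_trace <- numeric(total)

  for (t in seq_len(total)) {
    perm <- sample.int(n)
    state <- relabel_consecutive(
      epa_sweep_cpp(inp$Xm, inp$L, perm, alpha, delta, inp$use_likelihood,
                    inp$niw$mu0, inp$niw$lambda0, inp$niw$Psi0, inp$niw$nu0))
    K <- max(state)
    if (is.null(fixed_alpha)) alpha <- sample_alpha_west(K, n, a, b)
    K_trace[t] <- K
    alpha_trace[t] <- alpha
    if (t > burn_in) draws[t - burn_in, ] <- state
  }

  new_tip_fit(prior = prior, draws = draws, K_trace = K_trace,
              log_info = tibble::tibble(t = seq_len(total), K = K_trace,
                                        alpha = alpha_trace),
              inp = inp,
              config = list(burn_in = burn_in, samples = samples, seed = seed,
                            metric = metric, delta = delta, a = a, b = b,
                            alpha_init = alpha_init, fixed_alpha = fixed_alpha,
                            use_likelihood = inp$use_likelihood))
}
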