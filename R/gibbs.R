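#' Initialize a chain state
#'
#' @param n subject count.
#' @param rule `"one_cluster"` (everyone at one table, the default narrative
#'   start), `"singletons"`, or `"random_k"` (uniform labels over `1..k`,
#'   redrawn until every label occurs).
#' @param k number of clusters for `"random_k"`.
#' @return integer label vector of length n with contiguous labels from 1.
#' @export
initialize_state <- function(n, rule = c("one_cluster", "singletons", "random_k"),
                             k = 2) {
  rule <- match.arg(rule)
  switch(rule,
    one_cluster = rep(1L, n),
    singletons = seq_len(n),
    random_k = {
      repeat {
        lab <- sample.int(k, n, replace = TRUE)
        if (length(unique(lab)) == k) break
      }
      relabel_consecutive(lab)
    })
}

# map occupied labels to 1..K preserving label order
relabel_consecutive <- function(lab) {
  as.integer(match(lab, sort(unique(lab))))
}

#' Run the table-invitation Gibbs sampler
#'
#' Each iteration: (1) a host subject r is drawn uniformly; (2) the invitation
#' size is drawn as Poisson with mean equal to the first change-point position
#' in r's sorted distances; (3) the invited subjects are moved to a proposed
#' new table; (4) every subject's label is resampled over the existing tables
#' plus the proposed one, with probability proportional to the
#' table-invitation prior weight times (optionally) the Normal-Inverse-Wishart
#' posterior-predictive density of the subject under each table's current
#' members; (5) emptied tables are dropped and labels relabelled
#' consecutively.
#'
#' @param X n x p numeric matrix of subjects (rows). May be `NULL` when
#'   `distances` is supplied and `use_likelihood = FALSE`.
#' @param distances optional precomputed distance matrix; computed from `X`
#'   with `metric` otherwise.
#' @param metric distance metric for [distance_matrix()].
#' @param burn_in discarded initial iterations (default 1000).
#' @param samples recorded iterations (default 1000).
#' @param seed integer seed; the run is fully reproducible given it.
#' @param init initialization rule, see [initialize_state()].
#' @param init_k clusters for `init = "random_k"`.
#' @param use_likelihood multiply prior weights by the NIW posterior
#'   predictive (default `TRUE` when `X` is given).
#' @param niw NIW prior (see [niw_prior()]); defaults to
#'   [niw_default_prior()] on `X`.
#' @param exclude_self drop the self-similarity term from the prior weights.
#' @param sweep_order resample subjects in `"ascending"` index order or a
#'   fresh `"shuffled"` order each iteration.
#' @param cp_config change-point settings, see [changepoint_config()].
#' @return object of class `tip_fit`: `draws` (samples x n matrix),
#'   `K_trace`, `log_info` (per-iteration host, invitation size, K), `config`,
#'   `lambda`, `subject_ids`.
#' @export
#' @examples
#' d <- simulate_clusters(c(10, 10), p = 2, seed = 1)
#' fit <- run_tip(d$X, burn_in = 50, samples = 50, seed = 1)
#' glance(fit)
run_tip <- function(X = NULL, distances = NULL, metric = "euclidean",
                    burn_in = 1000, samples = 1000, seed = NULL,
                    init = "one_cluster", init_k = 2,
                    use_likelihood = !is.null(X), niw = NULL,
                    exclude_self = FALSE,
                    sweep_order = c("ascending", "shuffled"),
                    cp_config = NULL) {
  sweep_order <- match.arg(sweep_order)
  inp <- prepare_inputs(X, distances, metric, use_likelihood, niw)
  n <- inp$n
  stopifnot(samples >= 1, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cp_config)) cp_config <- changepoint_config(n)
  cp1 <- first_changepoints(inp$D, cp_config)

  state <- initialize_state(n, init, init_k)
  total <- burn_in + samples
  draws <- matrix(NA_integer_, samples, n)
  K_trace <- integer(total)
  hosts <- integer(total); ntaus <- integer(total)

  for (t in seq_len(total)) {
    r <- sample.int(n, 1)
    n_tau <- min(max(stats::rpois(1, cp1[r]), 1L), n - 1L)
    invited <- invited_set(inp$L, r, n_tau)
    prop <- propose_partition(state, invited)
    ord <- if (sweep_order == "ascending") seq_len(n) else sample.int(n)
    state <- relabel_consecutive(
      tip_sweep_cpp(inp$Xm, inp$L, prop$assignments, as.integer(ord),
                    exclude_self, inp$use_likelihood,
                    inp$niw$mu0, inp$niw$lambda0, inp$niw$Psi0, inp$niw$nu0))
    K_trace[t] <- max(state)
    hosts[t] <- r; ntaus[t] <- n_tau
    if (t > burn_in) draws[t - burn_in, ] <- state
  }

  new_tip_fit(prior = "tip", draws = draws, K_trace = K_trace,
              log_info = tibble::tibble(t = seq_len(total), host = hosts,
                                        n_tau = ntaus, K = K_trace),
              inp = inp,
              config = list(burn_in = burn_in, samples = samples, seed = seed,
                            init = init, metric = metric,
                            use_likelihood = inp$use_likelihood,
                            exclude_self = exclude_self,
                            sweep_order = sweep_order))
}

# shared input preparation for the TIP and EPA samplers
prepare_inputs <- function(X, distances, metric, use_likelihood, niw,
                           constant_similarity = FALSE) {
  if (is.null(X) && is.null(distances))
    stop("supply X or a distance matrix", call. = FALSE)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (!is.null(distances) && nrow(as.matrix(distances)) != nrow(X))
      stop("X and distance matrix sizes disagree", call. = FALSE)
  }
  if (use_likelihood && is.null(X))
    stop("the likelihood needs the data matrix X", call. = FALSE)
  D <- if (is.null(distances)) distance_matrix(X, metric)
       else validate_distance_matrix(as.matrix(distances))
  n <- nrow(D)
  L <- if (constant_similarity) matrix(1, n, n) else similarity_matrix(D)
  if (use_likelihood && is.null(niw)) niw <- niw_default_prior(X)
  if (!use_likelihood)
    niw <- list(mu0 = 0, lambda0 = 1, Psi0 = matrix(1), nu0 = 1)  # unused stub
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  Xm <- if (use_likelihood) X else matrix(0, n, 1)
  list(X = X, Xm = Xm, D = D, L = L, n = n, niw = niw,
       use_likelihood = use_likelihood, subject_ids = ids)
}

new_tip_fit <- function(prior, draws, K_trace, log_info, inp, config) {
  structure(list(prior = prior, draws = draws, K_trace = K_trace,
                 log_info = log_info, config = config,
                 lambda = inp$L, distances = inp$D, X = inp$X,
                 niw = if (inp$use_likelihood) inp$niw else NULL,
                 subject_ids = inp$subject_ids),
            class = "tip_fit")
}
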