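#' Binary co-clustering (proximity) matrix of one partition
#'
#' Entry (i, j) is 1 when subjects i and j share a label in the given draw,
#' else 0; the diagonal is all ones.
#'
#' @param c label vector.
#' @return n x n binary matrix.
#' @export
proximity_matrix <- function(c) {
  B <- outer(c, c, `==`) * 1
  dimnames(B) <- NULL
  B
}

#' Posterior similarity matrix from a set of draws
#'
#' The entrywise mean of each draw's proximity matrix: entry (i, j) estimates
#' the posterior probability that subjects i and j are clustered together.
#'
#' @param draws a T x n integer matrix of posterior partitions (one row per
#'   draw), or a list of label vectors.
#' @return n x n matrix with entries in \[0, 1\] and unit diagonal.
#' @export
posterior_similarity <- function(draws) {
  if (is.list(draws)) draws <- do.call(rbind, draws)
  if (inherits(draws, "tip_fit")) draws <- draws$draws
  draws <- as.matrix(draws)
  if (nrow(draws) < 1) stop("need at least one draw", call. = FALSE)
  n <- ncol(draws)
  B <- matrix(0, n, n)
  for (t in seq_len(nrow(draws))) {
    lab <- draws[t, ]
    # Z Z' for the one-hot indicator Z of this draw
    Z <- outer(lab, sort(unique(lab)), `==`) * 1
    B <- B + tcrossprod(Z)
  }
  B / nrow(draws)
}

#' Posterior expected adjusted Rand (PEAR) of a candidate partition
#'
#' Scores a candidate partition against the posterior similarity matrix: the
#' posterior expectation of the adjusted Rand index, computed in closed form
#' from the pairwise co-clustering indicators of the candidate and the
#' entries of `Bbar` (the expectation is linear in both). A degenerate 0/0 is
#' defined as 0.
#'
#' @param c candidate label vector.
#' @param Bbar posterior similarity matrix (see [posterior_similarity()]).
#' @return numeric scalar (1 when the candidate matches every draw behind
#'   `Bbar`).
#' @export
pear <- function(c, Bbar) {
  n <- length(c)
  if (n < 2 || nrow(Bbar) != n || ncol(Bbar) != n)
    stop("partition length and Bbar dimension disagree", call. = FALSE)
  up <- upper.tri(Bbar)
  I <- (outer(c, c, `==`) * 1)[up]
  Bv <- Bbar[up]
  C <- n * (n - 1) / 2
  sumI <- sum(I); sumB <- sum(Bv)
  num <- sum(I * Bv) - sumI * sumB / C
  den <- 0.5 * (sumI + sumB) - sumI * sumB / C
  if (den == 0) return(0)
  num / den
}

#' PEAR-optimal consensus partition among the recorded draws
#'
#' Evaluates PEAR for every recorded draw against the posterior similarity
#' matrix and returns the maximizer; ties go to the earliest draw.
#'
#' @param draws T x n matrix of posterior partitions (or a `tip_fit`).
#' @param Bbar posterior similarity matrix; computed from `draws` when `NULL`.
#' @return list with `assignment` (label vector), `pear_value`,
#'   `argmax_index`, and `pear_trace` (per-draw PEAR values).
#' @export
select_consensus <- function(draws, Bbar = NULL) {
  if (inherits(draws, "tip_fit")) draws <- draws$draws
  if (is.list(draws)) draws <- do.call(rbind, draws)
  draws <- as.matrix(draws)
  if (nrow(draws) < 1) stop("no draws to select from", call. = FALSE)
  if (is.null(Bbar)) Bbar <- posterior_similarity(draws)
  trace <- vapply(seq_len(nrow(draws)), function(t) pear(draws[t, ], Bbar),
                  numeric(1))
  best <- which.max(trace)  # which.max takes the earliest maximizer
  list(assignment = as.integer(draws[best, ]),
       pear_value = trace[best],
       argmax_index = as.integer(best),
       pear_trace = trace)
}
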