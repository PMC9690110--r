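#' Invited set for a host subject
#'
#' The host r plus the n_tau - 1 subjects most similar to it (largest
#' lambda(r, j)); ties are broken by ascending subject index so the set is
#' deterministic.
#'
#' @param L similarity matrix.
#' @param r host subject index.
#' @param n_tau invited count including the host, in 1..n-1.
#' @return integer vector of invited subject indices (host first).
#' @export
invited_set <- function(L, r, n_tau) {
  n <- nrow(L)
  if (n_tau < 1 || n_tau > n - 1)
    stop("n_tau must be in 1..n-1", call. = FALSE)
  others <- setdiff(seq_len(n), r)
  # order by similarity to r descending, ties by ascending index
  ord <- others[order(-L[r, others], others)]
  c(r, ord[seq_len(n_tau - 1)])
}

#' Modified partition with the invited subjects at a new table
#'
#' Invited subjects are moved to the proposed label K + 1; everyone else keeps
#' their current label. This modified partition fixes the prior weights for
#' one full Gibbs sweep.
#'
#' @param assignments current cluster labels, 1..K, every label occupied.
#' @param invited integer vector of invited subject indices.
#' @return list with `assignments` (labels over 1..K+1) and `new_label`.
#' @export
propose_partition <- function(assignments, invited) {
  K <- max(assignments)
  prop <- assignments
  prop[invited] <- K + 1L
  list(assignments = as.integer(prop), new_label = K + 1L)
}

#' Table-invitation prior over cluster labels for one subject
#'
#' The unnormalized prior weight of subject i joining cluster k is the total
#' similarity between i and the members of k under the modified partition
#' (including i's own self-similarity term when i sits in k, unless
#' `exclude_self`). With constant similarity this reduces to size-proportional
#' seating.
#'
#' @param L similarity matrix.
#' @param proposal label vector over 1..K+1 (see [propose_partition()]).
#' @param i subject index.
#' @param exclude_self drop the j = i term from the sums.
#' @return normalized probability vector over labels 1..max(proposal); empty
#'   labels get probability 0.
#' @export
tip_prior_probs <- function(L, proposal, i, exclude_self = FALSE) {
  Kp <- max(proposal)
  lam <- L[i, ]
  if (exclude_self) lam[i] <- 0
  w <- vapply(seq_len(Kp), function(k) sum(lam[proposal == k]), numeric(1))
  tot <- sum(w)
  if (tot <= 0) stop("all prior weights are zero", call. = FALSE)
  w / tot
}
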