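#' Sorted distances from one subject to all others
#'
#' Extracts row `r` of the distance matrix, drops the zero self-distance, and
#' sorts ascending. This is the univariate sequence on which change-point
#' detection estimates how many near neighbours subject `r` has.
#'
#' @param D distance matrix.
#' @param r subject index, 1..n.
#' @return numeric vector of length n - 1, nondecreasing.
#' @export
sorted_row_distances <- function(D, r) {
  n <- nrow(D)
  if (!is.numeric(r) || length(r) != 1 || r < 1 || r > n || r != round(r))
    stop("subject index r out of range", call. = FALSE)
  sort(D[r, -r])
}

#' Change-point detection configuration
#'
#' @param n subject count (sets the default maximum number of change points,
#'   `floor(n/2 + 1)`).
#' @param Q maximum number of change points.
#' @param min_segment minimum segment length on either side of a split.
#' @param penalty cost reduction a split must exceed to be accepted; the
#'   default is the SIC-style `log(m)` where m is the sequence length (applied
#'   at detection time when `NULL`).
#' @return a list with components `Q`, `min_segment`, `penalty`.
#' @export
changepoint_config <- function(n, Q = floor(n / 2 + 1), min_segment = 1,
                               penalty = NULL) {
  stopifnot(Q >= 1, min_segment >= 1)
  list(Q = as.integer(Q), min_segment = as.integer(min_segment),
       penalty = penalty)
}

#' Binary segmentation for univariate mean changes
#'
#' Greedy recursive segmentation under the Gaussian mean-change cost (sum of
#' squared deviations about segment means). At each step the split with the
#' largest cost reduction across all current segments is taken, provided the
#' reduction exceeds the penalty; stops at `Q` change points or when no
#' admissible split remains.
#'
#' @param y numeric sequence (here: one subject's sorted distances).
#' @param Q maximum number of change points.
#' @param min_segment minimum points per segment.
#' @param penalty acceptance threshold on the cost reduction; default
#'   `log(length(y))` (SIC-style, one parameter per change point).
#' @return integer vector of change-point positions (1-based index of the last
#'   point of the left segment), sorted ascending; empty when none detected.
#' @export
#' @examples
#' binary_segmentation(c(0, 0, 0, 10, 10, 10))  # 3
binary_segmentation <- function(y, Q = floor(length(y) / 2 + 1),
                                min_segment = 1, penalty = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("y contains missing values", call. = FALSE)
  if (length(y) < 2 * min_segment) return(integer(0))
  if (is.null(penalty)) penalty <- log(length(y))
  as.integer(binseg_cpp(y, as.integer(Q), as.integer(min_segment),
                        as.numeric(penalty)))
}

#' Invitation size for a host subject
#'
#' How many subjects a randomly selected host invites to a new cluster. The
#' host's sorted distances are segmented; the position of the first change
#' point — the count of nearest neighbours before the first break in distance —
#' is the Poisson mean from which the invitation size is drawn, then clamped
#' into \{1, ..., n-1\}. When no change point is found the mean falls back to
#' `max(1, floor((n-1)/2))`.
#'
#' Uses R's RNG: seed with `set.seed()` for reproducibility.
#'
#' @param D distance matrix.
#' @param r host subject index.
#' @param config see [changepoint_config()].
#' @return list with `n_tau` (invited count, including the host) and
#'   `mean_used` (the Poisson mean).
#' @export
estimate_invitation_size <- function(D, r, config = changepoint_config(nrow(D))) {
  n <- nrow(D)
  y <- sorted_row_distances(D, r)
  cps <- binary_segmentation(y, Q = config$Q, min_segment = config$min_segment,
                             penalty = config$penalty)
  mean_used <- if (length(cps) >= 1) cps[1] else max(1, floor((n - 1) / 2))
  n_tau <- stats::rpois(1, mean_used)
  n_tau <- min(max(n_tau, 1L), n - 1L)
  list(n_tau = as.integer(n_tau), mean_used = as.numeric(mean_used))
}

# First-change-point position for every subject. Deterministic given D, so it
# is computed once per chain rather than once per iteration.
first_changepoints <- function(D, config = changepoint_config(nrow(D))) {
  n <- nrow(D)
  fallback <- max(1, floor((n - 1) / 2))
  vapply(seq_len(n), function(r) {
    cps <- binary_segmentation(sorted_row_distances(D, r), Q = config$Q,
                               min_segment = config$min_segment,
                               penalty = config$penalty)
    if (length(cps) >= 1) as.numeric(cps[1]) else as.numeric(fallback)
  }, numeric(1))
}
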