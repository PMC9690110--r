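#' Pairwise distance matrix between subjects
#'
#' Computes the symmetric n x n matrix of pairwise distances between the rows
#' of a subjects-by-features matrix. Row i is one subject (e.g. one
#' gene-expression sample); the result feeds the exponential-decay similarity
#' kernel used by the table-invitation and EPA priors.
#'
#' @param X numeric matrix or data frame, n subjects by p features, no missing
#'   values.
#' @param metric one of `"euclidean"` (default), `"manhattan"`, or
#'   `"correlation"` (one minus the Pearson correlation between rows).
#' @return an n x n numeric matrix with zero diagonal, row/column names taken
#'   from `rownames(X)` (subject row numbers otherwise).
#' @export
#' @examples
#' X <- rbind(c(0, 0), c(3, 4))
#' distance_matrix(X)[1, 2]  # 5: the 3-4-5 triangle
distance_matrix <- function(X, metric = c("euclidean", "manhattan", "correlation")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric", call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 subjects (rows)", call. = FALSE)
  if (any(!is.finite(X))) stop("X contains missing or non-finite values", call. = FALSE)
  D <- switch(metric,
    euclidean   = as.matrix(stats::dist(X, method = "euclidean")),
    manhattan   = as.matrix(stats::dist(X, method = "manhattan")),
    correlation = 1 - stats::cor(t(X))
  )
  D <- 0.5 * (D + t(D))
  diag(D) <- 0
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  dimnames(D) <- list(ids, ids)
  D
}

#' Validate (and gently symmetrize) a user-supplied distance matrix
#'
#' A precomputed distance matrix bypasses [distance_matrix()] but must satisfy
#' the same contract: square, finite, nonnegative, zero diagonal, and symmetric
#' to within `tol` (after which it is symmetrized by averaging).
#'
#' @param D square numeric matrix of pairwise distances.
#' @param tol symmetry tolerance on `max |D - t(D)|`.
#' @return the validated, exactly symmetric matrix.
#' @export
validate_distance_matrix <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square", call. = FALSE)
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries", call. = FALSE)
  if (any(D < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (max(abs(D - t(D))) > tol)
    stop("distance matrix is not symmetric within tolerance ", tol, call. = FALSE)
  if (any(abs(diag(D)) > tol)) stop("distance matrix diagonal must be zero", call. = FALSE)
  D <- 0.5 * (D + t(D))
  diag(D) <- 0
  D
}

#' Similarity scale hyperparameter from the median pairwise distance
#'
#' The decay rate of the similarity kernel is set automatically to the
#' reciprocal of the median of the strictly-upper-triangular pairwise
#' distances, so that a pair at the median distance has similarity exp(-1).
#'
#' @param D distance matrix (see [distance_matrix()]).
#' @return a list with `tau` (the decay rate, 1/median) and `median_distance`.
#' @export
#' @examples
#' D <- distance_matrix(matrix(c(0, 1, 3), ncol = 1))
#' estimate_tau(D)$tau  # 1/median(1, 3, 2) = 0.5
estimate_tau <- function(D) {
  D <- validate_distance_matrix(D)
  up <- D[upper.tri(D)]
  if (length(up) < 1) stop("need at least one subject pair", call. = FALSE)
  med <- stats::median(up)
  if (med <= 0)
    stop("all pairwise distances are zero; similarity scale is undefined",
         call. = FALSE)
  list(tau = 1 / med, median_distance = med)
}

#' Exponential-decay similarity matrix
#'
#' Maps distances to attraction weights in (0, 1]: lambda(i, j) =
#' exp(-tau * d_ij). Identical subjects get similarity 1; pairs at the median
#' distance (with the default `tau`) get exp(-1); far pairs decay to 0.
#'
#' @param D distance matrix.
#' @param tau positive decay rate; defaults to [estimate_tau()]'s `tau`.
#' @return a symmetric n x n matrix with unit diagonal and entries in (0, 1].
#' @export
similarity_matrix <- function(D, tau = NULL) {
  D <- validate_distance_matrix(D)
  if (is.null(tau)) tau <- estimate_tau(D)$tau
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop("tau must be a single positive number", call. = FALSE)
  L <- exp(-tau * D)
  dimnames(L) <- dimnames(D)
  L
}
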