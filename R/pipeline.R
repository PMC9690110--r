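#' Read a subjects-by-features matrix from CSV/TSV
#'
#' The delimiter is chosen by extension (`.tsv`/`.txt` = tab, else comma). If
#' the first column is non-numeric it is used as subject identifiers;
#' otherwise identifiers are row numbers. An optional label column can be
#' split off for evaluation.
#'
#' @param path file path.
#' @param label_col optional name of a true-label column to separate out.
#' @return list with `X` (numeric matrix, rownames = subject ids) and
#'   `labels` (vector or NULL).
#' @export
read_matrix_file <- function(path, label_col = NULL) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(readr::read_delim(path, delim = delim,
                                        show_col_types = FALSE,
                                        progress = FALSE))
  labels <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(df))
      stop("label column '", label_col, "' not found", call. = FALSE)
    labels <- df[[label_col]]
    df[[label_col]] <- NULL
  }
  ids <- NULL
  if (ncol(df) > 1 && !is.numeric(df[[1]])) {
    ids <- as.character(df[[1]])
    df[[1]] <- NULL
  }
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("non-numeric feature columns in ", path, call. = FALSE)
  rownames(X) <- if (is.null(ids)) as.character(seq_len(nrow(X))) else ids
  list(X = X, labels = labels)
}

#' Read a precomputed square distance matrix from CSV/TSV
#'
#' @param path file path; a leading non-numeric column is treated as row
#'   identifiers and must match the header order.
#' @return validated symmetric distance matrix.
#' @export
read_distance_file <- function(path) {
  m <- read_matrix_file(path)
  D <- m$X
  colnames(D) <- colnames(D) %||% rownames(D)
  if (!is.null(rownames(D)) && !is.null(colnames(D)) &&
      !identical(unname(rownames(D)), unname(colnames(D))))
    stop("distance matrix row and column identifiers disagree", call. = FALSE)
  validate_distance_matrix(D)
}

#' Principal-component reduction of a subjects-by-features matrix
#'
#' Column-centered SVD projection onto the top `q` principal directions, with
#' a fixed sign convention (the largest-magnitude loading of each component is
#' positive) so results are deterministic.
#'
#' @param X n x p numeric matrix.
#' @param q number of components, `1 <= q <= min(n, p)`.
#' @return list with `scores` (n x q), `explained` (per-component variance
#'   fractions) and `cumulative` (their cumsum).
#' @export
pca_reduce <- function(X, q) {
  X <- as.matrix(X)
  if (q < 1 || q > min(dim(X)))
    stop("q must be in 1..min(n, p)", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(q), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(q), drop = FALSE], 2, flip, `*`)
  rownames(scores) <- rownames(X)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained = expl[seq_len(q)],
       cumulative = cumsum(expl)[seq_len(q)])
}

#' Run the full clustering pipeline and write its artifacts
#'
#' Reads the input matrix (or takes one in memory), optionally reduces it by
#' PCA, builds distances and similarities, runs the selected sampler, and
#' writes the consensus assignments, posterior similarity matrix, one-cluster
#' edge list, cluster-count trace, and a JSON run report to `output_dir`.
#'
#' @param input path to a subjects-by-features CSV/TSV, or a numeric matrix.
#' @param distances optional path to (or matrix of) precomputed distances.
#' @param prior `"tip"`, `"epa"`, or `"crp"`.
#' @param pca_components optional number of principal components.
#' @param burn_in,samples,seed sampler settings.
#' @param output_dir directory for the artifacts (created if missing); `NULL`
#'   skips writing.
#' @param label_col optional true-label column name in the input file.
#' @param ... further arguments passed to [run_tip()] or [run_epa()].
#' @return (invisibly) list with `fit`, `consensus`, `graph`, `report`.
#' @export
run_pipeline <- function(input, distances = NULL, prior = c("tip", "epa", "crp"),
                         pca_components = NULL, burn_in = 1000, samples = 1000,
                         seed = 1, output_dir = NULL, label_col = NULL, ...) {
  prior <- match.arg(prior)
  labels <- NULL
  if (is.character(input)) {
    m <- read_matrix_file(input, label_col = label_col)
    X <- m$X; labels <- m$labels
  } else {
    X <- as.matrix(input)
  }
  if (is.character(distances)) distances <- read_distance_file(distances)
  if (!is.null(pca_components)) X <- pca_reduce(X, pca_components)$scores

  fit <- if (prior == "tip") {
    run_tip(X, distances = distances, burn_in = burn_in, samples = samples,
            seed = seed, ...)
  } else {
    run_epa(X, distances = distances, burn_in = burn_in, samples = samples,
            seed = seed, prior = prior, ...)
  }
  cons <- tip_consensus(fit)
  graph <- one_cluster_graph(cons$Bbar)

  report <- list(prior = prior, n = length(cons$assignment),
                 p = ncol(X), seed = seed, burn_in = burn_in,
                 samples = samples, K = cons$K, pear = cons$pear_value,
                 pca_components = pca_components)
  if (!is.null(labels)) report$ari_vs_labels <- adjusted_rand(cons$assignment, labels)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tidy(cons), file.path(output_dir, "consensus.csv"))
    bb <- as.data.frame(cons$Bbar)
    names(bb) <- fit$subject_ids
    readr::write_csv(cbind(subject_id = fit$subject_ids, bb),
                     file.path(output_dir, "bbar.csv"))
    readr::write_tsv(tibble::as_tibble(graph), file.path(output_dir, "edges.tsv"))
    readr::write_csv(tibble::tibble(t = seq_along(fit$K_trace), K = fit$K_trace),
                     file.path(output_dir, "k_trace.csv"))
    readr::write_csv(tibble::as_tibble(fit$draws, .name_repair = "minimal"),
                     file.path(output_dir, "draws.csv"))
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(fit = fit, consensus = cons, graph = graph, report = report))
}

#' Write a simulated dataset to CSV
#'
#' @param data a `sim_clusters` object.
#' @param path output CSV path; features plus a `.cluster` truth column.
#' @return the path, invisibly.
#' @export
write_simulation <- function(data, path) {
  readr::write_csv(as.data.frame(data), path)
  invisible(path)
}
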